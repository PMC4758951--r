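#' @include AllClasses.R
NULL

#' Accessors for psamfit classes
#'
#' @param x,object An object of the documented classes.
#' @param ... Unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("referenceSeq", function(x) standardGeneric("referenceSeq"))
#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
#' @rdname accessors
#' @export
setGeneric("monoDdG", function(x) standardGeneric("monoDdG"))
#' @rdname accessors
#' @export
setGeneric("diDdG", function(x) standardGeneric("diDdG"))
#' @rdname accessors
#' @export
setGeneric("strandPolicy", function(x) standardGeneric("strandPolicy"))
#' @rdname accessors
#' @export
setGeneric("isPalindromic", function(x) standardGeneric("isPalindromic"))
#' @rdname accessors
#' @export
setGeneric("probeLength", function(x) standardGeneric("probeLength"))
#' @rdname accessors
#' @export
setGeneric("gammaProfile", function(x) standardGeneric("gammaProfile"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))
#' @rdname accessors
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))
#' @rdname accessors
#' @export
setGeneric("positionalBiasOf", function(x) standardGeneric("positionalBiasOf"))
#' @rdname accessors
#' @export
setGeneric("intensityModelOf", function(x) standardGeneric("intensityModelOf"))
#' @rdname accessors
#' @export
setGeneric("probeWeights", function(x) standardGeneric("probeWeights"))
#' @rdname accessors
#' @export
setGeneric("trainR2", function(x) standardGeneric("trainR2"))
#' @rdname accessors
#' @export
setGeneric("bindingModes", function(x) standardGeneric("bindingModes"))
#' @rdname accessors
#' @export
setGeneric("relKa", function(x) standardGeneric("relKa"))
#' @rdname accessors
#' @export
setGeneric("modePvalues", function(x) standardGeneric("modePvalues"))

## ---- ProbeTable ----

#' @rdname accessors
#' @export
setMethod("sequences", "ProbeTable", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("intensities", "ProbeTable", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("probeIds", "ProbeTable", function(x) x@probeId)
#' @rdname accessors
#' @export
setMethod("probeLength", "ProbeTable", function(x) nchar(x@sequence[1]))
#' @rdname accessors
#' @export
setMethod("length", "ProbeTable", function(x) length(x@probeId))

#' @rdname accessors
#' @export
setMethod("as.data.frame", "ProbeTable", function(x, ...) {
  data.frame(probe_id = x@probeId, sequence = x@sequence,
             intensity = x@intensity, stringsAsFactors = FALSE)
})

setMethod("show", "ProbeTable", function(object) {
  cat(sprintf("ProbeTable: %d probes x %d bp\n", length(object@probeId),
              nchar(object@sequence[1])))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@intensity), max(object@intensity)))
})

#' Subset a ProbeTable
#'
#' @param x A [ProbeTable-class].
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @return A [ProbeTable-class] with the selected probes.
#' @export
setMethod("[", "ProbeTable", function(x, i, j, ..., drop = FALSE) {
  new("ProbeTable", probeId = x@probeId[i], sequence = x@sequence[i],
      intensity = x@intensity[i])
})

## ---- FeatureModel ----

#' @rdname accessors
#' @export
setMethod("referenceSeq", "FeatureModel", function(x) x@referenceSeq)
#' @rdname accessors
#' @export
setMethod("motifLength", "FeatureModel", function(x) nchar(x@referenceSeq))
#' @rdname accessors
#' @export
setMethod("monoDdG", "FeatureModel", function(x) x@monoDdG)
#' @rdname accessors
#' @export
setMethod("diDdG", "FeatureModel",
          function(x) if (ncol(x@diDdG)) x@diDdG else NULL)
#' @rdname accessors
#' @export
setMethod("strandPolicy", "FeatureModel", function(x) x@strandPolicy)
#' @rdname accessors
#' @export
setMethod("isPalindromic", "FeatureModel", function(x) x@symmetric)

setMethod("show", "FeatureModel", function(object) {
  L <- motifLength(object)
  cat(sprintf("FeatureModel: L = %d, reference %s%s, strands: %s\n", L,
              object@referenceSeq,
              if (object@symmetric) " (palindromic)" else "",
              object@strandPolicy))
  cat(sprintf("  %s\n", if (ncol(object@diDdG))
    "mononucleotide + dinucleotide features (FSAM)"
    else "mononucleotide features only (PSAM)"))
  cat("  relative affinities exp(-ddG/RT):\n")
  print(round(exp(-object@monoDdG), 3))
})

## ---- PositionalBias ----

#' @rdname accessors
#' @export
setMethod("gammaProfile", "PositionalBias", function(x) x@gamma)
#' @rdname accessors
#' @export
setMethod("probeLength", "PositionalBias", function(x) x@probeLength)
#' @rdname accessors
#' @export
setMethod("motifLength", "PositionalBias", function(x) x@motifLength)

setMethod("show", "PositionalBias", function(object) {
  W <- object@probeLength - object@motifLength + 1L
  cat(sprintf("PositionalBias: probe %d bp, motif %d bp, %d views (%s)\n",
              object@probeLength, object@motifLength, length(object@gamma),
              object@strandPolicy))
  cat(sprintf("  gamma range [%.3f, %.3f]; per-offset slope %.4g\n",
              min(object@gamma), max(object@gamma), biasSlope(object)))
})

setMethod("show", "IntensityModel", function(object) {
  cat(sprintf("IntensityModel (%s): beta0 = %.4g, beta1 = %.4g, ddGns = %.4g\n",
              if (object@saturating) "saturating" else "linear",
              object@beta0, object@beta1, object@ddGns))
})

## ---- FitState ----

#' @rdname accessors
#' @export
setMethod("fittedModel", "FitState", function(x) x@model)
#' @rdname accessors
#' @export
setMethod("positionalBiasOf", "FitState", function(x) x@bias)
#' @rdname accessors
#' @export
setMethod("intensityModelOf", "FitState", function(x) x@im)
#' @rdname accessors
#' @export
setMethod("probeWeights", "FitState", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("trainR2", "FitState", function(x) x@r2Train)

setMethod("show", "FitState", function(object) {
  cat("FitState\n")
  show(object@model)
  cat(sprintf("  training R^2 = %.4f; beta_PSAM = %.4g\n",
              object@r2Train, object@betaPsam))
})

## ---- BindingModeSet ----

#' @rdname accessors
#' @export
setMethod("bindingModes", "BindingModeSet", function(x) x@modes)
#' @rdname accessors
#' @export
setMethod("relKa", "BindingModeSet", function(x) x@relKa)
#' @rdname accessors
#' @export
setMethod("modePvalues", "BindingModeSet", function(x) x@modePvalues)
#' @rdname accessors
#' @export
setMethod("length", "BindingModeSet", function(x) length(x@modes))

setMethod("show", "BindingModeSet", function(object) {
  cat(sprintf("BindingModeSet: %d mode(s)\n", length(object@modes)))
  for (i in seq_along(object@modes))
    cat(sprintf("  mode %d: %s (L = %d), rel K_a = %.3g, p = %.3g\n", i,
                object@modes[[i]]@referenceSeq,
                motifLength(object@modes[[i]]), object@relKa[i],
                object@modePvalues[i]))
})
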