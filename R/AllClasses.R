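#' @import methods
NULL

## ---------------------------------------------------------------------------
## ProbeTable
## ---------------------------------------------------------------------------

#' Probe table: sequences and measured intensities
#'
#' Container for a protein binding microarray (PBM) probe table: one probe
#' identifier, one fixed-length DNA sequence, and one background-subtracted
#' fluorescence intensity per probe. Intensities are the regression response
#' throughout the package.
#'
#' @slot probeId character, unique probe identifiers.
#' @slot sequence character, DNA sequences over \{A,C,G,T\}, all the same
#'   length.
#' @slot intensity numeric, finite fluorescence intensities.
#' @export
setClass("ProbeTable",
  representation(probeId = "character", sequence = "character",
                 intensity = "numeric"))

setValidity("ProbeTable", function(object) {
  n <- length(object@probeId)
  if (length(object@sequence) != n || length(object@intensity) != n)
    return("probeId, sequence and intensity must have equal length")
  if (n == 0L) return("probe table is empty")
  if (anyDuplicated(object@probeId))
    return("duplicate probe identifiers")
  if (length(unique(nchar(object@sequence))) != 1L)
    return("all probe sequences must have the same length")
  if (any(grepl("[^ACGT]", object@sequence)))
    return("probe sequences must contain only A, C, G, T")
  if (any(!is.finite(object@intensity)))
    return("intensities must be finite")
  TRUE
})

#' Construct a ProbeTable
#'
#' @param probeId Character vector of unique probe identifiers. Defaults to
#'   `probe_1 ... probe_n`.
#' @param sequence Character vector of equal-length DNA sequences.
#' @param intensity Numeric vector of intensities.
#' @return A [ProbeTable-class] object.
#' @export
#' @examples
#' pt <- ProbeTable(sequence = c("ACGTACGT", "TTTTACGT"), intensity = c(5, 2))
#' probeLength(pt)
ProbeTable <- function(probeId = NULL, sequence, intensity) {
  sequence <- as.vector(toupper(sequence))
  if (is.null(probeId)) probeId <- paste0("probe_", seq_along(sequence))
  new("ProbeTable", probeId = as.character(probeId),
      sequence = sequence, intensity = as.numeric(intensity))
}

## ---------------------------------------------------------------------------
## FeatureModel
## ---------------------------------------------------------------------------

#' Feature-based binding free-energy model (PSAM / FSAM)
#'
#' Represents the specificity of a transcription factor as dimensionless
#' binding free-energy penalties ddG/RT, additive over sequence features of a
#' binding window of length L. Mononucleotide features form the
#' position-specific affinity matrix (PSAM); optional adjacent-dinucleotide
#' features extend it to a feature-specific affinity model (FSAM). Within
#' every mononucleotide block the reference base is anchored at ddG/RT = 0;
#' dinucleotide blocks follow the scale-based convention in which values are
#' reported relative to the overall PSAM scale and carry no anchor.
#'
#' @slot referenceSeq character scalar, the length-L reference (highest
#'   affinity) sequence.
#' @slot monoDdG 4 x L numeric matrix of mono ddG/RT, rows A,C,G,T.
#' @slot diDdG 16 x (L-1) numeric matrix of dinucleotide ddG/RT (16 x 0 when
#'   the model is mononucleotide-only), rows AA,CA,...,TT in column-major
#'   base order `(b1-1)*4 + b2`.
#' @slot symmetric logical, TRUE for a reverse-complement-symmetric
#'   (palindromic) model with tied parameters.
#' @slot strandPolicy one of `"both"`, `"forward_only"`, `"reverse_only"`;
#'   which probe strands are enumerated when scoring.
#' @export
setClass("FeatureModel",
  representation(referenceSeq = "character", monoDdG = "matrix",
                 diDdG = "matrix", symmetric = "logical",
                 strandPolicy = "character"))

setValidity("FeatureModel", function(object) {
  L <- nchar(object@referenceSeq)
  if (L < 1L) return("reference sequence is empty")
  if (grepl("[^ACGT]", object@referenceSeq))
    return("reference sequence must contain only A, C, G, T")
  if (!identical(dim(object@monoDdG), c(4L, L)))
    return(sprintf("monoDdG must be 4 x %d", L))
  if (any(!is.finite(object@monoDdG)))
    return("monoDdG values must be finite")
  if (nrow(object@diDdG) != 16L)
    return("diDdG must have 16 rows")
  if (!ncol(object@diDdG) %in% c(0L, L - 1L))
    return(sprintf("diDdG must have 0 or %d columns", L - 1L))
  if (ncol(object@diDdG) > 0L && any(!is.finite(object@diDdG)))
    return("diDdG values must be finite")
  refb <- match(strsplit(object@referenceSeq, "")[[1]], .BASES)
  anchor <- object@monoDdG[cbind(refb, seq_len(L))]
  if (any(abs(anchor) > 1e-8))
    return("mono block of the reference base must be anchored at ddG/RT = 0")
  if (!object@strandPolicy %in% c("both", "forward_only", "reverse_only"))
    return("strandPolicy must be both, forward_only or reverse_only")
  TRUE
})

#' Construct a FeatureModel
#'
#' @param referenceSeq Length-L reference sequence (anchored at ddG/RT = 0 in
#'   every mono block).
#' @param monoDdG 4 x L matrix of mono ddG/RT (rows A,C,G,T). Default: 0 for
#'   the reference base, `offRef` elsewhere.
#' @param diDdG Optional 16 x (L-1) matrix of dinucleotide ddG/RT.
#' @param symmetric Logical palindromic flag.
#' @param strandPolicy `"both"` (default), `"forward_only"` or
#'   `"reverse_only"`.
#' @param offRef Default mono ddG/RT for non-reference bases when `monoDdG`
#'   is not given.
#' @return A [FeatureModel-class] object.
#' @export
#' @examples
#' m <- featureModel("CACGTG", offRef = 2)
#' relativeAffinity("CACGTG", m)
featureModel <- function(referenceSeq, monoDdG = NULL, diDdG = NULL,
                         symmetric = FALSE, strandPolicy = "both",
                         offRef = 0) {
  referenceSeq <- toupper(referenceSeq)
  .checkDNA(referenceSeq, "reference sequence")
  L <- nchar(referenceSeq)
  refb <- match(strsplit(referenceSeq, "")[[1]], .BASES)
  if (is.null(monoDdG)) {
    monoDdG <- matrix(offRef, 4L, L)
    monoDdG[cbind(refb, seq_len(L))] <- 0
  }
  monoDdG <- as.matrix(monoDdG)
  dimnames(monoDdG) <- list(.BASES, NULL)
  if (is.null(diDdG)) diDdG <- matrix(numeric(0), 16L, 0L)
  diDdG <- as.matrix(diDdG)
  dimnames(diDdG) <- list(.DINUCS, NULL)
  new("FeatureModel", referenceSeq = referenceSeq, monoDdG = monoDdG,
      diDdG = diDdG, symmetric = symmetric, strandPolicy = strandPolicy)
}

## ---------------------------------------------------------------------------
## PositionalBias
## ---------------------------------------------------------------------------

#' Positional/strand bias profile
#'
#' Multiplicative coefficients gamma_v, one per view v = (offset, strand) of
#' a probe of fixed length, shared across all probes. The profile captures
#' how strongly a binding site at a given offset and orientation contributes
#' to the measured intensity. The maximum is normalised to 1; the overall
#' scale lives in the intensity model's beta1.
#'
#' @slot gamma numeric vector of per-view coefficients, ordered as the views
#'   returned by [enumerateViews()] (all forward then all reverse, ascending
#'   offset; strands restricted by `strandPolicy`).
#' @slot probeLength integer probe length.
#' @slot motifLength integer motif window length L.
#' @slot strandPolicy strand policy the view order corresponds to.
#' @export
setClass("PositionalBias",
  representation(gamma = "numeric", probeLength = "integer",
                 motifLength = "integer", strandPolicy = "character"))

setValidity("PositionalBias", function(object) {
  W <- object@probeLength - object@motifLength + 1L
  nv <- if (object@strandPolicy == "both") 2L * W else W
  if (length(object@gamma) != nv)
    return(sprintf("gamma must have %d entries for this geometry", nv))
  if (any(object@gamma < 0)) return("gamma must be non-negative")
  if (max(object@gamma) <= 0) return("at least one gamma must be positive")
  if (abs(max(object@gamma) - 1) > 1e-8)
    return("gamma must be normalised to max 1")
  TRUE
})

#' Construct a PositionalBias
#'
#' @param gamma Numeric vector of per-view coefficients (renormalised so the
#'   maximum is 1).
#' @param probeLength,motifLength Probe and motif window lengths.
#' @param strandPolicy View enumeration policy the gamma order refers to.
#' @return A [PositionalBias-class] object.
#' @export
positionalBias <- function(gamma, probeLength, motifLength,
                           strandPolicy = "both") {
  gamma <- as.numeric(gamma)
  if (any(gamma < 0) || max(gamma) <= 0)
    stop("gamma must be non-negative with at least one positive entry")
  new("PositionalBias", gamma = gamma / max(gamma),
      probeLength = as.integer(probeLength),
      motifLength = as.integer(motifLength), strandPolicy = strandPolicy)
}

## flat profile helper
.flatBias <- function(probeLength, motifLength, strandPolicy = "both") {
  W <- probeLength - motifLength + 1L
  nv <- if (strandPolicy == "both") 2L * W else W
  positionalBias(rep(1, nv), probeLength, motifLength, strandPolicy)
}

## ---------------------------------------------------------------------------
## IntensityModel
## ---------------------------------------------------------------------------

#' Probe intensity model parameters
#'
#' Links the summed (bias-weighted) relative affinities of a probe's views to
#' its fluorescence intensity: `y = beta0 + beta1 * sum_v gamma_v a_v` in the
#' linear regime, or, in the saturating occupancy form, each view contributes
#' `x_v / (1 + x_v)` with `x_v = gamma_v a_v + exp(-ddGns)` where `ddGns` is
#' the dimensionless non-specific binding term ddG_ns/RT.
#'
#' @slot beta0 numeric intercept (background intensity).
#' @slot beta1 numeric positive scale.
#' @slot ddGns numeric non-specific term ddG_ns/RT (large value means
#'   negligible non-specific binding).
#' @slot saturating logical; FALSE selects the linear model.
#' @slot conc numeric positive free-protein concentration scale of the
#'   saturating model (the `[P] Ka` factor multiplying the bias-weighted
#'   affinity inside the occupancy term); 1 by convention in the linear
#'   model, where it is confounded with beta1.
#' @export
setClass("IntensityModel",
  representation(beta0 = "numeric", beta1 = "numeric", ddGns = "numeric",
                 saturating = "logical", conc = "numeric"))

setValidity("IntensityModel", function(object) {
  if (length(object@beta1) != 1L || !is.finite(object@beta1) ||
      object@beta1 <= 0)
    return("beta1 must be a positive finite scalar")
  TRUE
})

#' Construct an IntensityModel
#'
#' @param beta0 Intercept.
#' @param beta1 Positive scale.
#' @param ddGns Non-specific binding term ddG_ns/RT.
#' @param saturating Logical; use the saturating occupancy form?
#' @param conc Free-protein concentration scale (saturating model only).
#' @return An [IntensityModel-class] object.
#' @export
intensityModel <- function(beta0 = 0, beta1 = 1, ddGns = 20,
                           saturating = FALSE, conc = 1) {
  new("IntensityModel", beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
      ddGns = as.numeric(ddGns), saturating = saturating,
      conc = as.numeric(conc))
}

## ---------------------------------------------------------------------------
## FitConfig
## ---------------------------------------------------------------------------

#' Fit configuration
#'
#' All hyperparameters of the inference pipeline in one (validated) object.
#' See [fitConfig()] for defaults and meanings.
#'
#' @export
setClass("FitConfig",
  representation(
    kSeed = "integer", seedTrimFrac = "numeric", alpha = "numeric",
    seedTol = "numeric", seedMaxIter = "integer",
    seedMinSupport = "integer", seedSupportFrac = "numeric",
    trimProbesFrac = "numeric", huberC = "numeric", robust = "logical",
    blockTol = "numeric", maxBlockPasses = "integer",
    maxOuterRounds = "integer", initDdG = "numeric", ddGCeiling = "numeric",
    includeDi = "logical", saturation = "logical",
    knownSeed = "character", polyGCRule = "logical",
    symmetry = "character", palTol = "numeric", growMotif = "logical",
    heldOutFrac = "numeric", maxModes = "integer", modeTol = "numeric",
    modeMaxRounds = "integer", modePThreshold = "numeric",
    modeMinRelKa = "numeric", modeMinResidR2 = "numeric",
    modeDupL1 = "numeric", rngSeed = "integer"))

setValidity("FitConfig", function(object) {
  if (object@seedTrimFrac < 0 || object@seedTrimFrac >= 0.5)
    return("seedTrimFrac must be in [0, 0.5)")
  if (object@trimProbesFrac < 0 || object@trimProbesFrac >= 0.5)
    return("trimProbesFrac must be in [0, 0.5)")
  if (object@alpha <= 0 || object@alpha > 1)
    return("alpha must be in (0, 1]")
  if (!object@symmetry %in% c("off", "auto", "on"))
    return("symmetry must be off, auto or on")
  TRUE
})

#' Construct a FitConfig
#'
#' @param kSeed Oligomer length K for seed discovery (default 8, matching the
#'   practical octamer limit of tabular PBM models).
#' @param seedTrimFrac Fraction trimmed from each tail of the per-probe
#'   exact-coefficient values in seed discovery (default 0.15).
#' @param alpha Step size of the convex coefficient update in seed discovery
#'   and of the multi-mode blending (default 0.1).
#' @param seedTol Convergence tolerance for seed discovery: relative change
#'   `max|delta beta| / max(beta)` (default 1e-6).
#' @param seedMaxIter Iteration cap for seed discovery (default 200).
#' @param seedMinSupport Minimum number of probes an oligomer must occur in
#'   to be eligible as the seed (default 30): the trimmed mean of a handful
#'   of values trims nothing and is dominated by single bright (or outlier)
#'   probes, so poorly supported K-mers cannot be estimated robustly. When
#'   no oligomer reaches the threshold the best-supported tier is used.
#' @param seedSupportFrac Within the sequence family of the
#'   highest-coefficient oligomer, members supported by fewer than this
#'   fraction of the family's maximum support are excluded before the
#'   final argmax (default 0.5). Sliding-window shadows of a concentrated
#'   binding site share most of their probes with it and acquire
#'   statistically indistinguishable coefficients; support dominance
#'   resolves the family in favour of the site itself, while designs with
#'   uniform K-mer coverage are left untouched.
#' @param trimProbesFrac Fraction of probes hard-trimmed (weight 0) per
#'   robust regression round (default 0.20).
#' @param huberC Huber tuning constant for the IRLS weights (default 1.345).
#' @param robust Use robust IRLS (TRUE) or plain least squares (FALSE); the
#'   latter exists for the robust-vs-OLS contrast.
#' @param blockTol Within-pass convergence tolerance on max |change in
#'   ddG/RT| during block cycling (default 1e-4).
#' @param maxBlockPasses Cap on passes over all blocks per cycling stage.
#' @param maxOuterRounds Cap on outer rounds (block cycling + bias
#'   re-estimation) (default 20).
#' @param initDdG Initial mono ddG/RT for non-reference bases (default 1.0;
#'   0 would make all windows equivalent and the first block fit degenerate).
#' @param ddGCeiling ddG/RT assigned to features whose regression coefficient
#'   is non-positive ("never observed bound"; default 10).
#' @param includeDi Fit dinucleotide blocks after the PSAM converges?
#' @param saturation Fit the saturating intensity model as a final step?
#' @param knownSeed Optional fixed seed sequence, skipping seed discovery.
#' @param polyGCRule Apply the poly-G/C strand policy rule to the seed?
#' @param symmetry Palindrome handling: `"off"`, `"auto"` (detect, then tie
#'   if symmetric), or `"on"` (force tying).
#' @param palTol Mean per-column L1 tolerance (relative-affinity scale) for
#'   declaring a motif palindromic (default 0.1).
#' @param growMotif Run motif-length selection after the initial fit?
#' @param heldOutFrac Held-out probe fraction for the length criterion
#'   (default 0.1).
#' @param maxModes Maximum number of binding modes for [fitMultiMode()].
#' @param modeTol Convergence tolerance on max |change in ddG/RT| during
#'   multi-mode refinement.
#' @param modeMaxRounds Cap on multi-mode refinement rounds (default 3;
#'   the alpha-blended updates change little after the first rounds).
#' @param modePThreshold Significance threshold for retaining a mode
#'   (default 0.01).
#' @param modeMinRelKa Minimum relative K_a (fraction of the strongest
#'   mode) for retaining a mode (default 0.01). The joint-regression t-test
#'   alone is anti-conservative because each candidate mode was optimised
#'   on the very residuals it is tested against; a "mode" binding three
#'   orders of magnitude weaker than the primary one is residual structure,
#'   not an alternative binding geometry.
#' @param modeMinResidR2 Minimum fraction of the residual variance a
#'   candidate mode must explain to enter the mode set (default 0.1); a
#'   residual fit explaining only a few percent reflects systematic model
#'   mismatch, not a coherent alternative binding geometry.
#' @param modeDupL1 L1 distance on mono ddG/RT below which a new mode is
#'   considered a duplicate of an existing one (default 0.05).
#' @param rngSeed RNG seed used for every stochastic choice in the pipeline.
#' @return A [FitConfig-class] object.
#' @export
#' @examples
#' cfg <- fitConfig(kSeed = 8, includeDi = TRUE)
fitConfig <- function(kSeed = 8L, seedTrimFrac = 0.15, alpha = 0.1,
                      seedTol = 1e-6, seedMaxIter = 200L,
                      seedMinSupport = 30L, seedSupportFrac = 0.5,
                      trimProbesFrac = 0.20, huberC = 1.345, robust = TRUE,
                      blockTol = 1e-4, maxBlockPasses = 20L,
                      maxOuterRounds = 20L, initDdG = 1.0, ddGCeiling = 10,
                      includeDi = FALSE, saturation = FALSE,
                      knownSeed = NA_character_, polyGCRule = TRUE,
                      symmetry = "off", palTol = 0.1, growMotif = FALSE,
                      heldOutFrac = 0.1, maxModes = 1L, modeTol = 1e-3,
                      modeMaxRounds = 3L, modePThreshold = 0.01,
                      modeMinRelKa = 0.01, modeMinResidR2 = 0.1,
                      modeDupL1 = 0.05, rngSeed = 1L) {
  new("FitConfig", kSeed = as.integer(kSeed), seedTrimFrac = seedTrimFrac,
      alpha = alpha, seedTol = seedTol, seedMaxIter = as.integer(seedMaxIter),
      seedMinSupport = as.integer(seedMinSupport),
      seedSupportFrac = seedSupportFrac,
      trimProbesFrac = trimProbesFrac, huberC = huberC, robust = robust,
      blockTol = blockTol, maxBlockPasses = as.integer(maxBlockPasses),
      maxOuterRounds = as.integer(maxOuterRounds), initDdG = initDdG,
      ddGCeiling = ddGCeiling, includeDi = includeDi, saturation = saturation,
      knownSeed = as.character(knownSeed), polyGCRule = polyGCRule,
      symmetry = symmetry, palTol = palTol, growMotif = growMotif,
      heldOutFrac = heldOutFrac, maxModes = as.integer(maxModes),
      modeTol = modeTol, modeMaxRounds = as.integer(modeMaxRounds),
      modePThreshold = modePThreshold, modeMinRelKa = modeMinRelKa,
      modeMinResidR2 = modeMinResidR2, modeDupL1 = modeDupL1,
      rngSeed = as.integer(rngSeed))
}

## ---------------------------------------------------------------------------
## FitState
## ---------------------------------------------------------------------------

#' Fitted model state
#'
#' The result of [fitModel()]: the feature model, positional bias, intensity
#' model, per-probe robustness weights from the final robust stage, the
#' frozen PSAM reference scale used for dinucleotide conversion, and the
#' training R-squared.
#'
#' @slot model [FeatureModel-class].
#' @slot bias [PositionalBias-class].
#' @slot im [IntensityModel-class].
#' @slot weights numeric per-probe robustness weights in [0, 1].
#' @slot betaPsam numeric; beta1 recorded at the end of the
#'   mononucleotide-only phase and frozen for dinucleotide conversions.
#' @slot r2Train numeric training R-squared.
#' @slot config [FitConfig-class] used for the fit.
#' @slot details list of per-round diagnostics (R-squared, convergence
#'   norms, seed, log messages).
#' @export
setClass("FitState",
  representation(model = "FeatureModel", bias = "PositionalBias",
                 im = "IntensityModel", weights = "numeric",
                 betaPsam = "numeric", r2Train = "numeric",
                 config = "FitConfig", details = "list"))

## ---------------------------------------------------------------------------
## BindingModeSet
## ---------------------------------------------------------------------------

#' A set of binding modes with relative association constants
#'
#' One or more feature models (modes), each with a relative K_a coefficient
#' (mode 1 anchored at 1), a shared intensity model and one positional bias
#' per mode (modes of different length have different view geometries).
#'
#' @slot modes list of [FeatureModel-class].
#' @slot relKa numeric relative K_a per mode; `relKa[1] == 1`.
#' @slot modePvalues numeric significance of each mode from the final joint
#'   regression (NA for a single-mode set).
#' @slot im shared [IntensityModel-class].
#' @slot biases list of [PositionalBias-class], one per mode.
#' @slot details list of diagnostics.
#' @export
setClass("BindingModeSet",
  representation(modes = "list", relKa = "numeric", modePvalues = "numeric",
                 im = "IntensityModel", biases = "list", details = "list"))

setValidity("BindingModeSet", function(object) {
  k <- length(object@modes)
  if (k == 0L) return("at least one mode required")
  if (length(object@relKa) != k || length(object@biases) != k)
    return("relKa and biases must match the number of modes")
  if (abs(object@relKa[1] - 1) > 1e-12)
    return("mode 1 must be anchored at relKa == 1")
  if (any(object@relKa <= 0)) return("relKa must be positive")
  TRUE
})

## ---------------------------------------------------------------------------
## SimSpec
## ---------------------------------------------------------------------------

#' Synthetic PBM data specification
#'
#' Defines the generating conditions for a synthetic PBM dataset with known
#' ground truth: probe geometry, a true binding model (one or more modes),
#' positional bias profile, intensity model, noise, and outlier
#' contamination. See [simSpec()].
#'
#' @export
setClass("SimSpec",
  representation(
    nProbes = "integer", probeLen = "integer", modes = "list",
    relKa = "numeric", gammaProfile = "ANY", beta0 = "numeric",
    beta1 = "numeric", noiseSdFrac = "numeric", outlierFrac = "numeric",
    outlierFactor = "numeric", saturating = "logical", ddGns = "numeric",
    conc = "numeric",
    plantFrac = "numeric", plantOffsets = "ANY", mutationRate = "numeric",
    diFeaturePos = "integer", diFeatureDinuc = "character",
    diFeatureDdG = "numeric", diFeatureFrac = "numeric",
    rngSeed = "integer"))

setValidity("SimSpec", function(object) {
  if (object@nProbes <= 0L) return("nProbes must be positive")
  for (f in c(object@noiseSdFrac, object@outlierFrac, object@plantFrac,
              object@mutationRate))
    if (f < 0 || f >= 1 + 1e-12) return("fractions must be in [0, 1]")
  if (any(vapply(object@modes, function(m) nchar(m@referenceSeq),
                 1L) > object@probeLen))
    return("motif longer than probe")
  TRUE
})
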