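## Synthetic PBM data with known ground truth. The generator emulates a
## universal-PBM-like design: fixed-length random probes, a fraction of
## which carry a (lightly mutagenised) planted binding site at a controlled
## or random offset, intensities produced by the forward intensity model
## with a positional bias profile, Gaussian noise, and an optional fraction
## of multiplicative bright-spot outliers.

## per-position ddG/RT strengths -> anchored 4 x L matrix
.truthFromStrengths <- function(ref, strengths) {
  L <- nchar(ref)
  refb <- match(strsplit(ref, "")[[1]], .BASES)
  M <- matrix(0, 4L, L, dimnames = list(.BASES, NULL))
  for (j in seq_len(L)) M[-refb[j], j] <- strengths[[j]]
  M
}

#' Built-in ground-truth binding models
#'
#' Realistic 8-bp free-energy models used as simulation ground truth:
#' `"asymmetric"` (a GATA-like motif with a strong core and softer flanks),
#' `"palindromic"` (an E-box-like reverse-complement-symmetric motif),
#' `"overlap"` and `"nonoverlap"` (a bZIP-like pair of dimer modes whose
#' half-sites do or do not overlap, for multi-mode simulations).
#'
#' @param kind Which truth model.
#' @return A [FeatureModel-class].
#' @export
#' @examples
#' defaultTruthModel("asymmetric")
defaultTruthModel <- function(kind = c("asymmetric", "palindromic",
                                       "overlap", "nonoverlap")) {
  kind <- match.arg(kind)
  flank <- c(0.4, 0.7, 1.0)
  mid <- c(0.8, 1.2, 1.6)
  core <- c(1.5, 2.2, 2.8)
  if (kind == "asymmetric") {
    ref <- "AGGATAAG"
    strengths <- list(flank, mid, core, core, core, core, mid, flank)
    M <- .truthFromStrengths(ref, strengths)
    return(featureModel(ref, M))
  }
  if (kind == "palindromic") {
    ref <- "TCACGTGA"   # equal to its own reverse complement
    strengths <- list(flank, mid, core, core, core, core, mid, flank)
    M <- .truthFromStrengths(ref, strengths)
    ## tie ddG(j, b) == ddG(L-1-j, comp(b)) exactly
    L <- ncol(M)
    for (j in seq_len(L %/% 2L)) {
      avg <- (M[, j] + M[4:1, L + 1L - j]) / 2
      M[, j] <- avg
      M[, L + 1L - j] <- avg[4:1]
    }
    return(featureModel(ref, M, symmetric = TRUE))
  }
  if (kind == "overlap") {
    ref <- "ATGACTCA"   # bZIP half-sites with 1-bp overlap
    strengths <- list(mid, core, core, core, core, core, core, mid)
    return(featureModel(ref, .truthFromStrengths(ref, strengths)))
  }
  ref <- "TGACGTCA"     # non-overlapping half-sites
  strengths <- list(core, core, core, core, core, core, core, core)
  featureModel(ref, .truthFromStrengths(ref, strengths))
}

#' Specify a synthetic PBM dataset
#'
#' Defaults mirror a universal-PBM-like geometry scaled to desk size:
#' 30-bp variable regions, half the probes carrying a mutagenised planted
#' site, a positional-bias ramp rising away from the substrate, 5 percent
#' Gaussian noise, and no outliers unless requested.
#'
#' @param nProbes Number of probes.
#' @param probeLen Probe (variable-region) length in bp.
#' @param modes List of true [FeatureModel-class] modes (default: the
#'   asymmetric built-in truth).
#' @param relKa Relative K_a per mode (mode 1 = 1).
#' @param gammaProfile `"flat"`, `"ramp"`, `"end-dip"`, or a custom numeric
#'   vector (one value per forward offset, or one per view).
#' @param beta0,beta1 Intensity intercept and scale (fluorescence units).
#' @param noiseSdFrac Gaussian noise sd as a fraction of the noiseless
#'   signal sd.
#' @param outlierFrac Fraction of probes turned into multiplicative
#'   outliers.
#' @param outlierFactor Multiplicative factor for outlier probes (default
#'   10, emulating bright-spot artifacts).
#' @param saturating Generate from the saturating occupancy model?
#' @param ddGns Non-specific term ddG_ns/RT for the saturating model.
#' @param conc Free-protein concentration scale of the saturating model
#'   (multiplies the bias-weighted affinity inside the occupancy term;
#'   values well above 1 saturate the strongest sites).
#' @param plantFrac Fraction of probes carrying a planted site.
#' @param plantOffsets Optional fixed 0-based offset(s) for planted sites
#'   (recycled); default random offsets.
#' @param mutationRate Per-position probability that a planted site carries
#'   a point mutation (yields the single/double mutants that pin down the
#'   free-energy parameters).
#' @param diFeaturePos 0-based position of a planted dinucleotide feature
#'   within mode 1's window, or `NA` for none. The feature is added to the
#'   truth model's dinucleotide block and planted as a coordinated double
#'   substitution in `diFeatureFrac` of the planted sites -- the only design
#'   under which a pairwise dependency is separable from what the
#'   mononucleotide marginals absorb.
#' @param diFeatureDinuc Two-base string of the planted dinucleotide.
#' @param diFeatureDdG ddG/RT of the planted dinucleotide feature.
#' @param diFeatureFrac Fraction of planted sites carrying the coordinated
#'   double substitution.
#' @param rngSeed Seed for all randomness of the generator.
#' @return A [SimSpec-class].
#' @export
simSpec <- function(nProbes = 5000L, probeLen = 30L,
                    modes = list(defaultTruthModel("asymmetric")),
                    relKa = rep(1, length(modes)),
                    gammaProfile = "ramp", beta0 = 100, beta1 = 1000,
                    noiseSdFrac = 0.05, outlierFrac = 0, outlierFactor = 10,
                    saturating = FALSE, ddGns = 20, conc = 1,
                    plantFrac = 0.5,
                    plantOffsets = NULL, mutationRate = 0.15,
                    diFeaturePos = NA_integer_, diFeatureDinuc = "CA",
                    diFeatureDdG = 0.8, diFeatureFrac = 0.1,
                    rngSeed = 1L) {
  if (is(modes, "FeatureModel")) modes <- list(modes)
  relKa <- as.numeric(relKa)
  if (length(relKa) != length(modes))
    stop("relKa must have one entry per mode")
  if (!is.na(diFeaturePos)) {
    m1 <- modes[[1L]]
    L <- motifLength(m1)
    stopifnot(diFeaturePos >= 0, diFeaturePos < L - 1L,
              diFeatureDinuc %in% .DINUCS)
    D <- if (ncol(m1@diDdG)) m1@diDdG else matrix(0, 16L, L - 1L)
    D[match(diFeatureDinuc, .DINUCS), diFeaturePos + 1L] <- diFeatureDdG
    modes[[1L]] <- featureModel(m1@referenceSeq, m1@monoDdG, diDdG = D,
                                symmetric = m1@symmetric,
                                strandPolicy = m1@strandPolicy)
  }
  new("SimSpec", nProbes = as.integer(nProbes),
      probeLen = as.integer(probeLen), modes = modes, relKa = relKa,
      gammaProfile = gammaProfile, beta0 = beta0, beta1 = beta1,
      noiseSdFrac = noiseSdFrac, outlierFrac = outlierFrac,
      outlierFactor = outlierFactor, saturating = saturating, ddGns = ddGns,
      conc = conc, plantFrac = plantFrac, plantOffsets = plantOffsets,
      mutationRate = mutationRate,
      diFeaturePos = as.integer(diFeaturePos),
      diFeatureDinuc = diFeatureDinuc, diFeatureDdG = diFeatureDdG,
      diFeatureFrac = diFeatureFrac, rngSeed = as.integer(rngSeed))
}

## gamma vector for one mode geometry
.gammaVector <- function(profile, probeLen, L, strandPolicy = "both") {
  W <- probeLen - L + 1L
  nv <- .nViews(probeLen, L, strandPolicy)
  if (is.numeric(profile)) {
    g <- if (length(profile) == nv) profile
         else if (length(profile) == W) {
           if (strandPolicy == "both") c(profile, profile) else profile
         } else stop("custom gamma profile has the wrong length")
    return(g / max(g))
  }
  g <- switch(profile,
    flat = rep(1, W),
    ramp = seq(0.2, 1, length.out = W),
    `end-dip` = {
      g <- seq(0.25, 1.15, length.out = W)
      tail <- seq.int(max(1L, W - 2L), W)
      g[tail] <- g[tail] * 0.5
      g
    },
    stop("unknown gamma profile: ", profile))
  g <- g / max(g)
  if (strandPolicy == "both") c(g, g) else g
}

#' Generate random probe sequences with planted sites
#'
#' Draws i.i.d. uniform-random probes from the spec's seeded RNG, then
#' plants a (possibly mutagenised) copy of a true mode's reference site at
#' a controlled or random offset in `plantFrac` of the probes (modes
#' assigned round-robin).
#'
#' @param spec A [SimSpec-class].
#' @return Character vector of probe sequences with attributes `planted`
#'   (logical), `offset` (0-based, NA when unplanted) and `mode` (mode
#'   index, NA when unplanted).
#' @export
makeProbes <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  set.seed(spec@rngSeed)
  n <- spec@nProbes
  P <- spec@probeLen
  mat <- matrix(sample.int(4L, n * P, replace = TRUE), n, P)
  planted <- rep(FALSE, n)
  offsets <- rep(NA_integer_, n)
  modeIdx <- rep(NA_integer_, n)
  nPlant <- round(spec@plantFrac * n)
  if (nPlant > 0L) {
    who <- sample.int(n, nPlant)
    planted[who] <- TRUE
    modeIdx[who] <- rep_len(seq_along(spec@modes), nPlant)
    diProbe <- rep(FALSE, n)
    if (!is.na(spec@diFeaturePos))
      diProbe[who[modeIdx[who] == 1L]] <-
        stats::runif(sum(modeIdx[who] == 1L)) < spec@diFeatureFrac
    for (i in seq_len(nPlant)) {
      p <- who[i]
      mod <- spec@modes[[modeIdx[p]]]
      L <- motifLength(mod)
      W <- P - L + 1L
      off <- if (is.null(spec@plantOffsets)) sample.int(W, 1L) - 1L
             else spec@plantOffsets[(i - 1L) %% length(spec@plantOffsets) + 1L]
      site <- match(strsplit(mod@referenceSeq, "")[[1]], .BASES)
      mut <- stats::runif(L) < spec@mutationRate
      if (any(mut))
        site[mut] <- vapply(site[mut],
                            function(b) sample(setdiff(1:4, b), 1L), 1L)
      if (!is.na(spec@diFeaturePos) && diProbe[p]) {
        j <- spec@diFeaturePos + 1L
        db <- match(strsplit(spec@diFeatureDinuc, "")[[1]], .BASES)
        site[j] <- db[1L]
        site[j + 1L] <- db[2L]
      }
      ## written orientation is arbitrary on a double-stranded probe
      if (stats::runif(1) < 0.5) site <- rev(5L - site)
      mat[p, (off + 1L):(off + L)] <- site
      offsets[p] <- off
    }
  }
  seqs <- do.call(paste0, as.data.frame(matrix(.BASES[mat], n, P)))
  attr(seqs, "planted") <- planted
  attr(seqs, "offset") <- offsets
  attr(seqs, "mode") <- modeIdx
  seqs
}

#' Simulate probe intensities from known truth
#'
#' Computes noiseless intensities from the spec's true modes, bias profile
#' and intensity parameters via the forward model, adds Gaussian noise, and
#' multiplies a seeded subset of probes by the outlier factor. The returned
#' table carries the full ground truth (models, bias profiles, noiseless
#' intensities, outlier flags) in its `truth` attribute.
#'
#' @param sequences Character vector of probe sequences (e.g. from
#'   [makeProbes()]).
#' @param spec A [SimSpec-class].
#' @return A [ProbeTable-class] with attribute `truth`.
#' @export
simulateIntensities <- function(sequences, spec) {
  stopifnot(is(spec, "SimSpec"))
  set.seed(spec@rngSeed + 101L)
  S <- .encodeSeqs(sequences)
  n <- nrow(S)
  P <- ncol(S)
  gammas <- lapply(spec@modes, function(m)
    .gammaVector(spec@gammaProfile, P, motifLength(m), m@strandPolicy))
  total <- numeric(n)
  for (m in seq_along(spec@modes)) {
    E <- .viewAffinityMatrix(S, spec@modes[[m]])
    if (spec@saturating) {
      x <- sweep(E, 2L, spec@conc * gammas[[m]] * spec@relKa[m], "*") +
        exp(-spec@ddGns)
      total <- total + rowSums(x / (1 + x))
    } else {
      total <- total + spec@relKa[m] * drop(E %*% gammas[[m]])
    }
  }
  y0 <- spec@beta0 + spec@beta1 * total
  noiseSd <- spec@noiseSdFrac * stats::sd(y0)
  y <- y0 + if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
  nOut <- floor(spec@outlierFrac * n)
  outliers <- if (nOut > 0L) sample.int(n, nOut) else integer(0)
  y[outliers] <- y[outliers] * spec@outlierFactor
  pt <- ProbeTable(sequence = sequences, intensity = y)
  attr(pt, "truth") <- list(
    modes = spec@modes, relKa = spec@relKa, gamma = gammas,
    beta0 = spec@beta0, beta1 = spec@beta1, noiseSd = noiseSd,
    noiseless = y0, outliers = sort(outliers),
    planted = attr(sequences, "planted"),
    plantOffset = attr(sequences, "offset"),
    plantMode = attr(sequences, "mode"))
  pt
}

#' One-call synthetic PBM dataset
#'
#' @param spec A [SimSpec-class].
#' @return A [ProbeTable-class] with attribute `truth`; see
#'   [simulateIntensities()].
#' @export
#' @examples
#' probes <- simulatePBM(simSpec(nProbes = 100, rngSeed = 3))
#' probes
simulatePBM <- function(spec) simulateIntensities(makeProbes(spec), spec)

#' Generate a promoter + annotation fixture with a planted category
#'
#' Random promoter sequences for `nGenes` genes, `nCategories` annotation
#' categories of `categorySize` genes each; the genes of the planted
#' category (if any) receive `sitesPerGene` extra copies of the model's
#' reference site at random offsets.
#'
#' @param model A [FeatureModel-class] providing the planted site.
#' @param nGenes,promoterLen Number of genes and promoter length in bp.
#' @param nCategories,categorySize Annotation geometry.
#' @param plantedCategory Index of the category whose genes receive sites
#'   (0 = plant nothing).
#' @param sitesPerGene Planted sites per in-category gene.
#' @param rngSeed Seed for all randomness.
#' @return List with `promoters` (named character), `annotation`
#'   (data.frame `gene_id`, `category`) and `truth`.
#' @export
makeGenomeFixture <- function(model, nGenes = 500L, promoterLen = 600L,
                              nCategories = 10L, categorySize = 30L,
                              plantedCategory = 1L, sitesPerGene = 3L,
                              rngSeed = 1L) {
  set.seed(rngSeed)
  L <- motifLength(model)
  stopifnot(promoterLen >= L)
  genes <- sprintf("gene_%04d", seq_len(nGenes))
  mat <- matrix(sample.int(4L, nGenes * promoterLen, replace = TRUE),
                nGenes, promoterLen)
  annotation <- do.call(rbind, lapply(seq_len(nCategories), function(k)
    data.frame(gene_id = sample(genes, categorySize),
               category = sprintf("GO:%04d", k),
               stringsAsFactors = FALSE)))
  plantedGenes <- character(0)
  if (plantedCategory >= 1L) {
    cat <- sprintf("GO:%04d", plantedCategory)
    plantedGenes <- annotation$gene_id[annotation$category == cat]
    site <- match(strsplit(model@referenceSeq, "")[[1]], .BASES)
    for (g in match(plantedGenes, genes)) {
      offs <- sample.int(promoterLen - L + 1L, sitesPerGene)
      for (o in offs) mat[g, o:(o + L - 1L)] <- site
    }
  }
  promoters <- do.call(paste0,
                       as.data.frame(matrix(.BASES[mat], nGenes,
                                            promoterLen)))
  names(promoters) <- genes
  list(promoters = promoters, annotation = annotation,
       truth = list(plantedCategory = plantedCategory,
                    plantedGenes = plantedGenes,
                    sitesPerGene = sitesPerGene))
}
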