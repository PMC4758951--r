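## Post-fit structural refinement: palindrome detection and tying,
## motif-length selection by held-out R^2, and the poly-G/C strand rule.

#' Poly-G/C strand policy for a motif
#'
#' Stretches of four or more guanines interfere with PBM probe synthesis
#' and are replaced by their reverse complement in some array designs.
#' A motif containing four or more consecutive cytosines is therefore
#' scored on the positive strand only; one containing four or more
#' consecutive guanines on the negative strand only; anything else on both.
#'
#' @param x A seed/reference sequence or a [FeatureModel-class].
#' @return `"forward_only"`, `"reverse_only"` or `"both"`.
#' @export
#' @examples
#' polyGCStrandPolicy("ACCCCA")   # forward_only
#' polyGCStrandPolicy("AGGGGA")   # reverse_only
polyGCStrandPolicy <- function(x) {
  s <- if (is(x, "FeatureModel")) x@referenceSeq else toupper(x)
  if (grepl("CCCC", s)) "forward_only"
  else if (grepl("GGGG", s)) "reverse_only"
  else "both"
}

## reverse-complement a PSAM given as a 4 x L relative-affinity matrix
.revCompAffMatrix <- function(A) A[4:1, rev(seq_len(ncol(A))), drop = FALSE]

#' Detect palindromic (reverse-complement-symmetric) binding
#'
#' Fits a forward-strand-only PSAM and a reverse-strand-only PSAM from the
#' same seed, reverse-complements the latter, and compares the two on the
#' relative-affinity scale by the mean per-column L1 distance. Distances at
#' or below `config@palTol` flag the motif as palindromic.
#'
#' @param probes A [ProbeTable-class].
#' @param config A [FitConfig-class]; `knownSeed` is used if set, otherwise
#'   seed discovery runs once on both strands.
#' @return List with `symmetric` (logical), `distance` (mean per-column L1),
#'   and the two strand-specific [FitState-class] fits (`forward`,
#'   `reverse`).
#' @export
detectPalindrome <- function(probes, config = fitConfig()) {
  cfg <- config
  cfg@symmetry <- "off"
  cfg@growMotif <- FALSE
  cfg@includeDi <- FALSE
  if (is.na(cfg@knownSeed))
    cfg@knownSeed <- findSeed(probes, cfg@kSeed, cfg)$seed
  fwd <- .fitCore(probes, cfg, forcePolicy = "forward_only")
  rev <- .fitCore(probes, cfg, forcePolicy = "reverse_only")
  A1 <- exp(-fwd@model@monoDdG)
  A2 <- .revCompAffMatrix(exp(-rev@model@monoDdG))
  distance <- mean(colSums(abs(A1 - A2)))
  list(symmetric = distance <= config@palTol, distance = distance,
       forward = fwd, reverse = rev)
}

## all reverse-complement-symmetric K-mers within Hamming distance maxH of
## `seed` (even K: fully self-complementary; odd K: symmetric up to the
## centre base, which is free)
.symmetricSeedCandidates <- function(seed, maxH = 2L) {
  K <- nchar(seed)
  half <- K %/% 2L
  freeN <- half + (K %% 2L)
  grids <- rep(list(1:4), freeN)
  combos <- as.matrix(expand.grid(grids))
  sref <- match(strsplit(seed, "")[[1]], .BASES)
  out <- character(0)
  for (i in seq_len(nrow(combos))) {
    s <- integer(K)
    s[seq_len(freeN)] <- combos[i, ]
    if (half > 0L)
      s[K + 1L - seq_len(half)] <- 5L - s[seq_len(half)]
    if (sum(s != sref) <= maxH)
      out <- c(out, paste(.BASES[s], collapse = ""))
  }
  out
}

#' Tie a fitted model to exact palindromic symmetry
#'
#' Re-seeds with the highest-affinity symmetric K-mer near the current seed
#' (within Hamming distance 2) and refits the PSAM with parameters tied so
#' that `ddG(pos, base) == ddG(L-1-pos, complement(base))`; the resulting
#' model satisfies `affinity(S) == affinity(revcomp(S))` exactly and uses
#' half the free parameters. For odd motif lengths the centre column is left
#' untied. If no symmetric seed exists within Hamming distance 2, a warning
#' is raised and the untied state returned.
#'
#' @param state A converged [FitState-class].
#' @param probes The [ProbeTable-class] the state was fitted on.
#' @param config A [FitConfig-class].
#' @return A [FitState-class] with a symmetric (tied) model.
#' @export
symmetrize <- function(state, probes, config = state@config) {
  seed <- state@model@referenceSeq
  cands <- .symmetricSeedCandidates(seed, 2L)
  if (length(cands) == 0L) {
    warning("no symmetric seed within Hamming distance 2; ",
            "returning the untied model")
    return(state)
  }
  aff <- relativeAffinity(cands, state@model)
  symSeed <- cands[which.max(aff)]
  cfg <- config
  cfg@knownSeed <- symSeed
  cfg@symmetry <- "off"
  cfg@growMotif <- FALSE
  .fitCore(probes, cfg, tie = TRUE)
}

#' Select the motif length by held-out R-squared
#'
#' Greedily grows the binding window one column at a time on each side,
#' refitting after every growth, and keeps a growth step iff the R-squared
#' on a held-out probe split increases; growth stops at the first decrease
#' on both sides (held-out data avoid the guaranteed training-R^2 increase
#' of nested models). Growth past the probe boundary is refused.
#'
#' @param probes A [ProbeTable-class].
#' @param state A converged [FitState-class] at the initial length.
#' @param config A [FitConfig-class]; `heldOutFrac` and `rngSeed` control
#'   the split.
#' @return A [FitState-class] refitted on all probes at the selected
#'   length.
#' @export
selectMotifLength <- function(probes, state, config = state@config) {
  set.seed(config@rngSeed + 7L)
  n <- length(probes)
  hold <- sample.int(n, max(1L, round(config@heldOutFrac * n)))
  train <- probes[-hold]
  test <- probes[hold]
  plen <- probeLength(probes)

  fitRef <- function(refSeq) {
    cfg <- config
    cfg@knownSeed <- refSeq
    cfg@growMotif <- FALSE
    cfg@symmetry <- "off"
    st <- .fitCore(train, cfg)
    list(state = st, r2 = .r2(test@intensity, predict(st, test)))
  }

  cur <- fitRef(state@model@referenceSeq)
  stopLeft <- stopRight <- FALSE
  while (!(stopLeft && stopRight)) {
    ref <- cur$state@model@referenceSeq
    if (!stopLeft) {
      if (nchar(ref) + 1L > plen) {
        message("motif would exceed the probe length; left growth stopped")
        stopLeft <- TRUE
      } else {
        ## provisional base; block refitting re-anchors to the best base
        cand <- fitRef(paste0("A", ref))
        if (cand$r2 > cur$r2) cur <- cand else stopLeft <- TRUE
      }
    }
    ref <- cur$state@model@referenceSeq
    if (!stopRight) {
      if (nchar(ref) + 1L > plen) {
        message("motif would exceed the probe length; right growth stopped")
        stopRight <- TRUE
      } else {
        cand <- fitRef(paste0(ref, "A"))
        if (cand$r2 > cur$r2) cur <- cand else stopRight <- TRUE
      }
    }
  }
  cfg <- config
  cfg@knownSeed <- cur$state@model@referenceSeq
  cfg@growMotif <- FALSE
  cfg@symmetry <- "off"
  .fitCore(probes, cfg)
}
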