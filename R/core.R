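## Core free-energy model: view enumeration, feature extraction, ddG/RT
## sums, relative affinities, and the forward intensity prediction.
## Coordinates are 0-based half-open in all user-facing output; internal
## code uses 1-based offsets on integer-encoded sequences.

.viewTable <- function(probeLen, L, strandPolicy = "both") {
  if (L > probeLen) stop("motif longer than probe")
  W <- probeLen - L + 1L
  off <- seq_len(W) - 1L
  switch(strandPolicy,
    both = data.frame(offset = c(off, off),
                      strand = rep(c("+", "-"), each = W),
                      stringsAsFactors = FALSE),
    forward_only = data.frame(offset = off, strand = rep("+", W),
                              stringsAsFactors = FALSE),
    reverse_only = data.frame(offset = off, strand = rep("-", W),
                              stringsAsFactors = FALSE),
    stop("unknown strand policy: ", strandPolicy))
}

.nViews <- function(probeLen, L, strandPolicy = "both") {
  nrow(.viewTable(probeLen, L, strandPolicy))
}

#' Enumerate binding-site views on a probe
#'
#' A view is one possible placement of the length-L binding window on a
#' probe: an offset combined with a strand. A reverse-strand view at offset
#' `o` is the reverse complement of the forward window at the same offset,
#' so the number of views is `2 * (probe length - L + 1)` when both strands
#' are scanned. Views are ordered all forward then all reverse, by ascending
#' offset; offsets are 0-based.
#'
#' @param probeSeq A single DNA string.
#' @param L Motif window length.
#' @param strandPolicy `"both"` (default), `"forward_only"` or
#'   `"reverse_only"`.
#' @return A data.frame with columns `offset` (0-based), `strand` (`"+"` or
#'   `"-"`) and `window` (the length-L window sequence).
#' @export
#' @examples
#' enumerateViews("ACGTA", 4)
enumerateViews <- function(probeSeq, L, strandPolicy = "both") {
  stopifnot(length(probeSeq) == 1L)
  probeSeq <- toupper(probeSeq)
  .checkDNA(probeSeq, "probe sequence")
  vt <- .viewTable(nchar(probeSeq), L, strandPolicy)
  fwd <- substring(probeSeq, vt$offset + 1L, vt$offset + L)
  vt$window <- ifelse(vt$strand == "+", fwd, revComp(fwd))
  vt
}

#' Sequence features of a binding window
#'
#' Decomposes a length-L window into its mononucleotide features (one per
#' position) and, optionally, its adjacent-dinucleotide features (one per
#' pair of neighbouring positions).
#'
#' @param window A single DNA string of length L.
#' @param includeDi Also return the L-1 dinucleotide features?
#' @return A data.frame with columns `order` (`"mono"`/`"di"`), `position`
#'   (0-based within the window) and `bases`.
#' @export
#' @examples
#' featuresOf("ACG", includeDi = TRUE)
featuresOf <- function(window, includeDi = FALSE) {
  stopifnot(length(window) == 1L)
  window <- toupper(window)
  .checkDNA(window, "window")
  L <- nchar(window)
  ch <- strsplit(window, "")[[1]]
  out <- data.frame(order = rep("mono", L), position = seq_len(L) - 1L,
                    bases = ch, stringsAsFactors = FALSE)
  if (includeDi && L >= 2L) {
    di <- data.frame(order = rep("di", L - 1L), position = seq_len(L - 1L) - 1L,
                     bases = paste0(ch[-L], ch[-1]), stringsAsFactors = FALSE)
    out <- rbind(out, di)
  }
  out
}

#' Binding free energy of a window under a model
#'
#' Sums the model's ddG/RT contributions over the features present in the
#' window: L mononucleotide features plus, if the model carries dinucleotide
#' blocks, L-1 adjacent-dinucleotide features. All free energies are
#' dimensionless (already divided by RT).
#'
#' @param window DNA string(s) of length equal to the model's motif length.
#' @param model A [FeatureModel-class].
#' @return Numeric vector of ddG/RT values.
#' @export
#' @examples
#' m <- featureModel("AC", monoDdG = rbind(c(0, 0.5), c(1, 0),
#'                                         c(2, 1.5), c(3, 2.5)))
#' windowDdG("GC", m)  # 2.0
windowDdG <- function(window, model) {
  L <- motifLength(model)
  if (any(nchar(window) != L))
    stop("window length must equal the model motif length (", L, ")")
  S <- .encodeSeqs(toupper(window))
  .viewDdGForWindows(S, model)
}

## ddG/RT for windows given as an n x L integer matrix (forward orientation)
.viewDdGForWindows <- function(S, model) {
  L <- ncol(S)
  M <- model@monoDdG
  acc <- numeric(nrow(S))
  for (j in seq_len(L)) acc <- acc + M[(j - 1L) * 4L + S[, j]]
  if (ncol(model@diDdG)) {
    D <- model@diDdG
    for (j in seq_len(L - 1L))
      acc <- acc + D[(j - 1L) * 16L + (S[, j] - 1L) * 4L + S[, j + 1L]]
  }
  acc
}

#' Relative binding affinity of a window
#'
#' `Ka(S) / Ka(Sref) = exp(-ddG(S)/RT)`; equals 1 for the reference window
#' of a mononucleotide-only model.
#'
#' @inheritParams windowDdG
#' @return Numeric vector of relative affinities in (0, Inf).
#' @export
#' @examples
#' m <- featureModel("CACGTG", offRef = 1)
#' relativeAffinity("CACGTG", m)  # 1
relativeAffinity <- function(window, model) exp(-windowDdG(window, model))

## ddG/RT matrix over all views: n probes x nViews.
## S: n x probeLen integer matrix. Columns follow .viewTable() order.
.viewDdGMatrix <- function(S, model) {
  L <- motifLength(model)
  P <- ncol(S)
  if (L > P) stop("motif longer than probe")
  W <- P - L + 1L
  M <- model@monoDdG
  hasDi <- ncol(model@diDdG) > 0L
  D <- model@diDdG
  pol <- model@strandPolicy
  doF <- pol %in% c("both", "forward_only")
  doR <- pol %in% c("both", "reverse_only")
  nv <- (doF + doR) * W
  out <- matrix(0, nrow(S), nv)
  col <- 0L
  if (doF) {
    for (o in seq_len(W)) {
      acc <- numeric(nrow(S))
      bprev <- NULL
      for (j in seq_len(L)) {
        b <- S[, o + j - 1L]
        acc <- acc + M[(j - 1L) * 4L + b]
        if (hasDi && j > 1L)
          acc <- acc + D[(j - 2L) * 16L + (bprev - 1L) * 4L + b]
        bprev <- b
      }
      col <- col + 1L
      out[, col] <- acc
    }
  }
  if (doR) {
    for (o in seq_len(W)) {
      acc <- numeric(nrow(S))
      bprev <- NULL
      for (j in seq_len(L)) {
        b <- 5L - S[, o + L - j]       # complement, reversed
        acc <- acc + M[(j - 1L) * 4L + b]
        if (hasDi && j > 1L)
          acc <- acc + D[(j - 2L) * 16L + (bprev - 1L) * 4L + b]
        bprev <- b
      }
      col <- col + 1L
      out[, col] <- acc
    }
  }
  out
}

## exp(-ddG) over all views
.viewAffinityMatrix <- function(S, model) exp(-.viewDdGMatrix(S, model))

## base identity (1..4) at window position j for every view: n x nViews
.viewBaseMatrix <- function(S, L, j, strandPolicy = "both") {
  P <- ncol(S)
  W <- P - L + 1L
  doF <- strandPolicy %in% c("both", "forward_only")
  doR <- strandPolicy %in% c("both", "reverse_only")
  out <- matrix(0L, nrow(S), (doF + doR) * W)
  col <- 0L
  if (doF) for (o in seq_len(W)) {
    col <- col + 1L
    out[, col] <- S[, o + j - 1L]
  }
  if (doR) for (o in seq_len(W)) {
    col <- col + 1L
    out[, col] <- 5L - S[, o + L - j]
  }
  out
}

## dinucleotide level (1..16) at window positions (j, j+1) for every view
.viewDiMatrix <- function(S, L, j, strandPolicy = "both") {
  b1 <- .viewBaseMatrix(S, L, j, strandPolicy)
  b2 <- .viewBaseMatrix(S, L, j + 1L, strandPolicy)
  (b1 - 1L) * 4L + b2
}

#' Predict probe intensity from sequence
#'
#' Forward model of PBM fluorescence. In the linear regime the intensity is
#' `beta0 + beta1 * sum_v gamma_v exp(-ddG(S_v)/RT)` over all views v of the
#' probe. In the saturating occupancy form each view contributes
#' `x_v / (1 + x_v)` with `x_v = conc * gamma_v exp(-ddG(S_v)/RT) +
#' exp(-ddG_ns/RT)`, which bounds every view's contribution by 1; `conc`
#' is the free-protein concentration scale.
#'
#' @param probeSeq Character vector of probe sequences (equal length).
#' @param model A [FeatureModel-class].
#' @param bias A [PositionalBias-class] matching the probe geometry and the
#'   model's strand policy.
#' @param im An [IntensityModel-class].
#' @return Numeric vector of predicted intensities.
#' @export
#' @examples
#' m <- featureModel("CACGTG", offRef = 2)
#' b <- positionalBias(rep(1, 2 * (10 - 6 + 1)), 10, 6)
#' predictIntensity("AACACGTGAA", m, b, intensityModel(beta0 = 1, beta1 = 10))
predictIntensity <- function(probeSeq, model, bias, im = intensityModel()) {
  S <- .encodeSeqs(toupper(probeSeq))
  E <- .viewAffinityMatrix(S, model)
  if (length(bias@gamma) != ncol(E) ||
      bias@strandPolicy != model@strandPolicy)
    stop("positional bias does not match the probe/model view geometry")
  .predictFromE(E, bias@gamma, im)
}

.predictFromE <- function(E, gamma, im) {
  if (im@saturating) {
    x <- sweep(E, 2L, im@conc * gamma, "*") + exp(-im@ddGns)
    im@beta0 + im@beta1 * rowSums(x / (1 + x))
  } else {
    drop(im@beta0 + im@beta1 * (E %*% gamma))
  }
}

#' Per-offset slope of a positional bias profile
#'
#' Linear-regression slope of gamma against offset (forward views, or all
#' views averaged over strands), a simple data-quality diagnostic: on
#' high-quality arrays the profile typically trends away from the substrate.
#'
#' @param bias A [PositionalBias-class].
#' @return Numeric slope per offset step.
#' @export
biasSlope <- function(bias) {
  W <- bias@probeLength - bias@motifLength + 1L
  g <- if (bias@strandPolicy == "both")
    (bias@gamma[seq_len(W)] + bias@gamma[W + seq_len(W)]) / 2
  else bias@gamma
  unname(stats::coef(stats::lm.fit(cbind(1, seq_len(W) - 1L), g))[2])
}
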