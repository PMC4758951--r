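## Seed discovery: robust trimmed-mean iterative estimation of per-K-mer
## affinity coefficients. Probe intensities are modeled as
## y(S) = sum_m beta_m X_m(S), where X_m(S) counts occurrences of oligomer m
## on both strands of probe S. The K-mer with the highest converged
## coefficient becomes the seed / reference sequence.

#' Count K-mer occurrences on both strands
#'
#' Counts occurrences of every K-mer in the forward sequence plus
#' occurrences in its reverse complement (each strand scanned at all
#' offsets; overlapping occurrences counted), as used in the seed-discovery
#' regression.
#'
#' @param probeSeq A single DNA string.
#' @param K Oligomer length.
#' @return Named integer vector of counts (only K-mers that occur).
#' @export
#' @examples
#' countKmers("AAAA", 2)  # AA: 3, TT: 3
#' countKmers("ACGT", 4)  # ACGT: 2 (self-reverse-complementary)
countKmers <- function(probeSeq, K) {
  stopifnot(length(probeSeq) == 1L)
  probeSeq <- toupper(probeSeq)
  .checkDNA(probeSeq, "probe sequence")
  n <- nchar(probeSeq)
  if (K > n) stop("K exceeds the probe length")
  starts <- seq_len(n - K + 1L)
  f <- substring(probeSeq, starts, starts + K - 1L)
  r <- substring(revComp(probeSeq), starts, starts + K - 1L)
  tab <- table(c(f, r))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Exact per-probe coefficient for one oligomer
#'
#' The coefficient value that makes the K-mer count model reproduce this
#' probe's intensity exactly, holding all other coefficients fixed:
#' `(y - sum_{m' != m} beta_m' X_m') / X_m`.
#'
#' @param y Measured intensity of the probe.
#' @param counts Named integer vector of the probe's K-mer counts (e.g. from
#'   [countKmers()]).
#' @param m The oligomer whose coefficient is solved for.
#' @param beta Named numeric vector of current coefficients; oligomers
#'   absent from `beta` count as 0.
#' @return The exact coefficient.
#' @export
#' @examples
#' exactCoefficient(10, c(AA = 2), "AA", c(AA = 0))  # 5
exactCoefficient <- function(y, counts, m, beta) {
  xm <- counts[m]
  if (is.na(xm) || xm == 0) stop("feature absent from probe")
  others <- setdiff(names(counts), m)
  b <- beta[others]
  b[is.na(b)] <- 0
  unname((y - sum(b * counts[others])) / xm)
}

#' Trimmed mean
#'
#' Mean of the values remaining after removing the `floor(trim * n)`
#' smallest and `floor(trim * n)` largest values.
#'
#' @param values Non-empty numeric vector.
#' @param trimFrac Trim fraction in `[0, 0.5)`.
#' @return The trimmed mean.
#' @export
#' @examples
#' trimmedMean(1:10, 0.15)  # 5.5
trimmedMean <- function(values, trimFrac = 0.15) {
  if (length(values) == 0L) stop("cannot take the trimmed mean of no values")
  if (trimFrac < 0 || trimFrac >= 0.5) stop("trimFrac must be in [0, 0.5)")
  k <- floor(trimFrac * length(values))
  s <- sort(values)
  mean(s[seq.int(k + 1L, length(values) - k)])
}

## --- internal machinery -----------------------------------------------

## K-mer instance triplets for a probe set: for every probe, the integer
## codes of all forward-strand and reverse-complement-strand K-mers.
## Returns list(probe = int, code = int (0-based), count = int) aggregated
## over duplicates within a probe.
.kmerTriplets <- function(S, K) {
  n <- nrow(S)
  P <- ncol(S)
  W <- P - K + 1L
  pw <- 4^(K - seq_len(K))            # positional weights, MSB first
  codes <- matrix(0, n, 2L * W)
  for (o in seq_len(W)) {
    accF <- numeric(n)
    accR <- numeric(n)
    for (j in seq_len(K)) {
      accF <- accF + (S[, o + j - 1L] - 1L) * pw[j]
      accR <- accR + (4L - S[, o + K - j]) * pw[j]
    }
    codes[, o] <- accF
    codes[, W + o] <- accR
  }
  probe <- rep(seq_len(n), times = 2L * W)
  code <- as.vector(codes)
  key <- (probe - 1) * 4^K + code
  o <- order(key)
  key <- key[o]
  runEnds <- c(which(diff(key) != 0), length(key))
  runStarts <- c(1L, head(runEnds, -1L) + 1L)
  list(probe = as.integer((key[runStarts]) %/% 4^K) + 1L,
       code = key[runStarts] %% 4^K,
       count = as.integer(runEnds - runStarts + 1L))
}

## membership of `codes` in the sequence family of `refCode`: alignable to
## the reference K-mer (either strand) at a relative shift of at most 3
## with at most (overlap - (K - 3)) mismatches
.kmerFamily <- function(refCode, codes, K) {
  toMat <- function(cd) {
    out <- matrix(0L, length(cd), K)
    rem <- cd
    for (j in K:1) {
      out[, j] <- as.integer(rem %% 4)
      rem <- rem %/% 4
    }
    out
  }
  Mx <- toMat(codes)
  refs <- toMat(refCode)
  refRc <- rev(3L - refs[1, ])
  hit <- rep(FALSE, length(codes))
  for (ref in list(refs[1, ], refRc)) {
    for (sft in -3:3) {
      jr <- seq_len(K)[seq_len(K) + sft >= 1 & seq_len(K) + sft <= K]
      jm <- jr + sft
      matches <- rowSums(Mx[, jm, drop = FALSE] ==
                         matrix(ref[jr], length(codes), length(jr),
                                byrow = TRUE))
      hit <- hit | matches >= K - 3L
    }
  }
  hit
}

.decodeKmer <- function(code, K) {
  out <- character(length(code))
  idx <- matrix(0L, length(code), K)
  rem <- code
  for (j in K:1) {
    idx[, j] <- rem %% 4
    rem <- rem %/% 4
  }
  apply(idx, 1L, function(r) paste(.BASES[r + 1L], collapse = ""))
}

#' Discover the seed K-mer by robust trimmed-mean iteration
#'
#' Fits probe intensities as a weighted sum of two-strand K-mer counts.
#' All coefficients start at 1e-4 (representative of non-specific binding).
#' Each iteration computes, for every oligomer m and every probe containing
#' it, the exact per-probe coefficient, takes the trimmed mean across those
#' probes (removing the top and bottom `seedTrimFrac` of values), clips
#' negative trimmed means to zero, and moves each coefficient a step
#' `alpha` towards its trimmed mean. Iteration stops when the largest
#' coefficient change, relative to the largest coefficient, falls below
#' `seedTol`, or after `seedMaxIter` iterations. The oligomer with the
#' highest coefficient is the seed; it is merged with its reverse
#' complement, ties broken lexicographically.
#'
#' @param probes A [ProbeTable-class].
#' @param K Oligomer length (defaults to `config@kSeed`).
#' @param config A [FitConfig-class].
#' @return List with `seed` (canonical K-mer string), `beta` (named vector
#'   of converged coefficients for all observed K-mers), `iterations`,
#'   `converged`.
#' @export
findSeed <- function(probes, K = config@kSeed, config = fitConfig()) {
  stopifnot(is(probes, "ProbeTable"))
  S <- .encodeSeqs(probes@sequence)
  if (K > ncol(S)) stop("K exceeds the probe length")
  y <- probes@intensity
  tr <- .kmerTriplets(S, K)
  grp <- match(tr$code, sort(unique(tr$code)))   # 1..G group index
  codes <- sort(unique(tr$code))
  G <- length(codes)
  n <- nrow(S)

  ## fixed grouped-structure bookkeeping (order within groups changes with
  ## the residuals, so re-sorted every iteration)
  gsize <- tabulate(grp, G)
  kTrim <- floor(config@seedTrimFrac * gsize)
  keepN <- gsize - 2L * kTrim

  ## Only oligomers observed in enough probes for the trimmed mean to trim
  ## at least one value per tail are iterated; the rest keep the
  ## non-specific initialisation. A "trimmed" mean over a handful of values
  ## trims nothing and is not robust, and letting such oligomers compete
  ## for credit injects per-probe noise into the well-supported estimates.
  updatable <- kTrim >= 1L

  beta <- rep(1e-4, G)
  it <- 0L
  converged <- FALSE
  x <- tr$count
  pid <- tr$probe
  while (it < config@seedMaxIter) {
    it <- it + 1L
    yhat <- drop(rowsum(x * beta[grp], pid, reorder = TRUE))
    r <- y - yhat
    val <- beta[grp] + r[pid] / x
    o <- order(grp, val)
    vs <- val[o]
    cs0 <- c(0, cumsum(vs))
    ends <- cumsum(gsize)
    starts <- ends - gsize + 1L
    hi <- ends - kTrim
    lo <- starts + kTrim
    tm <- (cs0[hi + 1L] - cs0[lo]) / keepN
    tm <- pmax(tm, 0)
    betaNew <- beta
    betaNew[updatable] <- (1 - config@alpha) * beta[updatable] +
      config@alpha * tm[updatable]
    delta <- max(abs(betaNew - beta)) / max(betaNew, 1e-300)
    beta <- betaNew
    if (delta < config@seedTol) {
      converged <- TRUE
      break
    }
  }
  ## Seed selection. Oligomers overlapping the true site share most of
  ## their probes with it and acquire coefficients statistically
  ## indistinguishable from (sometimes exceeding) the site's, so the raw
  ## argmax is unstable within that family. The argmax is therefore
  ## (1) restricted to oligomers with enough probe support to estimate a
  ## trimmed mean, and (2) re-resolved within the sequence family of the
  ## raw winner: among family members whose support is at least
  ## seedSupportFrac of the family maximum, the highest coefficient wins.
  ## When supports are comparable (context-randomised designs) this is the
  ## plain argmax; when one oligomer dominates the family's support (a
  ## concentrated binding site) that oligomer is preferred over its
  ## sliding-window shadows.
  support <- gsize
  minSupp <- min(config@seedMinSupport, max(support))
  elig <- which(support >= minSupp)
  rawBest <- elig[which.max(beta[elig])]
  fam <- elig[.kmerFamily(codes[rawBest], codes[elig], K)]
  fam <- fam[support[fam] >= config@seedSupportFrac * max(support[fam])]
  best <- fam[which.max(beta[fam])]
  seed <- .decodeKmer(codes[best], K)
  seed <- min(seed, revComp(seed))   # merge with reverse complement
  names(beta) <- names(support) <- .decodeKmer(codes, K)
  list(seed = seed, beta = beta, support = support, iterations = it,
       converged = converged)
}
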