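## Shared fixtures and independent oracles. The brute-force predictor walks
## every substring and its reverse complement with featuresOf(), staying
## independent of the vectorised view machinery it checks.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

## tiny two-position model used by several ddG examples
tinyModel <- function(withDi = FALSE) {
  M <- rbind(A = c(0, 0.5), C = c(1, 0), G = c(2, 1.5), T = c(3, 2.5))
  D <- NULL
  if (withDi) {
    D <- matrix(0, 16, 1)
    rownames(D) <- paste0(rep(BASES, each = 4), rep(BASES, 4))
    D["GA", 1] <- 0.7
  }
  featureModel("AC", M, diDdG = D)
}

## random anchored model with optional dinucleotide block
randModel <- function(L, withDi = FALSE) {
  ref <- randSeq(L)
  M <- matrix(runif(4 * L, 0, 3), 4, L)
  refb <- match(strsplit(ref, "")[[1]], BASES)
  for (j in seq_len(L)) M[, j] <- M[, j] - M[refb[j], j]
  D <- if (withDi) matrix(runif(16 * (L - 1), -0.5, 0.5), 16, L - 1)
  featureModel(ref, M, diDdG = D)
}

## brute-force intensity prediction via featuresOf/enumerateViews
bruteIntensity <- function(probeSeq, model, gamma, im) {
  vapply(probeSeq, function(s) {
    vt <- enumerateViews(s, motifLength(model), strandPolicy(model))
    aff <- vapply(vt$window, function(w) {
      f <- featuresOf(w, includeDi = !is.null(diDdG(model)))
      tot <- 0
      for (i in seq_len(nrow(f))) {
        tot <- tot + if (f$order[i] == "mono")
          monoDdG(model)[f$bases[i], f$position[i] + 1]
        else diDdG(model)[f$bases[i], f$position[i] + 1]
      }
      exp(-tot)
    }, numeric(1))
    if (im@saturating) {
      x <- im@conc * gamma * aff + exp(-im@ddGns)
      im@beta0 + im@beta1 * sum(x / (1 + x))
    } else {
      im@beta0 + im@beta1 * sum(gamma * aff)
    }
  }, numeric(1))
}

## exact rank-sum tail probability by enumeration: probability that a random
## size-m subset of ranks 1..N has rank-sum at least as extreme as observed
exactRankSumP <- function(inVals, outVals) {
  N <- length(inVals) + length(outVals)
  m <- length(inVals)
  combs <- utils::combn(N, m)
  r <- rank(c(inVals, outVals))
  obs <- sum(r[seq_len(m)])
  sums <- colSums(matrix(seq_len(N)[combs], nrow = m))
  mean(sums >= obs)
}
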