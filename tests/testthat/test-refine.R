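test_that("the poly-G/C rule restricts the scanned strand", {
  expect_equal(polyGCStrandPolicy("ACCCCA"), "forward_only")
  expect_equal(polyGCStrandPolicy("AGGGGA"), "reverse_only")
  expect_equal(polyGCStrandPolicy("ACGTACGT"), "both")
  expect_equal(polyGCStrandPolicy(featureModel("TTGGGGTT")), "reverse_only")
})

test_that("palindromic truth is detected and tied exactly", {
  spec <- simSpec(nProbes = 1000,
                  modes = list(defaultTruthModel("palindromic")),
                  rngSeed = 71)
  pt <- simulatePBM(spec)
  cfg <- fitConfig(knownSeed = "TCACGTGA", rngSeed = 3)
  dp <- detectPalindrome(pt, cfg)
  expect_true(dp$symmetric)
  expect_lt(dp$distance, 0.1)

  st <- fitModel(pt, cfg)
  sy <- symmetrize(st, pt, cfg)
  m <- fittedModel(sy)
  expect_true(isPalindromic(m))
  ## exact reverse-complement symmetry on 1,000 random windows
  set.seed(8)
  w <- vapply(1:1000, function(i) randSeq(8), "")
  expect_equal(relativeAffinity(w, m), relativeAffinity(revComp(w), m),
               tolerance = 1e-12)
  ## tying halves the number of free mono parameters
  A <- monoDdG(m)
  tied <- A[, 1:4]
  mirrored <- A[4:1, 8:5]
  expect_equal(tied, mirrored, ignore_attr = TRUE)
  ## symmetrised fit at least as close to the symmetric truth
  truthM <- monoDdG(attr(pt, "truth")$modes[[1]])
  rmse <- function(M) sqrt(mean((M - truthM)^2))
  expect_lte(rmse(monoDdG(fittedModel(sy))),
             rmse(monoDdG(fittedModel(st))) + 0.02)
})

test_that("asymmetric truth is not flagged palindromic", {
  spec <- simSpec(nProbes = 1000, rngSeed = 72)
  pt <- simulatePBM(spec)
  dp <- detectPalindrome(pt, fitConfig(knownSeed = "AGGATAAG", rngSeed = 3))
  expect_false(dp$symmetric)
  expect_gt(dp$distance, 0.5)
  ## a zero tolerance can never declare symmetry on noisy data
  cfg0 <- fitConfig(knownSeed = "TCACGTGA", rngSeed = 3, palTol = 0)
  specP <- simSpec(nProbes = 1000,
                   modes = list(defaultTruthModel("palindromic")),
                   rngSeed = 73)
  dp0 <- detectPalindrome(simulatePBM(specP), cfg0)
  expect_false(dp0$symmetric)
})

test_that("symmetric seed candidates respect the Hamming constraint", {
  cands <- psamfit:::.symmetricSeedCandidates("TCACGTGA", 2L)
  expect_true("TCACGTGA" %in% cands)
  expect_true(all(cands == revComp(cands)))
  hd <- vapply(strsplit(cands, ""), function(x)
    sum(x != strsplit("TCACGTGA", "")[[1]]), 1L)
  expect_true(all(hd <= 2))
  ## no symmetric seed near a strongly asymmetric reference -> warning
  st <- new("FitState", model = featureModel("AAATAAA", offRef = 2),
            bias = .flatBias(20L, 7L), im = intensityModel(),
            weights = rep(1, 10), betaPsam = 1, r2Train = 0,
            config = fitConfig(), details = list())
  expect_warning(out <- symmetrize(st, ProbeTable(
    sequence = replicate(10, randSeq(20)), intensity = runif(10))),
    "no symmetric seed")
  expect_identical(fittedModel(out)@referenceSeq, "AAATAAA")
})

test_that("growth at the probe boundary is refused", {
  spec <- simSpec(nProbes = 300, probeLen = 8L, plantFrac = 0.6,
                  rngSeed = 74)
  pt <- simulatePBM(spec)
  st <- fitModel(pt, fitConfig(knownSeed = "AGGATAAG", rngSeed = 3,
                               maxOuterRounds = 2L))
  expect_message(
    selectMotifLength(pt, st, fitConfig(knownSeed = "AGGATAAG", rngSeed = 3,
                                        maxOuterRounds = 1L,
                                        maxBlockPasses = 2L)),
    "probe length")
})
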