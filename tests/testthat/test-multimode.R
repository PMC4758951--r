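test_that("a single-mode request reduces to the standard fit", {
  pt <- simulatePBM(simSpec(nProbes = 600, rngSeed = 101))
  cfg <- fitConfig(knownSeed = "AGGATAAG", rngSeed = 5)
  ms <- fitMultiMode(pt, cfg, maxModes = 1L)
  st <- fitModel(pt, cfg)
  expect_equal(length(ms), 1L)
  expect_equal(relKa(ms), 1)
  expect_equal(monoDdG(bindingModes(ms)[[1]]), monoDdG(fittedModel(st)),
               tolerance = 1e-10)
})

test_that("mode-set predictions are the sum of per-mode contributions", {
  m1 <- defaultTruthModel("overlap")
  m2 <- defaultTruthModel("nonoverlap")
  b1 <- .flatBias(30L, 8L)
  ms <- new("BindingModeSet", modes = list(m1, m2), relKa = c(1, 0.3),
            modePvalues = c(NA_real_, NA_real_),
            im = intensityModel(beta0 = 10, beta1 = 100),
            biases = list(b1, b1), details = list())
  set.seed(41)
  seqs <- vapply(1:25, function(i) randSeq(30), "")
  im0 <- intensityModel(0, 1)
  manual <- 10 + 100 * (
    bruteIntensity(seqs, m1, b1@gamma, im0) +
    0.3 * bruteIntensity(seqs, m2, b1@gamma, im0))
  expect_equal(unname(predict(ms, seqs)), unname(manual), tolerance = 1e-10)
})

test_that("the dominant mode follows rel_Ka times best-view affinity", {
  m1 <- defaultTruthModel("overlap")      # ATGACTCA
  m2 <- defaultTruthModel("nonoverlap")   # TGACGTCA
  b <- .flatBias(30L, 8L)
  ms <- new("BindingModeSet", modes = list(m1, m2), relKa = c(1, 0.25),
            modePvalues = c(NA_real_, NA_real_), im = intensityModel(),
            biases = list(b, b), details = list())
  expect_equal(dominantMode(paste0(referenceSeq(m1), "TTTTTT"), ms), 1L)
  expect_equal(dominantMode(paste0(referenceSeq(m2), "TTTTTT"), ms), 2L)
  ## ties return the lowest index: identical modes
  msT <- new("BindingModeSet", modes = list(m1, m1), relKa = c(1, 1),
             modePvalues = c(NA_real_, NA_real_), im = intensityModel(),
             biases = list(b, b), details = list())
  expect_equal(dominantMode(referenceSeq(m1), msT), 1L)
  expect_error(dominantMode("ACGT", ms), "shorter")
})

test_that("single-mode truth drops the spurious second mode", {
  pt <- simulatePBM(simSpec(nProbes = 1000, rngSeed = 102))
  suppressMessages(
    ms <- fitMultiMode(pt, fitConfig(rngSeed = 5, maxModes = 2L)))
  expect_equal(length(ms), 1L)
})
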