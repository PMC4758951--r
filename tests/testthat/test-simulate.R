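test_that("the generator is reproducible under a fixed seed", {
  spec <- simSpec(nProbes = 200, rngSeed = 81)
  p1 <- simulatePBM(spec)
  p2 <- simulatePBM(spec)
  expect_identical(sequences(p1), sequences(p2))
  expect_identical(intensities(p1), intensities(p2))
})

test_that("planting honours the requested fraction and offsets", {
  spec <- simSpec(nProbes = 300, plantFrac = 1, plantOffsets = 5L,
                  mutationRate = 0, rngSeed = 82)
  seqs <- makeProbes(spec)
  ref <- referenceSeq(defaultTruthModel("asymmetric"))
  hasSite <- vapply(seqs, function(s) {
    w <- substring(s, 6, 13)
    w == ref || w == revComp(ref)
  }, TRUE)
  expect_true(all(hasSite))
  expect_true(all(attr(seqs, "planted")))
  expect_true(all(attr(seqs, "offset") == 5L))
})

test_that("random probe composition is approximately uniform", {
  spec <- simSpec(nProbes = 4000, probeLen = 25L, plantFrac = 0,
                  rngSeed = 83)
  seqs <- makeProbes(spec)
  counts <- table(strsplit(paste(seqs, collapse = ""), "")[[1]])
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("noiseless intensities equal the brute-force forward model", {
  spec <- simSpec(nProbes = 30, noiseSdFrac = 0, rngSeed = 84)
  pt <- simulatePBM(spec)
  truth <- attr(pt, "truth")
  im <- intensityModel(truth$beta0, truth$beta1)
  y0 <- bruteIntensity(sequences(pt), truth$modes[[1]], truth$gamma[[1]], im)
  expect_equal(unname(intensities(pt)), unname(y0), tolerance = 1e-10)
})

test_that("outlier flags count exactly floor(frac * n)", {
  spec <- simSpec(nProbes = 1000, outlierFrac = 0.1, rngSeed = 85)
  pt <- simulatePBM(spec)
  truth <- attr(pt, "truth")
  expect_length(truth$outliers, 100L)
  ## the flagged probes are exactly the multiplied ones
  spec0 <- simSpec(nProbes = 1000, outlierFrac = 0, rngSeed = 85)
  pt0 <- simulatePBM(spec0)
  ratio <- intensities(pt) / intensities(pt0)
  expect_equal(sort(which(abs(ratio - 10) < 1e-9)), truth$outliers)
})

test_that("the genome fixture plants extra sites in one category", {
  m <- defaultTruthModel("asymmetric")
  fx <- makeGenomeFixture(m, nGenes = 60, promoterLen = 200,
                          nCategories = 3, categorySize = 10,
                          plantedCategory = 1, sitesPerGene = 3,
                          rngSeed = 86)
  expect_length(fx$promoters, 60L)
  expect_equal(nrow(fx$annotation), 30L)
  planted <- fx$truth$plantedGenes
  nSites <- function(s) {
    v <- enumerateViews(s, 8)
    sum(v$window == referenceSeq(m))
  }
  inCounts <- vapply(fx$promoters[planted], nSites, numeric(1))
  outCounts <- vapply(fx$promoters[setdiff(names(fx$promoters), planted)],
                      nSites, numeric(1))
  expect_gte(min(inCounts), 1)
  expect_gt(mean(inCounts), mean(outCounts) + 2)
  ## deterministic under the seed
  fx2 <- makeGenomeFixture(m, nGenes = 60, promoterLen = 200,
                           nCategories = 3, categorySize = 10,
                           plantedCategory = 1, sitesPerGene = 3,
                           rngSeed = 86)
  expect_identical(fx$promoters, fx2$promoters)
})
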