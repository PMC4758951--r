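test_that("view enumeration covers all offsets on both strands", {
  v <- enumerateViews("ACGT", 4)
  expect_equal(nrow(v), 2L)
  expect_equal(v$window, c("ACGT", "ACGT"))  # palindromic full-length probe

  v <- enumerateViews("ACGTA", 4)
  expect_equal(v$offset, c(0L, 1L, 0L, 1L))
  expect_equal(v$strand, c("+", "+", "-", "-"))
  expect_equal(v$window, c("ACGT", "CGTA", "ACGT", "TACG"))

  expect_equal(nrow(enumerateViews(randSeq(36), 10)), 54L)
  expect_equal(nrow(enumerateViews("ACGTACGT", 4, "forward_only")), 5L)
  expect_error(enumerateViews("ACG", 4), "motif longer than probe")
})

test_that("feature decomposition yields L mono and L-1 di features", {
  f <- featuresOf("AC")
  expect_equal(f$order, c("mono", "mono"))
  expect_equal(f$bases, c("A", "C"))
  f <- featuresOf("AC", includeDi = TRUE)
  expect_equal(f$bases, c("A", "C", "AC"))
  expect_equal(f$position, c(0L, 1L, 0L))
  expect_equal(nrow(featuresOf(randSeq(8), includeDi = TRUE)), 15L)
  expect_error(featuresOf("ANC"), "outside")
})

test_that("window free energies sum over model blocks", {
  m <- tinyModel()
  expect_equal(windowDdG("AC", m), 0)           # reference convention
  expect_equal(windowDdG("GC", m), 2.0)
  md <- tinyModel(withDi = TRUE)
  expect_equal(windowDdG("GA", md), 2.0 + 0.5 + 0.7)
  expect_error(windowDdG("ACG", m), "length")
})

test_that("relative affinity is exp(-ddG) and monotone", {
  m <- tinyModel()
  expect_equal(relativeAffinity("AC", m), 1)
  expect_equal(relativeAffinity("CC", m), exp(-1))
  ws <- c("AC", "CC", "GC", "TC")
  dd <- windowDdG(ws, m)
  expect_true(all(diff(relativeAffinity(ws, m)[order(dd)]) < 0))
})

test_that("predicted intensity matches brute-force view enumeration", {
  set.seed(11)
  maxerr <- 0
  for (rep in 1:100) {
    L <- sample(2:6, 1)
    plen <- L + sample(0:6, 1)
    m <- randModel(L, withDi = rep %% 3 == 0)
    g <- runif(2 * (plen - L + 1))
    g <- g / max(g)
    b <- positionalBias(g, plen, L)
    im <- intensityModel(runif(1), runif(1, 0.5, 2), runif(1, 1, 5),
                         saturating = rep %% 2 == 0)
    seqs <- vapply(1:3, function(i) randSeq(plen), "")
    err <- abs(predictIntensity(seqs, m, b, im) -
               bruteIntensity(seqs, m, b@gamma, im))
    maxerr <- max(maxerr, err)
  }
  expect_lt(maxerr, 1e-12)
})

test_that("zero bias gives the intercept; saturation bounds the signal", {
  m <- randModel(4)
  plen <- 10L
  nv <- 2L * (plen - 4L + 1L)
  b0 <- positionalBias(c(1, rep(0, nv - 1L)), plen, 4L)
  im <- intensityModel(beta0 = 7, beta1 = 3)
  ## gamma almost all zero: only view 1 contributes
  s <- randSeq(plen)
  expect_equal(predictIntensity(s, m, b0, im),
               7 + 3 * relativeAffinity(substring(s, 1, 4), m))
  ## saturating predictions bounded by beta0 + beta1 * nviews
  set.seed(2)
  bs <- positionalBias(rep(1, nv), plen, 4L)
  ims <- intensityModel(beta0 = 1, beta1 = 2, ddGns = 0.1, saturating = TRUE)
  y <- predictIntensity(vapply(1:50, function(i) randSeq(plen), ""),
                        m, bs, ims)
  expect_true(all(y >= 1 & y <= 1 + 2 * nv))
})

test_that("strand-symmetric bias makes prediction reverse-complement invariant", {
  set.seed(3)
  m <- randModel(5)
  plen <- 12L
  W <- plen - 5L + 1L
  g1 <- runif(W)
  ## reverse view at offset o covers the same physical window as the
  ## forward view at the mirrored offset of the reverse-complement probe
  b <- positionalBias(c(g1, rev(g1)), plen, 5L)
  im <- intensityModel(2, 5)
  for (i in 1:20) {
    s <- randSeq(plen)
    expect_equal(predictIntensity(s, m, b, im),
                 predictIntensity(revComp(s), m, b, im), tolerance = 1e-12)
  }
})

test_that("probe table validation rejects malformed input", {
  expect_error(ProbeTable(sequence = c("ACGT", "ACG"), intensity = c(1, 2)),
               "same length")
  expect_error(ProbeTable(sequence = c("ACGU"), intensity = 1), "A, C, G, T")
  expect_error(ProbeTable(probeId = c("a", "a"),
                          sequence = c("ACGT", "ACGT"),
                          intensity = c(1, 2)), "duplicate")
  expect_error(ProbeTable(sequence = "ACGT", intensity = NaN), "finite")
})
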