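test_that("two-strand K-mer counting enumerates overlaps on both strands", {
  expect_equal(countKmers("AAAA", 2), c(AA = 3L, TT = 3L))
  expect_equal(countKmers("ACGT", 4), c(ACGT = 2L))  # self-complementary
  ## total count property: every offset on each strand contributes once
  set.seed(4)
  for (i in 1:10) {
    len <- sample(8:20, 1)
    K <- sample(2:6, 1)
    expect_equal(sum(countKmers(randSeq(len), K)), 2L * (len - K + 1L))
  }
  expect_error(countKmers("ACG", 5), "exceeds")
})

test_that("exact per-probe coefficient reproduces the intensity", {
  expect_equal(exactCoefficient(10, c(AA = 2L), "AA", c(AA = 0)), 5)
  expect_equal(
    exactCoefficient(10, c(AA = 2L, CC = 4L), "AA", c(CC = 1)), 3)
  ## exactness: plugging the solution back reproduces y
  cnt <- countKmers("ACGTAACC", 3)
  beta <- setNames(runif(length(cnt)), names(cnt))
  m <- names(cnt)[2]
  bm <- exactCoefficient(42, cnt, m, beta)
  beta[m] <- bm
  expect_equal(sum(beta[names(cnt)] * cnt), 42)
  expect_error(exactCoefficient(1, c(AA = 0L), "AA", c()), "absent")
})

test_that("trimmed mean removes floor(trim*n) values from each tail", {
  expect_equal(trimmedMean(1:10, 0.15), 5.5)
  x <- rnorm(37)
  expect_equal(trimmedMean(x, 0), mean(x))
  expect_equal(trimmedMean(c(1, 1, 1, 1, 1, 1, 100), 0.15), 1)
  ## agrees with the base-R partial-sort implementation
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:50, 1))
    tf <- runif(1, 0, 0.4)
    expect_equal(trimmedMean(x, tf), mean(x, trim = tf))
  }
  expect_error(trimmedMean(numeric(0)), "no values")
  ## robust to replacing up to trim-fraction of values with gross outliers
  x <- rnorm(100)
  xc <- x
  xc[1:15] <- 1e6
  expect_lt(abs(trimmedMean(xc, 0.15) - median(x)), 0.5)
})

test_that("seed discovery recovers a planted oligomer from clean data", {
  set.seed(6)
  site <- "AGGATAAG"
  n <- 400L
  seqs <- vapply(1:n, function(i) randSeq(30), "")
  for (i in 1:200) {
    o <- sample(23, 1)
    substring(seqs[i], o, o + 7) <- site
  }
  cnt <- vapply(seqs, function(s) {
    k <- countKmers(s, 8)
    sum(k[names(k) %in% c(site, revComp(site))])
  }, numeric(1))
  pt <- ProbeTable(sequence = seqs, intensity = 100 * cnt + 1)
  res <- findSeed(pt, 8, fitConfig())
  expect_equal(res$seed, min(site, revComp(site)))
  expect_gt(res$support[site], 100)
})

test_that("seed discovery is invariant to probe order", {
  spec <- simSpec(nProbes = 400, rngSeed = 13)
  pt <- simulatePBM(spec)
  res1 <- findSeed(pt, 8, fitConfig(seedMaxIter = 40))
  perm <- sample(length(pt))
  res2 <- findSeed(pt[perm], 8, fitConfig(seedMaxIter = 40))
  expect_equal(res1$seed, res2$seed)
  expect_equal(sort(res1$beta), sort(res2$beta), tolerance = 1e-10)
})

test_that("exact K-mer coefficients are a fixed point of the update", {
  ## data generated exactly from the count model: one iteration at the true
  ## coefficients leaves them unchanged (up to the convex step)
  set.seed(7)
  seqs <- vapply(1:60, function(i) randSeq(12), "")
  K <- 4L
  counts <- lapply(seqs, countKmers, K = K)
  kmers <- sort(unique(unlist(lapply(counts, names))))
  betaStar <- setNames(runif(length(kmers), 0, 2), kmers)
  y <- vapply(counts, function(cn) sum(betaStar[names(cn)] * cn), numeric(1))
  pt <- ProbeTable(sequence = seqs, intensity = y)
  ## per-probe exact coefficients all equal the true value at the optimum
  for (i in sample(length(seqs), 5)) {
    cn <- counts[[i]]
    for (m in names(cn)[1:2])
      expect_equal(exactCoefficient(y[i], cn, m, betaStar), betaStar[[m]])
  }
})
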