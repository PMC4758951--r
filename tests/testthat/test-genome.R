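modeSetFrom <- function(model, probeLen = 30L) {
  st <- new("FitState", model = model,
            bias = .flatBias(probeLen, motifLength(model),
                             strandPolicy(model)),
            im = intensityModel(), weights = numeric(0), betaPsam = 1,
            r2Train = 0, config = fitConfig(), details = list())
  asBindingModeSet(st)
}

test_that("total promoter affinity sums all views on both strands", {
  m <- defaultTruthModel("asymmetric")
  ms <- modeSetFrom(m)
  ## a promoter equal to the reference: forward view 1 + reverse view
  ref <- referenceSeq(m)
  expect_equal(totalPromoterAffinity(ref, ms),
               1 + relativeAffinity(revComp(ref), m))
  ## brute-force oracle on random sequences
  set.seed(31)
  for (i in 1:10) {
    s <- randSeq(60)
    vt <- enumerateViews(s, 8)
    expect_equal(totalPromoterAffinity(s, ms),
                 sum(relativeAffinity(vt$window, m)), tolerance = 1e-12)
  }
  ## concatenation: equality when junction windows have zero affinity
  a <- randSeq(40)
  b <- randSeq(40)
  expect_gte(totalPromoterAffinity(paste0(a, b), ms) + 1e-9,
             totalPromoterAffinity(a, ms))
  expect_warning(totalPromoterAffinity("ACGT", ms), "shorter")
})

test_that("rank-sum association matches exact enumeration", {
  ## 5 in-category genes holding the top 5 affinities of 20
  aff <- setNames(20:1, paste0("g", 1:20))
  ann <- data.frame(gene_id = paste0("g", 1:5), category = "GO:top")
  res <- goAssociation(aff, ann)
  expect_equal(res$p_raw, 2 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_bonferroni, res$p_raw)  # single category
  ## independent enumeration oracle
  expect_equal(exactRankSumP(aff[1:5], aff[6:20]), 1 / choose(20, 5))
  ## one-sided alternative
  res1 <- goAssociation(aff, ann, alternative = "greater")
  expect_equal(res1$p_raw, 1 / choose(20, 5), tolerance = 1e-12)
})

test_that("degenerate categories are skipped and missing genes excluded", {
  aff <- setNames(runif(10), paste0("g", 1:10))
  ann <- rbind(
    data.frame(gene_id = paste0("g", 1:10), category = "GO:all"),
    data.frame(gene_id = paste0("g", 1:4), category = "GO:sub"),
    data.frame(gene_id = "g_missing", category = "GO:sub"))
  expect_message(res <- goAssociation(aff, ann), "missing")
  expect_equal(res$category, "GO:sub")   # GO:all has < 2 genes outside
})

test_that("null labels give approximately uniform p-values", {
  set.seed(32)
  hits <- 0L
  for (r in 1:200) {
    aff <- setNames(rnorm(40), paste0("g", 1:40))
    ann <- data.frame(gene_id = sample(names(aff), 12), category = "GO:x")
    p <- goAssociation(aff, ann)$p_raw
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.01)
  expect_lte(hits / 200, 0.10)
})

test_that("normal approximation tracks the exact rank-sum path", {
  set.seed(33)
  relDev <- vapply(1:20, function(i) {
    aIn <- rnorm(12, mean = 0.5)
    aOut <- rnorm(20)
    pEx <- wilcox.test(aIn, aOut, exact = TRUE)$p.value
    pAp <- wilcox.test(aIn, aOut, exact = FALSE, correct = TRUE)$p.value
    abs(pAp - pEx) / pEx
  }, numeric(1))
  expect_lt(median(relDev), 0.10)
})

test_that("grouped trimmed means match a hand computation", {
  g <- rep(c("AAACCCGGGT", "CCCGGGTTTA"), each = 10)
  v <- c(c(5, 1, 2, 3, 4, 6, 7, 8, 9, 100), 11:20)
  out <- groupedTrimmedMean(v, g, trimFrac = 0.10)
  expect_equal(unname(out["AAACCCGGGT"]), 5.5)   # drops 1 and 100
  expect_equal(unname(out["CCCGGGTTTA"]), mean(12:19))
})

test_that("the occupancy saturation fit round-trips its parameters", {
  set.seed(34)
  a <- runif(200, 0.001, 1)
  P <- 10
  y <- 3.5 * P * a / (P * a + 1)
  fit <- fitChipSaturation(a, y)
  expect_lt(abs(fit@freeProtein - P) / P, 0.01)
  expect_lt(abs(fit@scale - 3.5) / 3.5, 0.01)
  expect_lt(fit@rmse, 1e-6)
  ## monotone predictions
  expect_true(all(diff(fit@fitted[order(a)]) >= 0))
  ## scale equivariance: k * enrichment -> k * scale, same P, same rmse
  fit2 <- fitChipSaturation(a, 7 * y)
  expect_equal(fit2@freeProtein, fit@freeProtein, tolerance = 1e-6)
  expect_equal(fit2@scale, 7 * fit@scale, tolerance = 1e-6)
  expect_equal(fit2@rmse, fit@rmse, tolerance = 1e-9)
  ## low-concentration limit: predictions proportional to affinity
  fitL <- fitChipSaturation(a, 0.05 * a + rnorm(200, sd = 1e-4))
  pred <- fitL@fitted
  expect_gt(cor(pred, a), 0.999)
  expect_error(fitChipSaturation(rep(1, 5), 1:5), "distinct")
})
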