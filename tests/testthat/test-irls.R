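test_that("clean data reproduce ordinary least squares", {
  set.seed(21)
  x <- runif(80)
  X <- cbind(1, x)
  y <- 3 + 2 * x + rnorm(80, sd = 0.05)
  fit <- irlsFit(X, y)
  ols <- qr.coef(qr(X), y)
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-2)
  ## weights: trimmed zeros present, but remaining Huber weights near 1
  expect_equal(sum(fit$weights == 0), floor(0.2 * 80))
})

test_that("gross outliers do not move the robust slope", {
  set.seed(22)
  x <- runif(200)
  y <- 2 * x + rnorm(200, sd = 0.01)
  y[1:20] <- y[1:20] + 100
  fit <- irlsFit(cbind(1, x), y)
  expect_lt(abs(fit$coefficients[2] - 2), 0.01)
  ## plain least squares fails the same check
  ols <- qr.coef(qr(cbind(1, x)), y)
  expect_gt(abs(ols[2] - 2), 0.5)
  ## the contaminated points carry zero weight
  expect_true(all(fit$weights[1:20] == 0))
})

test_that("a perfect fit leaves all weights at one", {
  x <- 1:30
  y <- 5 + 2 * x
  fit <- irlsFit(cbind(1, x), y)
  expect_true(all(fit$weights == 1))
  expect_true(fit$converged)
})

test_that("exactly floor(trim*n) observations are trimmed", {
  set.seed(23)
  for (n in c(37, 100, 253)) {
    X <- cbind(1, runif(n))
    y <- X %*% c(1, 2) + rnorm(n)
    fit <- irlsFit(X, y, trim = 0.2)
    expect_equal(sum(fit$weights == 0), floor(0.2 * n))
    expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  }
})

test_that("rank-deficient designs fail naming the collinear columns", {
  x <- runif(50)
  X <- cbind(a = 1, b = x, c = 2 * x)
  expect_error(irlsFit(X, rnorm(50)), "collinear.*c")
})

test_that("the robust estimate agrees with MASS::rlm on contaminated data", {
  skip_if_not_installed("MASS")
  set.seed(24)
  x <- runif(300)
  y <- 1 + 4 * x + rnorm(300, sd = 0.1)
  y[1:30] <- y[1:30] * 10
  ours <- irlsFit(cbind(1, x), y)$coefficients
  theirs <- MASS::rlm(y ~ x, psi = MASS::psi.huber, maxit = 50)$coefficients
  expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
})
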