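#' Robust linear regression by IRLS with hard trimming
#'
#' Iteratively reweighted least squares tailored to PBM fitting: starting
#' from ordinary least squares, each iteration computes residuals, a robust
#' scale estimate `sigma = 1.4826 * median(|r|)`, Huber weights
#' `w_i = min(1, c * sigma / |r_i|)`, additionally zeroes the weights of the
#' `floor(trim * n)` probes with the largest absolute residuals, and refits
#' by weighted least squares, until the coefficients change by less than
#' `tol` (relative) or `maxIter` iterations. When all residuals are equal
#' (perfect fit) weights stay at 1 and no trimming is applied.
#'
#' @param X Numeric design matrix (include an intercept column yourself).
#' @param y Numeric response.
#' @param trim Fraction of probes hard-trimmed per iteration (default 0.20).
#' @param huberC Huber tuning constant (default 1.345).
#' @param robust FALSE gives plain (unweighted) least squares.
#' @param maxIter,tol Iteration cap and relative coefficient tolerance.
#' @return List with `coefficients`, `weights` (in `[0, 1]`, exactly
#'   `floor(trim * n)` zeros when robust and residuals are not degenerate),
#'   `fitted`, `residuals`, `sigma`, `iterations`, `converged`.
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(100); y <- 2 * x + rnorm(100, sd = 0.01)
#' y[1:10] <- y[1:10] + 100  # gross outliers
#' fit <- irlsFit(cbind(1, x), y)
#' fit$coefficients[2]  # close to 2
irlsFit <- function(X, y, trim = 0.20, huberC = 1.345, robust = TRUE,
                    maxIter = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (n < p + 1L) stop("need at least ncol(X) + 1 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  w <- rep(1, n)
  if (!robust) {
    fitted <- drop(X %*% beta)
    return(list(coefficients = beta, weights = w, fitted = fitted,
                residuals = y - fitted, sigma = stats::sd(y - fitted),
                iterations = 0L, converged = TRUE))
  }
  k <- floor(trim * n)
  converged <- FALSE
  it <- 0L
  sigma <- NA_real_
  while (it < maxIter) {
    it <- it + 1L
    r <- y - drop(X %*% beta)
    ar <- abs(r)
    sigma <- 1.4826 * stats::median(ar)
    if (sigma <= 1e-12 * max(abs(y), 1)) {
      ## (near-)perfect fit: nothing to down-weight
      w <- rep(1, n)
      converged <- TRUE
      break
    }
    w <- pmin(1, huberC * sigma / ar)
    w[ar < .Machine$double.eps] <- 1
    if (k > 0L) w[order(ar, decreasing = TRUE)[seq_len(k)]] <- 0
    betaNew <- lm.wfit(X, y, w)$coefficients
    delta <- max(abs(betaNew - beta)) / max(1e-10, max(abs(betaNew)))
    beta <- betaNew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  fitted <- drop(X %*% beta)
  list(coefficients = beta, weights = w, fitted = fitted,
       residuals = y - fitted, sigma = sigma, iterations = it,
       converged = converged)
}
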