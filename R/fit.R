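## Robust block-wise model estimation: the central inference engine.
## The free-energy parameters of one feature block at a time are re-estimated
## by robust linear regression of the intensities on per-feature affinity
## regressors, cycling over blocks until convergence; the positional bias
## profile is re-estimated between cycles; an optional final nonlinear stage
## fits the saturating intensity model.

.r2 <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

## ---------------------------------------------------------------------
## single block update
## ---------------------------------------------------------------------

## S: encoded probe matrix; j: 1-based block position. Returns the updated
## model plus the robust weights of the block regression.
.fitBlockInternal <- function(S, y, model, gamma, betaPsam, config,
                              order = "mono", j) {
  L <- motifLength(model)
  E <- .viewAffinityMatrix(S, model)
  G <- sweep(E, 2L, gamma, "*")
  if (order == "mono") {
    B <- .viewBaseMatrix(S, L, j, model@strandPolicy)
    nlev <- 4L
    old <- model@monoDdG[, j]
    labs <- paste0("mono:", j - 1L, ":", .BASES)
  } else {
    if (j > L - 1L) stop("dinucleotide block position out of range")
    B <- .viewDiMatrix(S, L, j, model@strandPolicy)
    nlev <- 16L
    old <- model@diDdG[, j]
    labs <- paste0("di:", j - 1L, ":", .DINUCS)
  }
  R <- matrix(0, nrow(S), nlev)
  for (lev in seq_len(nlev)) R[, lev] <- rowSums(G * (B == lev))
  R <- sweep(R, 2L, exp(pmin(old, config@ddGCeiling)), "*")
  absent <- colSums(abs(R)) == 0
  if (any(absent))
    stop("feature absent from every probe view: ",
         paste(labs[absent], collapse = ", "))
  X <- cbind(1, R)
  colnames(X) <- c("(Intercept)", labs)
  fit <- irlsFit(X, y, trim = config@trimProbesFrac, huberC = config@huberC,
                 robust = config@robust)
  bphi <- fit$coefficients[-1]
  ceilinged <- bphi <= 0
  newDdG <- rep(config@ddGCeiling, length(bphi))
  newDdG[!ceilinged] <- -log(bphi[!ceilinged] / betaPsam)
  if (order == "mono") {
    refb <- match(substring(model@referenceSeq, j, j), .BASES)
    newDdG <- newDdG - newDdG[refb]
    ## keep the reference the highest-affinity base at this position
    if (min(newDdG) < -1e-9) {
      refb <- which.min(newDdG)
      substring(model@referenceSeq, j, j) <- .BASES[refb]
      newDdG <- newDdG - newDdG[refb]
    }
    newDdG <- pmin(newDdG, config@ddGCeiling)
    newDdG[refb] <- 0
    model@monoDdG[, j] <- newDdG
  } else {
    newDdG <- pmin(pmax(newDdG, -config@ddGCeiling), config@ddGCeiling)
    model@diDdG[, j] <- newDdG
  }
  list(model = model, weights = fit$weights,
       coefficients = fit$coefficients, ddG = stats::setNames(newDdG, labs),
       nCeilinged = sum(ceilinged))
}

#' Re-estimate one feature block by robust regression
#'
#' Updates the ddG/RT values of a single mononucleotide or dinucleotide
#' block, holding all other blocks fixed. The per-probe regressor for a
#' feature is the bias-weighted sum of `exp(-(ddG(S_v) - ddG_phi)/RT)` over
#' the views that contain the feature; the fitted coefficients are converted
#' back through `ddG_phi/RT = -log(beta_phi / beta_PSAM)`. Mononucleotide
#' blocks are re-anchored so the reference base sits at 0; dinucleotide
#' blocks keep the scale-based values unanchored. A feature with a
#' non-positive regression coefficient is assigned the configured ddG
#' ceiling (never observed bound).
#'
#' @param state A [FitState-class] holding the current model, bias and
#'   PSAM reference scale.
#' @param probes A [ProbeTable-class].
#' @param position 0-based block position within the motif window.
#' @param order `"mono"` or `"di"`.
#' @param config A [FitConfig-class]; defaults to the state's config.
#' @return The updated [FitState-class] (weights refreshed from the block
#'   regression).
#' @export
fitBlock <- function(state, probes, position, order = c("mono", "di"),
                     config = state@config) {
  order <- match.arg(order)
  S <- .encodeSeqs(probes@sequence)
  betaPsam <- if (length(state@betaPsam) && is.finite(state@betaPsam))
    state@betaPsam else state@im@beta1
  res <- .fitBlockInternal(S, probes@intensity, state@model,
                           state@bias@gamma, betaPsam, config,
                           order, as.integer(position) + 1L)
  state@model <- res$model
  state@weights <- res$weights
  state@details$lastBlock <- res$ddG
  state
}

## ---------------------------------------------------------------------
## block cycling
## ---------------------------------------------------------------------

## Cycle all blocks of one order until max |ddG change| < blockTol or
## maxBlockPasses. tie = TRUE mirror-averages position pairs so the model
## stays reverse-complement symmetric.
.cycleBlocks <- function(S, y, model, gamma, betaPsam, config,
                         order = "mono", tie = FALSE) {
  L <- motifLength(model)
  nb <- if (order == "mono") L else L - 1L
  weights <- rep(1, nrow(S))
  passes <- 0L
  repeat {
    passes <- passes + 1L
    before <- if (order == "mono") model@monoDdG else model@diDdG
    for (j in seq_len(nb)) {
      res <- .fitBlockInternal(S, y, model, gamma, betaPsam, config,
                               order, j)
      model <- res$model
      weights <- res$weights
      if (tie && order == "mono") model <- .mirrorAverage(model, j)
    }
    after <- if (order == "mono") model@monoDdG else model@diDdG
    if (max(abs(after - before)) < config@blockTol ||
        passes >= config@maxBlockPasses) break
  }
  list(model = model, weights = weights, passes = passes)
}

## average ddG(j, b) with ddG(L-1-j, comp(b)) (1-based: j and L+1-j) to
## enforce palindromic tying; the centre column of an odd-length motif is
## left untied
.mirrorAverage <- function(model, j) {
  L <- motifLength(model)
  jm <- L + 1L - j
  if (jm == j) return(model)
  a <- model@monoDdG[, j]
  b <- model@monoDdG[4:1, jm]       # complement = reversed base order
  avg <- (a + b) / 2
  model@monoDdG[, j] <- avg
  model@monoDdG[, jm] <- avg[4:1]
  model
}

## ---------------------------------------------------------------------
## positional bias
## ---------------------------------------------------------------------

.fitBiasInternal <- function(S, y, model, config) {
  E <- .viewAffinityMatrix(S, model)
  ## a palindromic model gives identical forward and reverse view columns;
  ## tie the strands to keep the design full-rank
  collapse <- model@symmetric && model@strandPolicy == "both"
  if (collapse) {
    W <- ncol(E) / 2L
    E <- E[, seq_len(W), drop = FALSE] + E[, W + seq_len(W), drop = FALSE]
  }
  nv <- ncol(E)
  if (nrow(E) < nv + 1L)
    stop(sprintf(paste0("fewer probes (%d) than views (%d): pool probes or",
                        " smooth the positional profile"), nrow(E), nv))
  X <- cbind(1, E)
  colnames(X) <- c("(Intercept)", paste0("view", seq_len(nv)))
  fit <- irlsFit(X, y, trim = config@trimProbesFrac, huberC = config@huberC,
                 robust = config@robust)
  co <- pmax(fit$coefficients[-1], 0)
  if (max(co) <= 0)
    stop("no view received a positive bias coefficient")
  gamma <- co / max(co)
  if (collapse) gamma <- c(gamma, gamma)
  list(bias = positionalBias(gamma, ncol(S), motifLength(model),
                             model@strandPolicy),
       beta0 = unname(fit$coefficients[1]),
       beta1 = max(co),
       weights = fit$weights)
}

#' Estimate the positional bias profile
#'
#' Robustly regresses probe intensities on the per-view relative affinities
#' `exp(-ddG(S_v)/RT)` under the current model, one shared coefficient per
#' view. Negative coefficients are clipped to zero and the profile is
#' normalised to maximum 1; the overall scale is folded into the intensity
#' model's beta1.
#'
#' @inheritParams fitBlock
#' @return A [PositionalBias-class] with attributes `beta0` and `beta1`
#'   (the intercept and scale of the accompanying intensity fit).
#' @export
fitPositionalBias <- function(state, probes, config = state@config) {
  S <- .encodeSeqs(probes@sequence)
  res <- .fitBiasInternal(S, probes@intensity, state@model, config)
  out <- res$bias
  attr(out, "beta0") <- res$beta0
  attr(out, "beta1") <- res$beta1
  out
}

## ---------------------------------------------------------------------
## nonlinear (saturating) stage
## ---------------------------------------------------------------------

.fitNonlinearInternal <- function(S, y, model, bias, im, weights, config) {
  E <- .viewAffinityMatrix(S, model)
  g <- bias@gamma
  keep <- weights > 0
  Ek <- E[keep, , drop = FALSE]
  yk <- y[keep]
  wk <- weights[keep]
  ## lcc parametrises the free-protein concentration scale on the log
  ## scale to keep it positive
  fn <- function(b0, b1, dns, lcc) {
    x <- sweep(Ek, 2L, exp(lcc) * g, "*") + exp(-dns)
    b0 + b1 * rowSums(x / (1 + x))
  }
  fit <- try(minpack.lm::nlsLM(
    yk ~ fn(b0, b1, dns, lcc),
    start = list(b0 = im@beta0, b1 = im@beta1, dns = 8, lcc = 0),
    weights = wk,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$convInfo$isConv) {
    warning("saturating intensity fit did not converge; ",
            "returning linear-stage parameters")
    return(im)
  }
  co <- stats::coef(fit)
  if (!is.finite(co["b1"]) || co["b1"] <= 0) {
    warning("saturating intensity fit degenerate; ",
            "returning linear-stage parameters")
    return(im)
  }
  intensityModel(co["b0"], co["b1"], co["dns"], saturating = TRUE,
                 conc = exp(co["lcc"]))
}

#' Fit the saturating intensity model
#'
#' Levenberg-Marquardt fit of the occupancy-form intensity model (intercept,
#' scale, the non-specific term ddG_ns/RT, and the free-protein
#' concentration scale), initialised from the linear stage with ddG_ns
#' large (near-zero non-specific binding) and unit concentration. Robust-stage
#' probe weights are carried over; if the fit fails to converge the
#' linear-stage parameters are returned with a warning.
#'
#' @inheritParams fitBlock
#' @return An [IntensityModel-class].
#' @export
fitNonlinear <- function(state, probes, config = state@config) {
  S <- .encodeSeqs(probes@sequence)
  .fitNonlinearInternal(S, probes@intensity, state@model, state@bias,
                        state@im, state@weights, config)
}

## ---------------------------------------------------------------------
## full pipeline
## ---------------------------------------------------------------------

## Core fit: seed -> PSAM cycling + bias -> optional dinucleotides ->
## optional saturating stage. `tie` requests palindromic parameter tying,
## `forcePolicy` overrides the poly-G/C strand rule (used by the palindrome
## detector).
.fitCore <- function(probes, config, tie = FALSE, forcePolicy = NULL) {
  set.seed(config@rngSeed)
  S <- .encodeSeqs(probes@sequence)
  y <- probes@intensity
  n <- length(y)
  logRounds <- list()

  if (!is.na(config@knownSeed)) {
    seed <- toupper(config@knownSeed)
    seedInfo <- NULL
  } else {
    seedInfo <- findSeed(probes, config@kSeed, config)
    seed <- seedInfo$seed
  }
  policy <- if (!is.null(forcePolicy)) forcePolicy
            else if (config@polyGCRule) polyGCStrandPolicy(seed)
            else "both"
  model <- featureModel(seed, offRef = config@initDdG,
                        strandPolicy = policy, symmetric = tie)
  if (tie) for (j in seq_len(motifLength(model)))
    model <- .mirrorAverage(model, j)
  L <- motifLength(model)
  bias <- .flatBias(ncol(S), L, policy)
  gamma <- bias@gamma
  im <- intensityModel(beta0 = min(y), beta1 = max(stats::sd(y), 1e-8))
  weights <- rep(1, n)

  ## --- mononucleotide phase ---
  prev <- model@monoDdG
  for (round in seq_len(config@maxOuterRounds)) {
    cyc <- .cycleBlocks(S, y, model, gamma, im@beta1, config, "mono", tie)
    model <- cyc$model
    bf <- .fitBiasInternal(S, y, model, config)
    gamma <- bf$bias@gamma
    bias <- bf$bias
    im <- intensityModel(bf$beta0, max(bf$beta1, 1e-12), im@ddGns, FALSE)
    weights <- bf$weights
    pred <- .predictFromE(.viewAffinityMatrix(S, model), gamma * im@beta1,
                          intensityModel(im@beta0, 1, im@ddGns, FALSE))
    obj <- sum(weights * (y - pred)^2)
    delta <- max(abs(model@monoDdG - prev))
    logRounds[[length(logRounds) + 1L]] <-
      data.frame(phase = "mono", round = round, passes = cyc$passes,
                 r2 = .r2(y, pred), objective = obj, maxDelta = delta)
    prev <- model@monoDdG
    if (delta < 10 * config@blockTol) break
  }
  betaPsam <- im@beta1

  ## --- dinucleotide phase ---
  if (config@includeDi && L >= 2L) {
    model@diDdG <- matrix(0, 16L, L - 1L,
                          dimnames = list(.DINUCS, NULL))
    prevDi <- model@diDdG
    ## weakly informed dinucleotide features can oscillate between the
    ## ceiling and small values; a handful of passes is where the
    ## well-informed features have long converged
    diCfg <- config
    diCfg@maxBlockPasses <- min(config@maxBlockPasses, 5L)
    for (round in seq_len(min(config@maxOuterRounds, 3L))) {
      cyc <- .cycleBlocks(S, y, model, gamma, betaPsam, diCfg, "di")
      model <- cyc$model
      bf <- .fitBiasInternal(S, y, model, config)
      gamma <- bf$bias@gamma
      bias <- bf$bias
      im <- intensityModel(bf$beta0, max(bf$beta1, 1e-12), im@ddGns, FALSE)
      weights <- bf$weights
      pred <- .predictFromE(.viewAffinityMatrix(S, model), gamma * im@beta1,
                            intensityModel(im@beta0, 1, im@ddGns, FALSE))
      obj <- sum(weights * (y - pred)^2)
      delta <- max(abs(model@diDdG - prevDi))
      logRounds[[length(logRounds) + 1L]] <-
        data.frame(phase = "di", round = round, passes = cyc$passes,
                   r2 = .r2(y, pred), objective = obj, maxDelta = delta)
      prevDi <- model@diDdG
      if (delta < 10 * config@blockTol) break
    }
  }

  ## --- optional saturating stage ---
  if (config@saturation)
    im <- .fitNonlinearInternal(S, y, model, bias, im, weights, config)

  E <- .viewAffinityMatrix(S, model)
  pred <- if (im@saturating) .predictFromE(E, gamma, im)
          else .predictFromE(E, gamma * im@beta1,
                             intensityModel(im@beta0, 1, im@ddGns, FALSE))
  details <- list(log = do.call(rbind, logRounds), seed = seed,
                  seedInfo = seedInfo)
  new("FitState", model = model, bias = bias, im = im, weights = weights,
      betaPsam = betaPsam, r2Train = .r2(y, pred), config = config,
      details = details)
}

#' Fit a sequence-to-affinity model to PBM intensities
#'
#' Full inference pipeline: seed discovery (unless a seed is supplied),
#' poly-G/C strand rule, robust block-wise PSAM estimation cycling with
#' positional-bias re-estimation, optional dinucleotide blocks (fit after
#' the PSAM has converged, against the frozen PSAM reference scale),
#' optional saturating intensity fit, and optional structural refinement
#' (palindrome tying, motif-length selection).
#'
#' @param probes A [ProbeTable-class].
#' @param config A [FitConfig-class].
#' @return A [FitState-class].
#' @export
#' @examples
#' spec <- simSpec(nProbes = 300, rngSeed = 4)
#' probes <- simulatePBM(spec)
#' st <- fitModel(probes, fitConfig(knownSeed = "AGGATAAG"))
#' trainR2(st)
fitModel <- function(probes, config = fitConfig()) {
  stopifnot(is(probes, "ProbeTable"))
  state <- .fitCore(probes, config)
  if (config@growMotif)
    state <- selectMotifLength(probes, state, config)
  if (config@symmetry == "on") {
    state <- symmetrize(state, probes, config)
  } else if (config@symmetry == "auto") {
    cfg <- config
    cfg@knownSeed <- state@details$seed
    dp <- detectPalindrome(probes, cfg)
    state@details$palindrome <- dp[c("symmetric", "distance")]
    if (dp$symmetric) state <- symmetrize(state, probes, config)
  }
  state
}

#' Predict intensities for probes under a fitted state
#'
#' @param object A [FitState-class].
#' @param probes A [ProbeTable-class] (or character vector of sequences) of
#'   the same probe length the state was fitted on.
#' @param ... Unused.
#' @return Numeric vector of predicted intensities.
#' @export
setMethod("predict", "FitState", function(object, probes, ...) {
  seqs <- if (is(probes, "ProbeTable")) probes@sequence else probes
  im <- object@im
  if (!im@saturating)
    im <- intensityModel(im@beta0, 1, im@ddGns, FALSE)
  g <- if (object@im@saturating) object@bias@gamma
       else object@bias@gamma * object@im@beta1
  S <- .encodeSeqs(toupper(seqs))
  E <- .viewAffinityMatrix(S, object@model)
  .predictFromE(E, g, im)
})
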