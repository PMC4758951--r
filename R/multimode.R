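## Forward selection and joint refinement of multiple binding modes:
## distinct feature models combined additively, each with a relative K_a.

## per-mode bias-weighted affinity sum for every probe (no beta0/beta1)
.modeAffinitySum <- function(S, model, bias) {
  drop(.viewAffinityMatrix(S, model) %*% bias@gamma)
}

.asModeSet <- function(state, pvalue = NA_real_) {
  new("BindingModeSet", modes = list(state@model), relKa = 1,
      modePvalues = pvalue, im = state@im, biases = list(state@bias),
      details = list(states = list(state)))
}

#' Convert a single fit into a binding-mode set
#'
#' @param state A [FitState-class].
#' @return A [BindingModeSet-class] with one mode and `relKa = 1`.
#' @export
asBindingModeSet <- function(state) .asModeSet(state)

#' Fit multiple binding modes by forward selection
#'
#' Implements the four-step procedure: (i) fit a single binding model with
#' the standard pipeline; (ii) fit additional binding-mode model(s) to the
#' residuals of the combined model so far; (iii) iteratively re-fit each
#' mode against the intensities minus every other mode's contribution,
#' blending old and refit parameters on the ddG/RT scale with step size
#' `alpha`, until convergence; (iv) perform a final robust multiple
#' regression of the intensities on the per-mode affinity sums, giving each
#' mode's relative K_a (normalised to the strongest mode) and a
#' significance p-value. A residual fit that rediscovers an existing mode
#' (same seed, or mono ddG L1 distance below `config@modeDupL1`) or that
#' explains less than `config@modeMinResidR2` of the residual variance
#' stops the forward selection; modes with p above `config@modePThreshold`
#' or a relative K_a below `config@modeMinRelKa` are dropped.
#'
#' @param probes A [ProbeTable-class].
#' @param config A [FitConfig-class].
#' @param maxModes Maximum number of modes (default `config@maxModes`).
#' @return A [BindingModeSet-class].
#' @export
fitMultiMode <- function(probes, config = fitConfig(),
                         maxModes = config@maxModes) {
  stopifnot(maxModes >= 1L)
  y <- probes@intensity
  S <- .encodeSeqs(probes@sequence)
  baseCfg <- config
  baseCfg@symmetry <- "off"
  baseCfg@growMotif <- FALSE

  ## (i) primary mode
  states <- list(.fitCore(probes, baseCfg))
  if (maxModes == 1L) return(.asModeSet(states[[1L]]))

  dup <- function(cand, existing) {
    for (st in existing) {
      if (cand@model@referenceSeq == st@model@referenceSeq) return(TRUE)
      rcSeed <- revComp(cand@model@referenceSeq)
      if (rcSeed == st@model@referenceSeq) return(TRUE)
      if (motifLength(cand@model) == motifLength(st@model) &&
          mean(abs(cand@model@monoDdG - st@model@monoDdG)) <
            config@modeDupL1) return(TRUE)
    }
    FALSE
  }

  contrib <- function(st)
    st@im@beta1 * .modeAffinitySum(S, st@model, st@bias)

  ## (ii) residual modes
  for (k in 2:maxModes) {
    yhat <- Reduce(`+`, lapply(states, contrib)) + states[[1L]]@im@beta0
    r <- y - yhat
    cfg <- baseCfg
    cfg@knownSeed <- NA_character_
    cfg@rngSeed <- baseCfg@rngSeed + k
    cand <- try(.fitCore(ProbeTable(probes@probeId, probes@sequence, r),
                         cfg), silent = TRUE)
    if (inherits(cand, "try-error") || dup(cand, states) ||
        cand@r2Train < config@modeMinResidR2) {
      message("no additional binding mode found; stopping at ",
              length(states), " mode(s)")
      break
    }
    states[[k]] <- cand
  }
  nm <- length(states)
  if (nm == 1L) return(.asModeSet(states[[1L]]))

  ## (iii) iterative joint refinement with alpha-blending on the ddG scale
  for (round in seq_len(config@modeMaxRounds)) {
    maxDelta <- 0
    for (m in seq_len(nm)) {
      others <- setdiff(seq_len(nm), m)
      ym <- y - Reduce(`+`, lapply(states[others], contrib))
      cfg <- baseCfg
      cfg@knownSeed <- states[[m]]@model@referenceSeq
      ## the blend only needs an approximate refit; full convergence is
      ## restored by the outer refinement rounds
      cfg@maxOuterRounds <- min(cfg@maxOuterRounds, 2L)
      refit <- .fitCore(ProbeTable(probes@probeId, probes@sequence, ym), cfg)
      oldM <- states[[m]]@model
      a <- config@alpha
      newMono <- (1 - a) * oldM@monoDdG + a * refit@model@monoDdG
      maxDelta <- max(maxDelta, abs(newMono - oldM@monoDdG))
      refit@model@monoDdG <- .reanchorMono(newMono, oldM@referenceSeq)
      if (ncol(oldM@diDdG) && ncol(refit@model@diDdG)) {
        newDi <- (1 - a) * oldM@diDdG + a * refit@model@diDdG
        maxDelta <- max(maxDelta, abs(newDi - oldM@diDdG))
        refit@model@diDdG <- newDi
      }
      states[[m]] <- refit
    }
    if (maxDelta < config@modeTol) break
  }

  ## (iv) final joint robust multiple regression
  A <- vapply(states, function(st) .modeAffinitySum(S, st@model, st@bias),
              numeric(length(y)))
  X <- cbind(`(Intercept)` = 1, A)
  colnames(X) <- c("(Intercept)", paste0("mode", seq_len(nm)))
  fit <- irlsFit(X, y, trim = config@trimProbesFrac,
                 huberC = config@huberC, robust = config@robust)
  b <- fit$coefficients[-1]
  pv <- .wlsPvalues(X, y, fit$weights)[-1]
  keep <- which(b > 0 & pv <= config@modePThreshold &
                b >= config@modeMinRelKa * max(b))
  if (length(keep) == 0L) keep <- which.max(b)
  if (length(keep) < nm)
    message("dropping ", nm - length(keep),
            " mode(s) not significant in the joint regression")
  ord <- keep[order(b[keep], decreasing = TRUE)]
  states <- states[ord]
  b <- b[ord]
  pv <- pv[ord]
  if (length(states) == 1L) return(.asModeSet(states[[1L]], pv))

  im <- intensityModel(unname(fit$coefficients[1]), unname(b[1]),
                       states[[1L]]@im@ddGns, FALSE)
  new("BindingModeSet", modes = lapply(states, function(s) s@model),
      relKa = unname(b / b[1]), modePvalues = unname(pv), im = im,
      biases = lapply(states, function(s) s@bias),
      details = list(states = states, jointWeights = fit$weights))
}

## re-anchor a blended mono matrix so each reference base sits at 0 again
.reanchorMono <- function(M, refSeq) {
  refb <- match(strsplit(refSeq, "")[[1]], .BASES)
  for (j in seq_len(ncol(M))) M[, j] <- M[, j] - M[refb[j], j]
  M
}

## two-sided t-test p-values of WLS coefficients at fixed weights
.wlsPvalues <- function(X, y, w) {
  keep <- w > 0
  Xk <- X[keep, , drop = FALSE] * sqrt(w[keep])
  yk <- y[keep] * sqrt(w[keep])
  fit <- stats::lm.fit(Xk, yk)
  df <- sum(keep) - ncol(X)
  s2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xk)))
  se <- sqrt(diag(XtXinv) * s2)
  tval <- fit$coefficients / se
  2 * stats::pt(abs(tval), df, lower.tail = FALSE)
}

#' Dominant binding mode for a sequence
#'
#' Returns the index of the mode maximising `relKa_m * max_v
#' exp(-ddG_m(S_v)/RT)` over the sequence's views; ties return the lowest
#' index. Modes longer than the sequence are skipped; if every mode is
#' longer, an error is raised.
#'
#' @param seq A single DNA string.
#' @param modeset A [BindingModeSet-class].
#' @return Integer mode index.
#' @export
dominantMode <- function(seq, modeset) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  scores <- rep(-Inf, length(modeset@modes))
  for (m in seq_along(modeset@modes)) {
    mod <- modeset@modes[[m]]
    if (motifLength(mod) > nchar(seq)) next
    S <- .encodeSeqs(seq)
    scores[m] <- modeset@relKa[m] * max(.viewAffinityMatrix(S, mod))
  }
  if (all(!is.finite(scores)))
    stop("sequence shorter than every binding mode")
  which.max(scores)
}

#' Predict intensities under a binding-mode set
#'
#' Sums the per-mode contributions `beta1 * relKa_m * sum_v gamma_v
#' exp(-ddG_m(S_v)/RT)` on top of the shared intercept (occupancy form per
#' view when the intensity model saturates).
#'
#' @param object A [BindingModeSet-class].
#' @param probes A [ProbeTable-class] or character vector of sequences.
#' @param ... Unused.
#' @return Numeric vector of predicted intensities.
#' @export
setMethod("predict", "BindingModeSet", function(object, probes, ...) {
  seqs <- if (is(probes, "ProbeTable")) probes@sequence else toupper(probes)
  S <- .encodeSeqs(seqs)
  im <- object@im
  total <- numeric(nrow(S))
  for (m in seq_along(object@modes)) {
    E <- .viewAffinityMatrix(S, object@modes[[m]])
    g <- object@biases[[m]]@gamma
    if (im@saturating) {
      x <- sweep(E, 2L, im@conc * g * object@relKa[m], "*") + exp(-im@ddGns)
      total <- total + rowSums(x / (1 + x))
    } else {
      total <- total + object@relKa[m] * drop(E %*% g)
    }
  }
  im@beta0 + im@beta1 * total
})
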