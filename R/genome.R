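## In-vivo scoring utilities: total promoter affinity, Gene Ontology
## rank-sum association, and the single-parameter ChIP saturation model.

#' ChIP saturation fit
#'
#' Result of [fitChipSaturation()]: the single free-protein scale `P` of the
#' equilibrium occupancy model `enrichment ~ scale * P a / (P a + 1)`.
#'
#' @slot freeProtein numeric, the fitted `P` (the `[P] Ka` scale).
#' @slot scale numeric multiplicative scale.
#' @slot rmse numeric RMSE between observed and predicted enrichments after
#'   normalising observed enrichments to maximum 1.
#' @slot fitted numeric fitted enrichments (raw scale).
#' @export
setClass("ChipSaturationFit",
  representation(freeProtein = "numeric", scale = "numeric",
                 rmse = "numeric", fitted = "numeric"))

setMethod("show", "ChipSaturationFit", function(object) {
  cat(sprintf(
    "ChipSaturationFit: free-protein scale P = %.4g, scale = %.4g, RMSE = %.4g\n",
    object@freeProtein, object@scale, object@rmse))
})

## coerce model-ish inputs to a BindingModeSet
.toModeSet <- function(x) {
  if (is(x, "BindingModeSet")) return(x)
  if (is(x, "FitState")) return(asBindingModeSet(x))
  if (is(x, "FeatureModel"))
    stop("a bare FeatureModel has no probe geometry; wrap it in a ",
         "FitState/BindingModeSet or use relativeAffinity() directly")
  stop("cannot interpret ", class(x), " as a binding model")
}

## total (gamma-free) affinity of one sequence under one mode
.totalAffinityMode <- function(seq, model) {
  L <- motifLength(model)
  if (nchar(seq) < L) return(NA_real_)
  S <- .encodeSeqs(seq)
  sum(.viewAffinityMatrix(S, model))
}

#' Total binding affinity of a promoter sequence
#'
#' Sliding-window sum of relative affinities over all views of the sequence
#' (both strands unless the mode's strand policy restricts), summed over
#' binding modes weighted by their relative K_a. No positional bias enters:
#' the profile is a microarray-technology correction, not a property of
#' genomic DNA.
#'
#' @param seq Character vector of DNA sequences (any lengths).
#' @param modeset A [BindingModeSet-class] or [FitState-class].
#' @return Numeric vector of total affinities (0 with a warning for
#'   sequences shorter than every mode).
#' @export
totalPromoterAffinity <- function(seq, modeset) {
  modeset <- .toModeSet(modeset)
  seq <- toupper(seq)
  out <- numeric(length(seq))
  tooShort <- rep(TRUE, length(seq))
  ## batch sequences of equal length for speed
  for (len in unique(nchar(seq))) {
    idx <- which(nchar(seq) == len)
    S <- .encodeSeqs(seq[idx])
    tot <- numeric(length(idx))
    covered <- FALSE
    for (m in seq_along(modeset@modes)) {
      mod <- modeset@modes[[m]]
      if (motifLength(mod) > len) next
      covered <- TRUE
      tot <- tot + modeset@relKa[m] * rowSums(.viewAffinityMatrix(S, mod))
    }
    out[idx] <- tot
    tooShort[idx] <- !covered
  }
  if (any(tooShort))
    warning(sum(tooShort), " sequence(s) shorter than every binding mode; ",
            "affinity set to 0")
  out
}

#' Gene Ontology association by rank-sum test
#'
#' For every annotation category, compares the total promoter affinities of
#' in-category genes against all other genes with a Wilcoxon-Mann-Whitney
#' rank-sum test (exact for small untied groups, normal approximation with
#' tie correction otherwise), and applies a Bonferroni correction over the
#' number of categories tested. Categories with fewer than 2 genes on
#' either side are skipped; annotated genes missing from the affinity
#' vector are excluded and counted.
#'
#' @param affinities Named numeric vector of per-gene total promoter
#'   affinities (names are gene identifiers), or a data.frame with columns
#'   `gene_id` and `total_affinity`.
#' @param annotation A data.frame with columns `gene_id` and `category`.
#' @param alternative `"two.sided"` (default) or `"greater"` for the
#'   one-sided high-affinity alternative.
#' @return A data.frame sorted by raw p-value with columns `category`,
#'   `n_in`, `U_statistic`, `p_raw`, `p_bonferroni`.
#' @export
goAssociation <- function(affinities, annotation,
                          alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(affinities))
    affinities <- stats::setNames(affinities$total_affinity,
                                  affinities$gene_id)
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "category") %in% names(annotation)))
  missing <- setdiff(unique(annotation$gene_id), names(affinities))
  if (length(missing))
    message(length(missing),
            " annotated gene(s) missing from the affinity table; excluded")
  annotation <- annotation[annotation$gene_id %in% names(affinities), ]
  cats <- unique(annotation$category)
  rows <- list()
  skipped <- character(0)
  for (cc in cats) {
    inGenes <- unique(annotation$gene_id[annotation$category == cc])
    aIn <- affinities[names(affinities) %in% inGenes]
    aOut <- affinities[!names(affinities) %in% inGenes]
    if (length(aIn) < 2L || length(aOut) < 2L) {
      skipped <- c(skipped, cc)
      next
    }
    exact <- length(aIn) <= 25L && length(aOut) <= 25L
    wt <- suppressWarnings(stats::wilcox.test(
      aIn, aOut, alternative = alternative, exact = exact, correct = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      category = cc, n_in = length(aIn), U_statistic = unname(wt$statistic),
      p_raw = wt$p.value, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message(length(skipped),
            " categor(ies) skipped (fewer than 2 genes in or out)")
  if (length(rows) == 0L)
    return(data.frame(category = character(0), n_in = integer(0),
                      U_statistic = numeric(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0)))
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out[order(out$p_raw), , drop = FALSE]
}

#' Grouped trimmed means
#'
#' Trimmed mean of values within each group; preprocessing utility for,
#' e.g., per-K-mer ChIP fold-enrichments.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @param trimFrac Trim fraction per tail (default 0.10).
#' @return Named numeric vector of per-group trimmed means.
#' @export
groupedTrimmedMean <- function(values, groups, trimFrac = 0.10) {
  vapply(split(values, groups), trimmedMean, numeric(1),
         trimFrac = trimFrac)
}

#' Fit the single-parameter ChIP saturation model
#'
#' Nonlinear least-squares fit of the equilibrium occupancy form
#' `enrichment ~ scale * P a / (P a + 1)` over the free-protein scale `P`
#' and a multiplicative `scale`, where `a` is the relative binding affinity
#' of each site. Higher-affinity sites saturate towards `scale`. The
#' reported RMSE is computed after normalising observed enrichments to
#' maximum 1, making it comparable across datasets; `P` and the relative
#' RMSE are invariant to rescaling the enrichments, while `scale` scales
#' along with them.
#'
#' @param relAffinity Numeric vector of per-site relative affinities (at
#'   least 3 distinct values).
#' @param enrichment Numeric vector of per-site enrichments.
#' @return A [ChipSaturationFit-class].
#' @export
fitChipSaturation <- function(relAffinity, enrichment) {
  stopifnot(length(relAffinity) == length(enrichment))
  if (length(unique(relAffinity)) < 3L)
    stop("degenerate input: need at least 3 sites with distinct affinities")
  a <- relAffinity
  y <- enrichment
  best <- NULL
  for (P0 in 10^(-2:2) / stats::median(a[a > 0])) {
    fit <- try(minpack.lm::nlsLM(
      y ~ s * P * a / (P * a + 1),
      start = list(P = P0, s = max(y)),
      lower = c(P = 1e-12, s = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("saturation fit failed to converge")
  co <- stats::coef(best$fit)
  pred <- co["s"] * co["P"] * a / (co["P"] * a + 1)
  mx <- max(y)
  new("ChipSaturationFit", freeProtein = unname(co["P"]),
      scale = unname(co["s"]), rmse = sqrt(mean((y / mx - pred / mx)^2)),
      fitted = pred)
}
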