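#' Fit the sub-region intolerance model (subRVIS)
#'
#' Fits, jointly across all sub-regions genome-wide, an ordinary
#' least-squares regression of the count of common functional variants
#' (non-synonymous, minor allele frequency > 0.1%) on the total count of
#' qualifying variants in each sub-region. Each sub-region's intolerance
#' score is its studentized residual from this fit: the departure of its
#' observed common functional variation from the expectation given its total
#' variation. Lower scores indicate more intolerant regions. Raw residuals
#' are, by construction, orthogonal to the total variant tally.
#'
#' @param counts data frame with columns `total_variants` and
#'   `common_functional`, one row per sub-region (as produced by
#'   [tally_region_counts()]); extra identifying columns (`gene_id`,
#'   `region_index`, `label`) are carried into the score table.
#' @param studentize `"external"` (leave-one-out variance, the default) or
#'   `"internal"`.
#' @return An object of class `"subrvis"`: a list with the OLS `fit`, the
#'   `scores` vector, a `score_table` data frame (input columns plus
#'   `score`), and the studentization used. Methods: `print`, `summary`,
#'   `coef`, `residuals`, `fitted`, `predict`, `plot`, `simulate`, `nobs`.
#' @examples
#' cts <- data.frame(total_variants = c(10, 20, 30, 10, 20, 30),
#'                   common_functional = c(1, 2, 3, 3, 0, 5))
#' m <- subrvis(cts)
#' round(m$scores, 3)
#' @export
subrvis <- function(counts, studentize = c("external", "internal")) {
  studentize <- match.arg(studentize)
  stopifnot(all(c("total_variants", "common_functional") %in% names(counts)))
  if (nrow(counts) < 3)
    .stopf("need at least 3 sub-regions with data to fit the regression")
  if (stats::var(counts$total_variants) == 0)
    .stopf("degenerate design: total_variants has zero variance")
  fit <- stats::lm(common_functional ~ total_variants, data = counts)
  scores <- if (studentize == "external") stats::rstudent(fit)
            else stats::rstandard(fit)
  # numerically zero residuals (exactly collinear data) studentize to garbage
  # through a ~zero leave-one-out variance; a zero residual is a zero score
  e <- stats::residuals(fit)
  zero <- abs(e) < 1e-10 * (max(abs(counts$common_functional)) + 1)
  scores[zero & !is.finite(scores)] <- 0
  if (all(zero)) scores[] <- 0
  score_table <- counts
  score_table$score <- unname(scores)
  structure(list(fit = fit, scores = unname(scores),
                 score_table = score_table, studentize = studentize,
                 call = match.call()),
            class = "subrvis")
}

#' @export
print.subrvis <- function(x, ...) {
  cat("Sub-region intolerance model (studentized-residual scores)\n")
  cat(sprintf("  %d sub-regions; studentization: %s\n",
              nobs(x), x$studentize))
  cf <- stats::coef(x$fit)
  cat(sprintf("  common_functional = %.4f + %.4f * total_variants\n",
              cf[1], cf[2]))
  cat("  score quantiles:\n")
  print(round(stats::quantile(x$scores, c(0, .25, .5, .75, 1)), 3))
  invisible(x)
}

#' @export
summary.subrvis <- function(object, ...) {
  structure(list(lm_summary = summary(object$fit),
                 score_summary = summary(object$scores),
                 studentize = object$studentize,
                 n = nobs(object)),
            class = "summary.subrvis")
}

#' @export
print.summary.subrvis <- function(x, ...) {
  cat(sprintf("Sub-region intolerance model over %d regions (%s studentization)\n\n",
              x$n, x$studentize))
  print(x$lm_summary)
  cat("Score distribution:\n")
  print(x$score_summary)
  invisible(x)
}

#' @export
coef.subrvis <- function(object, ...) stats::coef(object$fit)

#' @export
nobs.subrvis <- function(object, ...) length(object$scores)

#' @export
fitted.subrvis <- function(object, ...) stats::fitted(object$fit)

#' Residuals of a sub-region intolerance model
#' @param object a [subrvis()] fit.
#' @param type `"studentized"` (the scores) or `"raw"` (OLS residuals).
#' @param ... unused.
#' @export
residuals.subrvis <- function(object, type = c("studentized", "raw"), ...) {
  type <- match.arg(type)
  if (type == "raw") unname(stats::residuals(object$fit)) else object$scores
}

#' Predict expected common functional variant counts
#' @param object a [subrvis()] fit.
#' @param newdata data frame with a `total_variants` column; defaults to the
#'   training counts.
#' @param ... unused.
#' @export
predict.subrvis <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
simulate.subrvis <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Plot a sub-region intolerance fit
#'
#' Scatter of common functional against total variant counts with the fitted
#' regression line; points are shaded by score so intolerant regions (low
#' scores, below the line) stand out.
#'
#' @param x a [subrvis()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.subrvis <- function(x, ...) {
  d <- x$score_table
  shade <- cut(x$scores, breaks = stats::quantile(x$scores, 0:4 / 4),
               include.lowest = TRUE)
  graphics::plot(d$total_variants, d$common_functional,
                 col = grDevices::grey.colors(4)[shade], pch = 19,
                 xlab = "total variants in sub-region",
                 ylab = "common functional variants", ...)
  graphics::abline(x$fit, lwd = 2)
  invisible(x)
}

#' Per-gene variability of sub-region intolerance scores
#'
#' Summarizes, per gene, how much intolerance varies among its sub-regions
#' as the sample standard deviation of the gene's scores. Genes with fewer
#' than `min_regions` scored sub-regions are not assessed (`NA`).
#'
#' @param score_table data frame with `gene_id` and `score` columns (e.g.
#'   `$score_table` of a [subrvis()] fit over tallied counts).
#' @param min_regions minimal number of scored sub-regions (default 3).
#' @return Data frame with columns `gene_id`, `n_regions`, `variability`.
#' @export
gene_variability_score <- function(score_table, min_regions = 3) {
  sp <- split(score_table$score, score_table$gene_id)
  data.frame(
    gene_id = names(sp),
    n_regions = vapply(sp, length, integer(1)),
    variability = vapply(sp, function(s)
      if (length(s) >= min_regions) stats::sd(s) else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
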