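#' Genome-wide logistic model of pathogenic-variant presence
#'
#' Fits, across all sub-regions of the tested genes, the logistic regression
#' `logit(Pr(Y = 1)) = alpha + beta1 * log(Z) + beta2 * X`, where `Y` flags
#' presence of at least one non-LoF pathogenic variant in the region, `Z` is
#' the region's sequence-composition mutation rate and `X` one or more
#' intolerance score vectors. Each score is scaled by its own standard
#' deviation (population convention, over all supplied regions) so `beta2`
#' — the "score effect size" — is per score SD. The natural log is used.
#' A genic score constant within genes is just another score column.
#'
#' The analysis is meant to be restricted upstream to genes carrying at
#' least one reported pathogenic variant (regions of genes with no
#' pathogenic variant carry no localization information).
#'
#' @param Y binary presence vector (length n >= 10).
#' @param Z positive mutation rates.
#' @param X numeric vector, matrix or data frame of score columns.
#' @param scale_scores scale each score by its SD first (default `TRUE`).
#' @return Object of class `"genome_fit"`: coefficients, standard errors,
#'   Wald `p_values`, `aic`, `loglik`, `n`, the underlying `glm` fit and the
#'   score scaling used. Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `nobs`.
#' @export
fit_region_model <- function(Y, Z, X, scale_scores = TRUE) {
  if (is.atomic(X) && is.null(dim(X))) X <- data.frame(score = X)
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("score", seq_along(X))
  n <- length(Y)
  if (n < 10) .stopf("need at least 10 regions")
  if (length(Z) != n || nrow(X) != n) .stopf("Y, Z and scores must align")
  if (any(Z <= 0)) .stopf("mutation rates must be positive")
  if (all(Y == 0) || all(Y == 1)) .stopf("degenerate response: Y has no variation")
  sds <- vapply(X, .pop_sd, numeric(1))
  if (any(sds == 0)) .stopf("zero-variance score: %s",
                            paste(names(X)[sds == 0], collapse = ", "))
  if (scale_scores) X[] <- Map(`/`, X, sds)
  d <- data.frame(Y = Y, log_Z = log(Z), X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(Y ~ ., data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged || any(abs(stats::coef(fit)) > 30, na.rm = TRUE))
    .stopf("perfect separation detected; fit rejected", class = "srvis_separation")
  sm <- summary(fit)$coefficients
  structure(list(coefficients = stats::coef(fit),
                 se = sm[, "Std. Error"],
                 p_values = sm[, "Pr(>|z|)"],
                 aic = stats::AIC(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 n = n, score_names = names(X), score_sds = sds,
                 scaled = scale_scores, fit = fit),
            class = "genome_fit")
}

#' @export
print.genome_fit <- function(x, ...) {
  cat(sprintf("Genome-wide logistic fit over %d sub-regions (AIC %.3f)\n",
              x$n, x$aic))
  tab <- cbind(estimate = x$coefficients, se = x$se, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.genome_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.genome_fit <- function(object, ...) object$coefficients

#' @export
nobs.genome_fit <- function(object, ...) object$n

#' @export
predict.genome_fit <- function(object, newdata = NULL, type = "response", ...) {
  stats::predict(object$fit, newdata = newdata, type = type, ...)
}

#' @export
residuals.genome_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' Score effect size and its Wald p-value
#' @param fit a [fit_region_model()] result.
#' @param score score column name; defaults to the first score.
#' @return Named list `beta2`, `p`.
#' @export
score_effect <- function(fit, score = fit$score_names[1]) {
  list(beta2 = unname(fit$coefficients[score]),
       p = unname(fit$p_values[score]))
}

#' Mutability-weighted resampling of the presence vector
#'
#' Generates null response vectors that keep the observed number of
#' pathogenic regions but re-assign which regions they are, with more
#' mutable regions more likely to receive a 1: positions are drawn as a
#' weighted sample without replacement of size `sum(Y)` with probabilities
#' proportional to `Z` (successive draws renormalized over the remaining
#' regions). Every resample has exactly `sum(Y)` ones.
#'
#' @param Y observed binary presence vector.
#' @param Z positive mutation rates.
#' @param R number of resamples (default 1000).
#' @param seed RNG seed.
#' @return `n x R` integer matrix of resampled response vectors.
#' @export
resample_response <- function(Y, Z, R = 1000, seed = 1) {
  k <- sum(Y)
  if (k == 0) .stopf("Y contains no pathogenic region; nothing to resample")
  n <- length(Y)
  set.seed(as.integer(seed))
  out <- matrix(0L, nrow = n, ncol = R)
  for (r in seq_len(R)) out[sample.int(n, k, prob = Z), r] <- 1L
  out
}

#' Resampling p-value for the genome-wide fit
#'
#' Compares the observed score p-value with the p-values obtained on
#' mutability-resampled response vectors: with `C` the number of null
#' p-values strictly larger than the observed one, the resampling p-value is
#' `(R - C + 1) / (R + 1)`.
#'
#' @param observed_p Wald p-value of the score on the observed data.
#' @param null_ps p-values from the `R` resampled fits.
#' @return The resampling p-value, in (0, 1].
#' @export
resampling_pvalue <- function(observed_p, null_ps) {
  R <- length(null_ps)
  C <- sum(null_ps > observed_p)
  (R - C + 1) / (R + 1)
}

#' Full genome-wide test with resampling null
#'
#' Fits the observed model, refits it against `R` mutability-resampled
#' response vectors, and summarizes the score's effect size, Wald p-value
#' and resampling p-value.
#'
#' @inheritParams fit_region_model
#' @param R number of resamples.
#' @param seed RNG seed.
#' @param score which score column the resampling p-value refers to.
#' @return List: `fit` (the observed [fit_region_model()]), `beta2`, `p`,
#'   `resampling_p`, `null_ps`.
#' @export
genome_resampling_test <- function(Y, Z, X, R = 1000, seed = 1, score = NULL) {
  fit <- fit_region_model(Y, Z, X)
  if (is.null(score)) score <- fit$score_names[1]
  obs <- score_effect(fit, score)
  Ystar <- resample_response(Y, Z, R = R, seed = seed)
  null_ps <- vapply(seq_len(R), function(r) {
    f <- fit_region_model(Ystar[, r], Z, X)
    score_effect(f, score)$p
  }, numeric(1))
  list(fit = fit, beta2 = obs$beta2, p = obs$p,
       resampling_p = resampling_pvalue(obs$p, null_ps), null_ps = null_ps)
}

#' Relative AIC probability of two models
#'
#' `p = exp((AIC_min - AIC_max) / 2)`: the relative probability that the
#' model with the larger AIC minimizes information loss compared with the
#' lower-AIC model. Monotone decreasing in `|AIC_a - AIC_b|`; equal AICs
#' give `p = 1`.
#'
#' @param aic_a,aic_b AIC values of two fitted models.
#' @param labels optional model names, used to report the minimal model.
#' @return List `minimal` (label or index of the lower-AIC model) and `p`.
#' @export
aic_probability <- function(aic_a, aic_b, labels = c("a", "b")) {
  stopifnot(is.finite(aic_a), is.finite(aic_b))
  list(minimal = labels[which.min(c(aic_a, aic_b))],
       p = exp((min(aic_a, aic_b) - max(aic_a, aic_b)) / 2))
}

#' Permutation p-value for the biological vs random division
#'
#' Given the score effect size of the biological division and effect sizes
#' from `n_p` size-preserving random re-divisions of every gene (each
#' obtained by re-running region permutation, rescoring and refitting), the
#' p-value is `(n_p - K + 1) / (n_p + 1)`, where `K` counts permuted effect
#' sizes strictly smaller in absolute value than the biological one.
#'
#' @param biological_beta2 score effect size of the biological division.
#' @param permuted_beta2s effect sizes of the permuted divisions.
#' @return The permutation p-value.
#' @export
division_permutation_test <- function(biological_beta2, permuted_beta2s) {
  n_p <- length(permuted_beta2s)
  K <- sum(abs(permuted_beta2s) < abs(biological_beta2))
  (n_p - K + 1) / (n_p + 1)
}
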