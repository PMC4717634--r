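#' Expected pathogenic-variant counts under the mutability null
#'
#' Distributes a gene's total pathogenic tally across its sub-regions in
#' proportion to their mutation rates: `E_i = sum(Y) * Z_i / sum(Z)`. The
#' expected counts sum to the observed total exactly.
#'
#' @param Y integer vector of per-region pathogenic counts.
#' @param Z positive vector of per-region mutation rates.
#' @return Numeric vector of expected counts.
#' @export
expected_counts <- function(Y, Z) {
  if (length(Y) != length(Z)) .stopf("Y and Z must have equal length")
  sz <- sum(Z)
  if (sz <= 0) .stopf("mutation rates sum to zero")
  sum(Y) * Z / sz
}

#' Covariance of the pathogenic departure with the intolerance score
#'
#' The per-gene test statistic: the sample covariance (n-1 denominator) of
#' `D = Y - E` — each region's departure of observed from expected
#' pathogenic counts — with the region intolerance scores `X`. When
#' pathogenic excess concentrates in low-scoring (intolerant) regions the
#' covariance is negative.
#'
#' @param Y observed counts.
#' @param E expected counts (see [expected_counts()]).
#' @param X intolerance scores.
#' @return The covariance statistic.
#' @export
departure_covariance <- function(Y, E, X) {
  if (length(Y) < 2) .stopf("need at least 2 regions")
  stats::cov(Y - E, X)
}

#' Gene-specific multinomial permutation test
#'
#' Tests whether a gene's intolerance scores predict where its reported
#' pathogenic variants fall, beyond regional mutability. The observed
#' statistic is [departure_covariance()]. Under the null, pathogenic
#' variants are re-placed by drawing from
#' `Multinomial(sum(Y), Z / sum(Z))` `n_p` times; with `G` the number of
#' permutations whose statistic is less than or equal to the observed one
#' (inclusive tail), the p-value is `(G + 1) / (n_p + 1)`.
#'
#' Genes with fewer than two regions, no pathogenic variant, a non-positive
#' mutation rate, or a missing score are not assessed: the result carries a
#' `skip_reason` instead of a p-value.
#'
#' @param gene_id gene identifier (also seeds the per-gene RNG substream).
#' @param Y per-region pathogenic counts.
#' @param Z per-region mutation rates.
#' @param X per-region intolerance scores.
#' @param n_p number of permutations (default 20000).
#' @param seed run seed; combined with `gene_id` into a deterministic
#'   substream so results do not depend on gene processing order.
#' @return A list of class `"gene_test"`: `gene_id`, `n_regions`, `C_g`,
#'   `G`, `n_permutations`, `p_value`, `skip_reason` (`NA` when assessed).
#' @export
gene_permutation_test <- function(gene_id, Y, Z, X, n_p = 20000, seed = 1) {
  skip <- function(reason)
    structure(list(gene_id = gene_id, n_regions = length(Y), C_g = NA_real_,
                   G = NA_integer_, n_permutations = n_p, p_value = NA_real_,
                   skip_reason = reason), class = "gene_test")
  if (length(Y) < 2) return(skip("fewer than two regions"))
  if (sum(Y) < 1) return(skip("no reported pathogenic variant"))
  if (any(!is.finite(Z)) || any(Z <= 0)) return(skip("non-positive mutation rate"))
  if (any(!is.finite(X))) return(skip("missing intolerance score"))
  prob <- Z / sum(Z)
  E <- sum(Y) * prob
  # cov(D, X) reduces to (sum(Y*Xc) - sum(E*Xc)) / (n-1) with Xc centered;
  # observed and permuted statistics use the identical arithmetic so that a
  # permutation reproducing Y ties the observed value exactly (inclusive tail)
  Xc <- X - mean(X)
  eXc <- sum(E * Xc)
  C_g <- (sum(Y * Xc) - eXc) / (length(Y) - 1)
  set.seed(.gene_seed(seed, gene_id))
  Ystar <- stats::rmultinom(n_p, size = sum(Y), prob = prob)
  Cstar <- (colSums(Ystar * Xc) - eXc) / (length(Y) - 1)
  G <- sum(Cstar <= C_g)
  structure(list(gene_id = gene_id, n_regions = length(Y), C_g = C_g,
                 G = G, n_permutations = n_p,
                 p_value = (G + 1) / (n_p + 1), skip_reason = NA_character_),
            class = "gene_test")
}

#' @export
print.gene_test <- function(x, ...) {
  if (!is.na(x$skip_reason)) {
    cat(sprintf("<gene_test> %s: skipped (%s)\n", x$gene_id, x$skip_reason))
  } else {
    cat(sprintf("<gene_test> %s: %d regions, C_g = %.4g, p = %.4g (%d permutations)\n",
                x$gene_id, x$n_regions, x$C_g, x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p p-values in (0, 1].
#' @return FDR-adjusted p-values (monotone, capped at 1).
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Run the gene-specific test across a cohort
#'
#' Applies [gene_permutation_test()] to every gene and FDR-adjusts the
#' p-values of the assessed genes.
#'
#' @param pathogenic per-region counts from [tally_pathogenic()].
#' @param rates per-region rates from [region_mutation_rates()].
#' @param scores data frame `gene_id`, `region_index`, `score` (e.g. the
#'   `score_table` of a [subrvis()] fit).
#' @param n_p permutations per gene (default 20000).
#' @param seed run seed.
#' @return Data frame with one row per gene: `gene_id`, `n_regions`, `C_g`,
#'   `p_value`, `fdr_p`, `skip_reason`.
#' @export
gene_test_cohort <- function(pathogenic, rates, scores, n_p = 20000, seed = 1) {
  key <- function(d) paste(d$gene_id, d$region_index)
  z <- rates$mutation_rate[match(key(pathogenic), key(rates))]
  x <- scores$score[match(key(pathogenic), key(scores))]
  res <- lapply(split(seq_len(nrow(pathogenic)), pathogenic$gene_id), function(i) {
    i <- i[order(pathogenic$region_index[i])]  # row order must not matter
    r <- gene_permutation_test(pathogenic$gene_id[i[1]], pathogenic$count[i],
                               z[i], x[i], n_p = n_p, seed = seed)
    data.frame(gene_id = r$gene_id, n_regions = r$n_regions, C_g = r$C_g,
               p_value = r$p_value, skip_reason = r$skip_reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$fdr_p <- NA_real_
  assessed <- is.na(out$skip_reason)
  out$fdr_p[assessed] <- fdr_adjust(out$p_value[assessed])
  out[, c("gene_id", "n_regions", "C_g", "p_value", "fdr_p", "skip_reason")]
}
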