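#' Variant-level effect score for de novo mutations
#'
#' Synonymous variants score 0; canonical splice, stop gain and stop loss
#' score 1; missense variants take their PolyPhen-2 HumVar probability.
#' Missense variants lacking a HumVar score get `NA` and are excluded
#' downstream.
#'
#' @param consequence character vector in `{"synonymous", "missense",
#'   "canonical_splice", "stop_gain", "stop_loss", "other"}`.
#' @param polyphen2_humvar HumVar scores in `[0, 1]` (`NA` when absent).
#' @return Numeric vector of effect scores in `[0, 1]` (`NA` where
#'   undefined).
#' @export
variant_effect_score <- function(consequence, polyphen2_humvar = NA_real_) {
  out <- rep(NA_real_, length(consequence))
  out[consequence == "synonymous"] <- 0
  out[consequence %in% c("canonical_splice", "stop_gain", "stop_loss")] <- 1
  mis <- consequence == "missense"
  out[mis] <- polyphen2_humvar[mis]
  out
}

#' Percentile of each score within a score distribution
#'
#' The percentile of a region's score among all scored regions of the
#' division: the percentage of scores less than or equal to it. Lower
#' (more intolerant) scores get lower percentiles.
#'
#' @param scores scores to place.
#' @param reference the genome-wide score distribution (defaults to
#'   `scores` itself).
#' @return Percentiles in (0, 100].
#' @export
score_percentile <- function(scores, reference = scores) {
  reference <- reference[is.finite(reference)]
  vapply(scores, function(s)
    if (!is.finite(s)) NA_real_ else 100 * mean(reference <= s), numeric(1))
}

#' Hot-zone classification
#'
#' A mutation is a hot-zone mutation when it is likely damaging at the
#' variant level (effect score >= 0.95) and falls in an intolerant region
#' (score percentile <= 25). Both thresholds are inclusive. Missing inputs
#' classify as `FALSE`.
#'
#' @param effect_score variant effect scores (see [variant_effect_score()]).
#' @param region_score_percentile percentile of the containing region's
#'   intolerance score (see [score_percentile()]).
#' @param effect_min damaging threshold (default 0.95).
#' @param percentile_max intolerance percentile threshold (default 25).
#' @return Logical vector.
#' @export
classify_hot_zone <- function(effect_score, region_score_percentile,
                              effect_min = 0.95, percentile_max = 25) {
  out <- !is.na(effect_score) & !is.na(region_score_percentile) &
    effect_score >= effect_min & region_score_percentile <= percentile_max
  out
}

#' Case/control hot-zone enrichment
#'
#' Two-sided Fisher's exact test on the 2x2 table of hot-zone vs other de
#' novo mutations in cases and controls.
#'
#' @param case_hot,case_total hot-zone and total counts among case
#'   mutations.
#' @param control_hot,control_total the same among control mutations.
#' @return List: `odds_ratio` (conditional MLE; `NA` if a margin is zero),
#'   `p`, and the 2x2 `table`.
#' @export
hotzone_enrichment <- function(case_hot, case_total, control_hot, control_total) {
  stopifnot(case_hot <= case_total, control_hot <= control_total)
  tab <- matrix(c(case_hot, case_total - case_hot,
                  control_hot, control_total - control_hot),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("hot", "other")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p = 1, table = tab))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Convert Bayes-classifier pathogenicity predictions to a 0-1 score
#'
#' Maps (prediction, probability) pairs from a polymorphism/disease-causing
#' classifier to a single score where 0 is confidently deleterious and 1
#' confidently harmless: a `polymorphism` prediction keeps its probability
#' (range 0.5-1), a `disease_causing` prediction scores `1 - probability`
#' (range 0-0.5). The `_automatic` variants are database-backed labels; when
#' the classifier disagrees with them (probability < 0.5) the prediction is
#' flipped and the probability replaced by `1 - probability` before the
#' rule above is applied.
#'
#' @param prediction one of `disease_causing`, `disease_causing_automatic`,
#'   `polymorphism`, `polymorphism_automatic` (vectorized).
#' @param probability classifier probability in (0, 1].
#' @return Scores in `[0, 1]`.
#' @export
mutationtaster_score <- function(prediction, probability) {
  known <- c("disease_causing", "disease_causing_automatic",
             "polymorphism", "polymorphism_automatic")
  if (any(!prediction %in% known))
    .stopf("unknown prediction: %s",
           paste(setdiff(prediction, known), collapse = ", "))
  stopifnot(all(probability > 0), all(probability <= 1))
  pred <- sub("_automatic$", "", prediction)
  auto <- grepl("_automatic$", prediction)
  flip <- auto & probability < 0.5
  pred[flip] <- ifelse(pred[flip] == "polymorphism", "disease_causing", "polymorphism")
  probability[flip] <- 1 - probability[flip]
  ifelse(pred == "polymorphism", probability, 1 - probability)
}

#' Filter de novo mutations for the hot-zone analysis
#'
#' Removes mutations observed as standing variants in the reference
#' population cohort, and optionally applies multi-institute validation
#' rules for family-based calls: a mutation must not be called in both
#' siblings, and either at least one institute validated it, or at least
#' one institute labelled it a `strong` call while no institute labelled it
#' `not_called` or `weak`.
#'
#' @param mutations data frame with columns `chrom`, `pos`, `consequence`,
#'   `polyphen2_humvar`, `cohort` (`"case"`/`"control"`), and — when
#'   `validation_rules = TRUE` — `in_both_siblings` (logical) and
#'   `institute_labels` (comma-separated labels among `validated`, `strong`,
#'   `weak`, `not_called`, or free text).
#' @param population_positions data frame `chrom`, `pos` of known population
#'   variant sites, or `NULL`.
#' @param validation_rules apply the sibling/validation logic (default
#'   `FALSE`; appropriate for cohorts whose calls are already all
#'   validated).
#' @return The retained subset.
#' @export
filter_denovo <- function(mutations, population_positions = NULL,
                          validation_rules = FALSE) {
  keep <- rep(TRUE, nrow(mutations))
  if (!is.null(population_positions) && nrow(population_positions) > 0) {
    keep <- keep & !(paste(mutations$chrom, mutations$pos) %in%
                     paste(population_positions$chrom, population_positions$pos))
  }
  if (validation_rules) {
    labels <- lapply(strsplit(mutations$institute_labels, ",", fixed = TRUE), trimws)
    validated <- vapply(labels, function(l) "validated" %in% l, logical(1))
    strong_ok <- vapply(labels, function(l)
      "strong" %in% l && !any(c("weak", "not_called") %in% l), logical(1))
    keep <- keep & !mutations$in_both_siblings & (validated | strong_ok)
  }
  mutations[keep, , drop = FALSE]
}

#' Hot-zone analysis of a de novo mutation set
#'
#' Assigns each mutation the intolerance score of the sub-region containing
#' it, computes effect scores and hot-zone flags, and tests case/control
#' enrichment. Mutations in regions without a score are excluded from both
#' numerator and denominator.
#'
#' @param mutations filtered de novo mutations (see [filter_denovo()]).
#' @param regions cohort [region_table].
#' @param scores data frame `gene_id`, `region_index`, `score`.
#' @param models named list of [gene_model()] objects.
#' @inheritParams classify_hot_zone
#' @return List: per-mutation data frame (`flags`) with effect score,
#'   percentile and hot-zone flag, and the [hotzone_enrichment()] summary.
#' @export
hotzone_analysis <- function(mutations, regions, scores, models,
                             effect_min = 0.95, percentile_max = 25) {
  key <- paste(regions$gene_id, regions$region_index)
  skey <- paste(scores$gene_id, scores$region_index)
  region_score <- rep(NA_real_, nrow(mutations))
  for (gid in unique(regions$gene_id)) {
    gm <- models[[gid]]
    span <- range(gm$exons)
    cand <- which(mutations$chrom == gm$chrom &
                  mutations$pos >= span[1] & mutations$pos < span[2])
    if (!length(cand)) next
    ridx <- assign_positions_to_regions(
      gm, regions[regions$gene_id == gid, , drop = FALSE], mutations$pos[cand])
    hit <- !is.na(ridx)
    region_score[cand[hit]] <- scores$score[match(paste(gid, ridx[hit]), skey)]
  }
  eff <- variant_effect_score(mutations$consequence, mutations$polyphen2_humvar)
  pct <- score_percentile(region_score, reference = scores$score)
  flags <- data.frame(mutations, effect_score = eff, percentile = pct,
                      hot_zone = classify_hot_zone(eff, pct, effect_min,
                                                   percentile_max),
                      stringsAsFactors = FALSE)
  scored <- !is.na(region_score) & !is.na(eff)
  f <- flags[scored, , drop = FALSE]
  enr <- hotzone_enrichment(sum(f$hot_zone & f$cohort == "case"),
                            sum(f$cohort == "case"),
                            sum(f$hot_zone & f$cohort == "control"),
                            sum(f$cohort == "control"))
  list(flags = flags, enrichment = enr)
}
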