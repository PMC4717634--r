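test_that("variant effect scores follow the consequence rules", {
  expect_equal(variant_effect_score("synonymous"), 0)
  expect_equal(variant_effect_score(c("canonical_splice", "stop_gain", "stop_loss")),
               rep(1, 3))
  expect_equal(variant_effect_score("missense", 0.97), 0.97)
  expect_true(is.na(variant_effect_score("missense", NA)))
  expect_true(is.na(variant_effect_score("other", 0.5)))
})

test_that("hot-zone thresholds are inclusive and missing-safe", {
  expect_true(classify_hot_zone(0.95, 25.0))
  expect_false(classify_hot_zone(0.949, 10))
  expect_false(classify_hot_zone(1.0, 26))
  expect_false(classify_hot_zone(NA, 10))
  expect_false(classify_hot_zone(1, NA))
  # monotonicity: tightening the percentile never adds hot-zone calls
  set.seed(14)
  eff <- runif(200); pct <- runif(200, 0, 100)
  n_hot <- vapply(c(50, 25, 10, 5), function(th)
    sum(classify_hot_zone(eff, pct, percentile_max = th)), integer(1))
  expect_true(all(diff(n_hot) <= 0))
})

test_that("score percentiles rank intolerant regions low", {
  s <- c(-2, -1, 0, 1, 2)
  p <- score_percentile(s)
  expect_equal(p, c(20, 40, 60, 80, 100))
  expect_equal(score_percentile(-2, reference = s), 20)
  expect_true(is.na(score_percentile(NA_real_, reference = s)))
})

test_that("enrichment matches Fisher and the hypergeometric oracle", {
  enr <- hotzone_enrichment(77, 366, 212, 1345)
  expect_equal(round(enr$p, 3), 0.018)
  expect_lt(abs(enr$p - oracle_fisher_two_sided(77, 366 - 77, 212, 1345 - 212)),
            1e-10)
  expect_equal(hotzone_enrichment(10, 100, 10, 100)$p, 1.0)
  small <- hotzone_enrichment(5, 10, 0, 10)
  expect_lt(abs(small$p - oracle_fisher_two_sided(5, 5, 0, 10)), 1e-10)
  zero <- hotzone_enrichment(0, 0, 0, 10)
  expect_equal(zero$p, 1)
  expect_true(is.na(zero$odds_ratio))
})

test_that("prediction-to-score conversion maps onto the two half-ranges", {
  expect_equal(mutationtaster_score("polymorphism", 0.8), 0.8)
  expect_equal(mutationtaster_score("disease_causing", 0.8), 0.2)
  # automatic labels disagreeing with the classifier are flipped first
  expect_equal(mutationtaster_score("disease_causing_automatic", 0.3), 0.7)
  expect_equal(mutationtaster_score("polymorphism_automatic", 0.3), 1 - 0.7)
  expect_equal(mutationtaster_score("polymorphism_automatic", 0.9), 0.9)
  expect_equal(mutationtaster_score("disease_causing_automatic", 0.9), 0.1)
  expect_error(mutationtaster_score("benign", 0.5), "unknown prediction")
  # range invariant: disease-causing results in [0, .5], polymorphism in [.5, 1]
  set.seed(4)
  pred <- sample(c("disease_causing", "disease_causing_automatic",
                   "polymorphism", "polymorphism_automatic"), 200, replace = TRUE)
  # classifier-backed (non-automatic) predictions always report prob > 0.5;
  # only database-backed automatic labels can disagree with the classifier
  prob <- ifelse(grepl("automatic", pred), runif(200, 0.01, 1),
                 runif(200, 0.51, 1))
  s <- mutationtaster_score(pred, prob)
  expect_true(all(s >= 0 & s <= 1))
  flipped <- grepl("automatic", pred) & prob < 0.5
  eff_pred <- ifelse(flipped, ifelse(grepl("polymorphism", pred),
                                     "disease_causing", "polymorphism"),
                     sub("_automatic", "", pred))
  expect_true(all(s[eff_pred == "disease_causing"] <= 0.5))
  expect_true(all(s[eff_pred == "polymorphism"] >= 0.5))
})

test_that("de novo filtering removes population hits and failed validations", {
  dn <- data.frame(chrom = "chr1", pos = 1:5,
                   consequence = "missense", polyphen2_humvar = 0.9,
                   cohort = "case",
                   in_both_siblings = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                   institute_labels = c("validated", "strong,weak", "strong",
                                        "validated", "strong,low_conf"),
                   stringsAsFactors = FALSE)
  popn <- data.frame(chrom = "chr1", pos = 1)
  f <- filter_denovo(dn, popn, validation_rules = TRUE)
  # pos1: population hit; pos2: strong+weak fails; pos4: in both siblings
  expect_equal(f$pos, c(3, 5))
  # without validation rules only the population exclusion applies
  expect_equal(filter_denovo(dn, popn)$pos, 2:5)
  expect_equal(nrow(filter_denovo(dn)), 5)
})

test_that("end-to-end hot-zone analysis assigns regions and tests enrichment", {
  co <- simulate_cohort(sim_config(n_genes = 120, seed = 31,
                                   n_case = 400, n_control = 800))
  counts <- tally_region_counts(qualify_sites(co$sites), co$regions, co$models)
  m <- subrvis(counts)
  dn <- filter_denovo(co$denovo, validation_rules = TRUE)
  hz <- hotzone_analysis(dn, co$regions, m$score_table, co$models)
  expect_equal(nrow(hz$flags), nrow(dn))
  expect_true(all(hz$flags$hot_zone %in% c(TRUE, FALSE)))
  expect_true(sum(hz$enrichment$table) <= nrow(dn))
  expect_true(hz$enrichment$p <= 1 && hz$enrichment$p > 0)
  # hot-zone calls require both thresholds
  called <- hz$flags[hz$flags$hot_zone, ]
  if (nrow(called)) {
    expect_true(all(called$effect_score >= 0.95))
    expect_true(all(called$percentile <= 25))
  }
})
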