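make_sites <- function(pos, cov = 60, filt = "PASS", af = 0.01,
                       cons = "nonsynonymous", variant = TRUE) {
  data.frame(chrom = "chr3", pos = pos, mean_coverage = cov,
             filter_status = filt, is_variant = variant, alt_af = af,
             consequence = cons, stringsAsFactors = FALSE)
}

test_that("site qualification enforces coverage and filter status", {
  s <- rbind(make_sites(1, cov = 9.9), make_sites(2, cov = 10),
             make_sites(3, filt = "LowQual"), make_sites(4))
  q <- qualify_sites(s)
  expect_equal(q$pos, c(2, 4))
  expect_equal(nrow(qualify_sites(s[0, ])), 0)
  # non-variant coverage records are not filter-checked
  covrec <- make_sites(5, filt = "", variant = FALSE)
  expect_equal(nrow(qualify_sites(covrec)), 1)
})

test_that("region tallies apply the strict common-MAF threshold", {
  gm <- single_exon_gene(300)
  regions <- build_exon_regions(gm)
  models <- list(TGS = gm)
  s <- rbind(make_sites(10, af = 0.0005), make_sites(20, af = 0.002),
             make_sites(30, af = 0.002, cons = "synonymous"))
  tal <- tally_region_counts(s, regions, models)
  expect_equal(tal$total_variants, 3)
  expect_equal(tal$common_functional, 1)
  # exactly at threshold is not common; folded frequency is used
  expect_equal(tally_region_counts(make_sites(10, af = 0.001), regions,
                                   models)$common_functional, 0)
  expect_equal(tally_region_counts(make_sites(10, af = 0.999), regions,
                                   models)$common_functional, 0)
  expect_equal(tally_region_counts(make_sites(10, af = 0.995), regions,
                                   models)$common_functional, 1)
  empty <- tally_region_counts(s[0, ], regions, models)
  expect_equal(empty$total_variants, 0)
  # sites outside every region are counted nowhere and logged
  out <- tally_region_counts(make_sites(5000), regions, models)
  expect_equal(out$total_variants, 0)
})

test_that("intolerance scores match an independent studentization oracle", {
  cts <- data.frame(total_variants = c(10, 20, 30, 10, 20, 30),
                    common_functional = c(1, 2, 3, 3, 0, 5))
  m <- subrvis(cts)
  expect_equal(m$scores,
               oracle_ext_studentized(cts$total_variants, cts$common_functional),
               tolerance = 1e-8)
  # internal studentization is available and differs
  mi <- subrvis(cts, studentize = "internal")
  expect_false(isTRUE(all.equal(mi$scores, m$scores)))
  # counts on an exact line give all-zero scores
  lin <- data.frame(total_variants = c(10, 20, 30, 40),
                    common_functional = 2 + 0.1 * c(10, 20, 30, 40))
  expect_equal(subrvis(lin)$scores, rep(0, 4))
  # intercept absorbs a constant shift: scores unchanged
  shifted <- cts; shifted$common_functional <- shifted$common_functional + 7
  expect_equal(subrvis(shifted)$scores, m$scores, tolerance = 1e-8)
  expect_error(subrvis(cts[1:2, ]), "at least 3")
  flat <- data.frame(total_variants = c(5, 5, 5), common_functional = 1:3)
  expect_error(subrvis(flat), "degenerate design")
})

test_that("raw residuals are orthogonal to the total variant tally", {
  co <- simulate_cohort(sim_config(n_genes = 80, seed = 5))
  counts <- tally_region_counts(qualify_sites(co$sites), co$regions, co$models)
  m <- subrvis(counts)
  expect_lt(abs(stats::cor(residuals(m, type = "raw"),
                           counts$total_variants)), 1e-10)
  expect_lt(abs(sum(residuals(m, type = "raw"))), 1e-8)
})

test_that("subrvis object supports the standard model methods", {
  cts <- data.frame(total_variants = c(10, 20, 30, 10, 20, 30),
                    common_functional = c(1, 2, 3, 3, 0, 5))
  m <- subrvis(cts)
  expect_s3_class(m, "subrvis")
  expect_length(coef(m), 2)
  expect_equal(nobs(m), 6)
  expect_equal(length(fitted(m)), 6)
  expect_equal(predict(m, data.frame(total_variants = 20)),
               unname(coef(m)[1] + 20 * coef(m)[2]))
  expect_output(print(m), "studentization")
  expect_output(print(summary(m)), "Score distribution")
  sim <- simulate(m, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(6, 2))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("conservation averaging handles sparse tracks", {
  gm <- toy_gene_minus()
  regions <- build_exon_regions(gm)
  # constant track -> every region scores the constant
  allpos <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    b <- parse_blocks(regions$blocks[i])
    unlist(lapply(seq_len(nrow(b)), function(k) seq(b[k, 1], b[k, 2] - 1)))
  }))
  const <- data.frame(chrom = "chr2", pos = allpos, score = 1.7)
  expect_equal(compute_subgerp(const, regions)$subgerp, rep(1.7, 3))
  # mean of available bases only; empty region -> NA
  b1 <- parse_blocks(regions$blocks[1])
  sparse <- data.frame(chrom = "chr2", pos = b1[1, "start"] + 0:1,
                       score = c(2, 4))
  sg <- compute_subgerp(sparse, regions)
  expect_equal(sg$subgerp[1], 3)
  expect_true(all(is.na(sg$subgerp[2:3])))
  # random sparse track equals a brute-force mean
  set.seed(21)
  keep <- sample(allpos, 200)
  tr <- data.frame(chrom = "chr2", pos = keep, score = rnorm(200))
  sg2 <- compute_subgerp(tr, regions)
  for (i in 1:3) {
    b <- parse_blocks(regions$blocks[i])
    pos <- unlist(lapply(seq_len(nrow(b)), function(k) seq(b[k, 1], b[k, 2] - 1)))
    expect_equal(sg2$subgerp[i], mean(tr$score[tr$pos %in% pos]))
  }
})

test_that("mutation rates sum context rates over region positions", {
  uni <- expand.grid(p = c("A", "C", "G", "T"), r = c("A", "C", "G", "T"),
                     n = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                     stringsAsFactors = FALSE)
  uni <- uni[uni$r != uni$alt, ]
  uni <- data.frame(context = paste0(uni$p, uni$r, uni$n), alt = uni$alt,
                    rate = 2e-8)
  # uniform table: rate = 3 * L * r
  expect_equal(as.numeric(compute_mutation_rate("AACGTA", uni)), 3 * 4 * 2e-8)
  # hand-summed toy: positions C (ctx ACG) and G (ctx CGT)
  toy <- data.frame(context = c("ACG", "ACG", "CGT"), alt = c("T", "G", "A"),
                    rate = c(1e-8, 5e-9, 2e-8))
  expect_equal(as.numeric(compute_mutation_rate("ACGT", toy)), 3.5e-8)
  # doubling the table doubles the rate
  toy2 <- toy; toy2$rate <- toy2$rate * 2
  expect_equal(as.numeric(compute_mutation_rate("ACGT", toy2)),
               2 * as.numeric(compute_mutation_rate("ACGT", toy)))
  # N contexts are skipped and counted
  withN <- compute_mutation_rate("ANCGT", toy)
  expect_equal(attr(withN, "skipped"), 2L)
  expect_equal(as.numeric(compute_mutation_rate("AC", toy)), 0)
  # per-region rates are positive with the default table
  gm <- single_exon_gene(30)
  seqs <- c(TGS = paste(rep("ACGT", 8), collapse = ""))
  rr <- region_mutation_rates(build_exon_regions(gm), seqs)
  expect_gt(rr$mutation_rate, 0)
})

test_that("gene variability score needs three regions and matches sd", {
  st <- data.frame(gene_id = c("A", "A", "B", "B", "B", "C", "C", "C"),
                   score = c(1, 2, 1, 1, 1, -1, 0, 1))
  v <- gene_variability_score(st)
  expect_true(is.na(v$variability[v$gene_id == "A"]))
  expect_equal(v$variability[v$gene_id == "B"], 0)
  expect_equal(v$variability[v$gene_id == "C"], 1)
})

test_that("suppressed regions recover lower scores across cohorts", {
  diffs <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(n_genes = 40, seed = 1000 + s))
    counts <- tally_region_counts(qualify_sites(co$sites), co$regions, co$models)
    m <- subrvis(counts)
    mean(m$score_table$score[co$truth$intolerant]) -
      mean(m$score_table$score[!co$truth$intolerant])
  }, numeric(1))
  tt <- t.test(diffs, alternative = "less")
  expect_lt(tt$p.value, 0.01)
})
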