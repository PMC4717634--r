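test_that("domain regions tile the CDS with terminal unaligned stretches", {
  gm <- single_exon_gene(900)
  aln <- data.frame(gene_id = "TGS", domain_id = c("d1", "d2"),
                    aa_start = c(10, 120), aa_end = c(50, 200),
                    evalue = c(1e-10, 1e-8), score = c(100, 80))
  r <- build_domain_regions(gm, aln)
  expect_equal(r$cds_start, c(0, 27, 150, 357, 600))
  expect_equal(r$cds_end, c(27, 150, 357, 600, 900))
  expect_equal(r$label, c("unaligned", "d1", "unaligned", "d2", "unaligned"))
  expect_equal(r$region_index, 1:5)
  expect_true(check_region_tiling(r, gm$cds_length))
})

test_that("a gene without alignments becomes a single unaligned region", {
  gm <- single_exon_gene(900)
  for (aln in list(NULL, data.frame(gene_id = character(0), domain_id = character(0),
                                    aa_start = integer(0), aa_end = integer(0),
                                    evalue = numeric(0), score = numeric(0)))) {
    r <- build_domain_regions(gm, aln)
    expect_equal(nrow(r), 1)
    expect_equal(r$label, "unaligned")
    expect_equal(c(r$cds_start, r$cds_end), c(0, 900))
  }
})

test_that("overlapping alignments resolve to the better bit score", {
  gm <- single_exon_gene(900)
  aln <- data.frame(gene_id = "TGS", domain_id = c("d1", "d2"),
                    aa_start = c(10, 40), aa_end = c(50, 90),
                    evalue = c(1e-10, 1e-8), score = c(100, 60))
  r <- build_domain_regions(gm, aln)
  expect_false("d2" %in% r$label)
  expect_equal(r$label[r$label != "unaligned"], "d1")
  # ties break by lower evalue, then lexicographic domain id
  aln2 <- data.frame(gene_id = "TGS", domain_id = c("dB", "dA"),
                     aa_start = c(10, 10), aa_end = c(50, 50),
                     evalue = c(1e-8, 1e-8), score = c(100, 100))
  r2 <- build_domain_regions(gm, aln2)
  expect_equal(r2$label[r2$label != "unaligned"], "dA")
})

test_that("E-value gate and CDS-overrun rejection are applied", {
  gm <- single_exon_gene(900)
  aln <- data.frame(gene_id = "TGS", domain_id = c("weak", "long"),
                    aa_start = c(10, 250), aa_end = c(50, 320),
                    evalue = c(0.5, 1e-9), score = c(90, 80))
  expect_warning(r <- build_domain_regions(gm, aln), "extend past the CDS")
  expect_equal(r$label, "unaligned")  # weak fails E-value, long overruns 300 aa
  expect_equal(attr(r, "rejected")$domain_id, "long")
  # zero-length gap between adjacent alignments produces no region
  adj <- data.frame(gene_id = "TGS", domain_id = c("a", "b"),
                    aa_start = c(1, 51), aa_end = c(50, 300),
                    evalue = c(1e-9, 1e-9), score = c(90, 80))
  r2 <- build_domain_regions(gm, adj)
  expect_equal(r2$label, c("a", "b"))
  expect_true(check_region_tiling(r2, 900))
})

test_that("exon regions follow transcription order on both strands", {
  gp <- toy_gene_plus()
  r <- build_exon_regions(gp)
  expect_equal(r$cds_start, c(0, 99, 300))
  expect_equal(r$cds_end, c(99, 300, 351))
  expect_equal(r$label, c("exon1", "exon2", "exon3"))
  one <- build_exon_regions(single_exon_gene(300))
  expect_equal(nrow(one), 1)
  expect_equal(one$cds_end, 300)
  # minus strand: first region is the 3'-most exon genomically
  gm <- toy_gene_minus()
  rm_ <- build_exon_regions(gm)
  b1 <- parse_blocks(rm_$blocks[1])
  expect_equal(unname(b1[1, ]), c(1000, 1051))
  # round-trip: every region's blocks map back to its CDS interval
  for (i in seq_len(nrow(rm_))) {
    b <- parse_blocks(rm_$blocks[i])
    pos <- unlist(lapply(seq_len(nrow(b)), function(k) seq(b[k, 1], b[k, 2] - 1)))
    cds <- sort(map_genomic_to_cds(gm, pos))
    expect_equal(cds, seq(rm_$cds_start[i], rm_$cds_end[i] - 1))
  }
})

test_that("CDS<->genomic mapping is a bijection on covered bases", {
  gp <- toy_gene_plus()
  expect_equal(nrow(map_cds_to_genomic(gp, 10, 50)), 1)   # inside exon 1
  spanning <- map_cds_to_genomic(gp, 90, 120)             # crosses intron 1
  expect_equal(nrow(spanning), 2)
  expect_equal(sum(spanning[, "end"] - spanning[, "start"]), 30)
  expect_error(map_cds_to_genomic(gp, 300, 400), "out of range")
  set.seed(11)
  for (rep in 1:25) {
    g <- random_gene_model(sprintf("R%02d", rep), sample(1:5, 1),
                           sample(c("+", "-"), 1))
    s <- sample.int(g$cds_length - 1, 1) - 1L
    e <- s + sample.int(g$cds_length - s, 1)
    b <- map_cds_to_genomic(g, s, e)
    expect_equal(sum(b[, "end"] - b[, "start"]), e - s)
    pos <- unlist(lapply(seq_len(nrow(b)), function(k) seq(b[k, 1], b[k, 2] - 1)))
    expect_setequal(map_genomic_to_cds(g, pos), s:(e - 1))
  }
})

test_that("size permutation conserves the region multiset and is seeded", {
  gm <- single_exon_gene(900)
  aln <- data.frame(gene_id = "TGS", domain_id = c("d1", "d2"),
                    aa_start = c(10, 120), aa_end = c(50, 200),
                    evalue = c(1e-10, 1e-8), score = c(100, 80))
  r <- build_domain_regions(gm, aln)
  p1 <- permute_region_sizes(r, seed = 5, gene = gm)
  expect_setequal(p1$cds_end - p1$cds_start, r$cds_end - r$cds_start)
  expect_equal(nrow(p1), nrow(r))
  expect_true(check_region_tiling(p1, 900))
  expect_identical(permute_region_sizes(r, seed = 5, gene = gm), p1)
  diffs <- vapply(1:20, function(s)
    !identical(permute_region_sizes(r, seed = s, gene = gm)$label, r$label),
    logical(1))
  expect_true(any(diffs))
  # single-region gene: output identical to input
  solo <- build_domain_regions(gm, NULL)
  expect_equal(permute_region_sizes(solo, seed = 1, gene = gm)$cds_end, 900)
})

test_that("gene model invariants and canonical transcript selection hold", {
  expect_error(gene_model("B", "chr1", "+", c(0, 50), c(60, 100)), "overlapping")
  expect_error(gene_model("B", "chr1", "*", 0, 30), "strand")
  expect_warning(gene_model("B", "chr1", "+", 0, 100), "not a multiple of 3")
  tx <- list(t2 = gene_model("G", "chr1", "+", 0, 300),
             t1 = gene_model("G", "chr1", "+", 0, 600),
             t3 = gene_model("G", "chr1", "+", 1000, 1600))
  # longest CDS wins; tie between t1 and t3 breaks to lexicographic id
  expect_identical(select_canonical_transcript(tx), tx$t1)
})

test_that("whole-cohort builders tile every gene and permute conservatively", {
  co <- simulate_cohort(sim_config(n_genes = 30, seed = 91))
  perm <- permute_regions(co$regions, co$models, seed = 17)
  for (g in names(co$models)) {
    rg <- co$regions[co$regions$gene_id == g, ]
    pg <- perm[perm$gene_id == g, ]
    check_region_tiling(rg, co$models[[g]]$cds_length)
    check_region_tiling(pg, co$models[[g]]$cds_length)
    expect_setequal(pg$cds_end - pg$cds_start, rg$cds_end - rg$cds_start)
  }
})
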