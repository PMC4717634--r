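#' Configuration for a synthetic cohort
#'
#' Defines the study conditions for a fully synthetic cohort with planted
#' regional-intolerance structure: gene architecture, population-variant
#' density, how strongly common functional variation is suppressed in
#' intolerant regions, and how strongly pathogenic variants are enriched
#' toward them. Defaults emulate human coding-gene scale — a few coding
#' exons of mean length ~170 nt, around five sub-regions per gene, roughly
#' one variant site per 20 coding bases in the reference cohort — with
#' clear but not extreme planted structure (20% intolerant regions,
#' five-fold suppression and enrichment).
#'
#' @param n_genes number of genes (default 200).
#' @param exons_per_gene_lambda Poisson mean for (exon count - 1).
#' @param exon_length_mean mean coding exon length, nt.
#' @param domains_per_gene_lambda Poisson mean for domain alignments per
#'   gene.
#' @param domain_length_aa mean domain alignment length, amino acids.
#' @param frac_intolerant fraction of sub-regions planted as intolerant.
#' @param suppression factor (>= 1) dividing the common-functional
#'   probability in intolerant regions.
#' @param enrichment factor (>= 1) multiplying pathogenic placement weight
#'   in intolerant regions.
#' @param variant_density expected qualifying variant sites per coding base.
#' @param p_nonsyn probability a variant site is non-synonymous.
#' @param p_common baseline probability a non-synonymous variant is common
#'   (folded MAF > 0.1%) in a tolerant region.
#' @param pathogenic_per_gene Poisson mean of reported pathogenic variants
#'   per gene.
#' @param n_case,n_control de novo mutation counts for the two cohorts.
#' @param rate_table trinucleotide rate table (default
#'   [default_rate_table()]).
#' @param seed RNG seed; the whole cohort is deterministic given it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 200, exons_per_gene_lambda = 4,
                       exon_length_mean = 170, domains_per_gene_lambda = 2,
                       domain_length_aa = 70, frac_intolerant = 0.2,
                       suppression = 5, enrichment = 5,
                       variant_density = 0.05, p_nonsyn = 0.7,
                       p_common = 0.3, pathogenic_per_gene = 2,
                       n_case = 300, n_control = 1200,
                       rate_table = default_rate_table(), seed = 1) {
  if (suppression < 1 || enrichment < 1)
    .stopf("suppression and enrichment factors must be >= 1")
  if (n_genes < 1 || exon_length_mean <= 0 || variant_density < 0)
    .stopf("infeasible simulation config")
  structure(as.list(environment()), class = "sim_config")
}

#' Preset cohort scenarios
#'
#' Two named configurations mirroring archetypal intolerance profiles seen
#' in real disease genes: `"concentrated"` — mostly tolerant genes with a
#' small, strongly intolerant portion carrying nearly all pathogenic
#' variants (a MAPT-like profile) — and `"graded"` — genes split into two
#' moderate intolerance tiers (an ATP1A3-like profile).
#'
#' @param scenario `"concentrated"` or `"graded"`.
#' @param ... overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
sim_preset <- function(scenario = c("concentrated", "graded"), ...) {
  scenario <- match.arg(scenario)
  if (scenario == "concentrated")
    sim_config(frac_intolerant = 0.1, suppression = 10, enrichment = 12, ...)
  else
    sim_config(frac_intolerant = 0.4, suppression = 3, enrichment = 3, ...)
}

.random_gene <- function(cfg, i, chrom, offset) {
  n_ex <- 1L + stats::rpois(1, cfg$exons_per_gene_lambda)
  ex_len <- pmax(30L, as.integer(round(stats::rgamma(n_ex, shape = 2,
                                                     scale = cfg$exon_length_mean / 2))))
  slop <- sum(ex_len) %% 3L            # keep CDS length a codon multiple
  ex_len[n_ex] <- ex_len[n_ex] + (3L - slop) %% 3L
  introns <- if (n_ex > 1) sample(200:2000, n_ex - 1, replace = TRUE) else integer(0)
  starts <- offset + cumsum(c(0L, ex_len[-n_ex] + introns))
  gene_model(sprintf("G%04d", i), chrom,
             sample(c("+", "-"), 1), starts, starts + ex_len)
}

.random_alignments <- function(cfg, gene, domain_pool) {
  n_aa <- gene$cds_length %/% 3L
  k <- stats::rpois(1, cfg$domains_per_gene_lambda)
  if (k == 0 || n_aa < 30) return(NULL)
  rows <- list(); cursor <- 1L
  for (j in seq_len(k)) {
    len <- max(15L, as.integer(round(stats::rexp(1, 1 / cfg$domain_length_aa))))
    gap <- sample(0:30, 1)
    start <- cursor + gap
    end <- min(start + len - 1L, n_aa)
    if (start > n_aa || end < start) break
    rows[[j]] <- data.frame(gene_id = gene$gene_id,
                            domain_id = sample(domain_pool, 1),
                            aa_start = start, aa_end = end,
                            evalue = 10^-stats::runif(1, 3, 30),
                            score = stats::runif(1, 50, 300),
                            stringsAsFactors = FALSE)
    cursor <- end + 1L
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# uniformly sample genomic positions within a region's CDS interval
.region_positions <- function(gene, cds_start, cds_end, n) {
  cds <- cds_start + sample.int(cds_end - cds_start, n, replace = TRUE) - 1L
  .cds_pos_to_genomic(gene, cds)
}

#' Simulate a full synthetic cohort
#'
#' Generates every input the analysis pipeline reads — gene models, domain
#' alignments, population site records, a per-base conservation track,
#' clinical pathogenic variants and de novo mutation sets — with planted
#' regional-intolerance structure:
#' \itemize{
#'   \item total qualifying variant sites per region ~
#'     `Poisson(length * variant_density)`;
#'   \item each variant is non-synonymous with probability `p_nonsyn` and,
#'     if so, common with probability `p_common` — divided by the
#'     `suppression` factor in intolerant regions;
#'   \item pathogenic variants are placed per gene from a multinomial with
#'     probabilities proportional to `Z_i * enrichment^intolerant_i`, so
#'     `enrichment = 1` reproduces the gene-test multinomial null exactly;
#'   \item the conservation track is higher on average in intolerant
#'     regions;
#'   \item case de novo missense mutations in intolerant regions skew
#'     toward damaging variant-level scores.
#' }
#' The cohort is deterministic given `cfg$seed`. With `out_dir` set, the
#' same tables are written in the TSV formats the package readers consume.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory to write the cohort files to.
#' @return A list bundle: `models`, `gene_seqs` (flank-padded CDS
#'   sequences), `alignments`, `regions` (domain division), `sites`,
#'   `conservation`, `pathogenic`, `denovo`, `rates`, `truth` (per-region
#'   planted intolerance flags), `config`.
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", 1:22)
  cursors <- stats::setNames(rep(0L, length(chroms)), chroms)
  domain_pool <- sprintf("cd%04d", 1:300)
  models <- list(); gene_seqs <- character(0); aln_rows <- list()
  for (i in seq_len(cfg$n_genes)) {
    ch <- sample(chroms, 1)
    gm <- .random_gene(cfg, i, ch, cursors[ch] + 5000L)
    cursors[ch] <- max(gm$exons) + 5000L
    models[[gm$gene_id]] <- gm
    gene_seqs[gm$gene_id] <- paste(sample(c("A", "C", "G", "T"),
                                          gm$cds_length + 2L, replace = TRUE),
                                   collapse = "")
    a <- .random_alignments(cfg, gm, domain_pool)
    if (!is.null(a)) aln_rows[[gm$gene_id]] <- a
  }
  alignments <- if (length(aln_rows)) do.call(rbind, aln_rows) else
    data.frame(gene_id = character(0), domain_id = character(0),
               aa_start = integer(0), aa_end = integer(0),
               evalue = numeric(0), score = numeric(0))
  rownames(alignments) <- NULL
  regions <- build_regions(models, "domain", alignments)
  rates <- region_mutation_rates(regions, gene_seqs, cfg$rate_table)
  n_r <- nrow(regions)
  intolerant <- stats::runif(n_r) < cfg$frac_intolerant
  truth <- data.frame(gene_id = regions$gene_id,
                      region_index = regions$region_index,
                      intolerant = intolerant, stringsAsFactors = FALSE)

  # population site records: one Poisson draw per region, then one
  # vectorized pass over all sites
  len <- regions$cds_end - regions$cds_start
  n_var <- stats::rpois(n_r, len * cfg$variant_density)
  ridx <- rep.int(seq_len(n_r), n_var)
  n_s <- length(ridx)
  cds <- regions$cds_start[ridx] +
    floor(stats::runif(n_s) * len[ridx])
  pos <- integer(n_s)
  for (gid in unique(regions$gene_id[ridx])) {
    sel <- which(regions$gene_id[ridx] == gid)
    pos[sel] <- .cds_pos_to_genomic(models[[gid]], cds[sel])
  }
  nonsyn <- stats::runif(n_s) < cfg$p_nonsyn
  p_com <- cfg$p_common / ifelse(intolerant[ridx], cfg$suppression, 1)
  common <- nonsyn & stats::runif(n_s) < p_com
  lowcov <- stats::runif(n_s) < 0.05
  sites <- data.frame(
    chrom = regions$chrom[ridx], pos = pos,
    mean_coverage = ifelse(lowcov, stats::runif(n_s, 0, 9.9),
                           pmax(10, stats::rnorm(n_s, 60, 15))),
    filter_status = ifelse(stats::runif(n_s) < 0.95, "PASS", "LowQual"),
    is_variant = TRUE,
    alt_af = ifelse(common, stats::runif(n_s, 0.0011, 0.4),
                    stats::runif(n_s, 1e-5, 0.001)),
    consequence = ifelse(nonsyn, "nonsynonymous", "synonymous"),
    stringsAsFactors = FALSE)

  # sparse conservation track, elevated in intolerant regions
  cpos <- vector("list", n_r)
  for (i in seq_len(n_r)) {
    blocks <- parse_blocks(regions$blocks[i])
    cpos[[i]] <- unlist(lapply(seq_len(nrow(blocks)),
                               function(b) seq.int(blocks[b, "start"], blocks[b, "end"] - 1L)))
  }
  n_base <- lengths(cpos)
  cridx <- rep.int(seq_len(n_r), n_base)
  conservation <- data.frame(
    chrom = regions$chrom[cridx], pos = unlist(cpos),
    score = stats::rnorm(length(cridx), ifelse(intolerant[cridx], 3, 0.5), 1),
    stringsAsFactors = FALSE)
  conservation <- conservation[stats::runif(nrow(conservation)) < 0.9, ]
  rownames(conservation) <- NULL

  # pathogenic variants: multinomial within gene, weighted by Z * enrichment
  path_rows <- list()
  ridx_by_gene <- split(seq_len(n_r), regions$gene_id)
  for (gid in names(ridx_by_gene)) {
    k <- stats::rpois(1, cfg$pathogenic_per_gene)
    if (k == 0) next
    idx <- ridx_by_gene[[gid]]
    w <- rates$mutation_rate[idx] *
      ifelse(intolerant[idx], cfg$enrichment, 1)
    if (sum(w) <= 0) next
    counts <- as.integer(stats::rmultinom(1, k, w / sum(w)))
    gm <- models[[gid]]
    for (j in which(counts > 0)) {
      i <- idx[j]
      pos <- .region_positions(gm, regions$cds_start[i], regions$cds_end[i], counts[j])
      path_rows[[length(path_rows) + 1L]] <- data.frame(
        chrom = gm$chrom, pos = pos, ref = "N", alt = "N",
        source = sample(c("clinvar", "hgmd"), counts[j], replace = TRUE),
        clinical_label = NA_character_, canonical = TRUE,
        consequence_terms = "missense_variant", stringsAsFactors = FALSE)
    }
  }
  pathogenic <- if (length(path_rows)) do.call(rbind, path_rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), source = character(0),
               clinical_label = character(0), canonical = logical(0),
               consequence_terms = character(0))
  if (nrow(pathogenic)) {
    pathogenic$clinical_label <- ifelse(pathogenic$source == "clinvar",
                                        "Pathogenic", "DM")
    # decoys the pathogenic filter must remove
    decoy <- pathogenic[sample.int(nrow(pathogenic),
                                   max(1, nrow(pathogenic) %/% 10)), , drop = FALSE]
    decoy$clinical_label <- ifelse(decoy$source == "clinvar",
                                   "Likely pathogenic", decoy$clinical_label)
    decoy$consequence_terms <- ifelse(decoy$clinical_label == "DM",
                                      "missense_variant,splice_region_variant",
                                      decoy$consequence_terms)
    decoy$pos <- decoy$pos + 1L  # distinct sites
    pathogenic <- rbind(pathogenic, decoy)
  }
  rownames(pathogenic) <- NULL

  denovo <- .simulate_denovo(cfg, models, regions, truth)
  bundle <- list(models = models, gene_seqs = gene_seqs,
                 alignments = alignments, regions = regions, sites = sites,
                 conservation = conservation, pathogenic = pathogenic,
                 denovo = denovo, rates = rates, truth = truth, config = cfg)
  if (!is.null(out_dir)) write_cohort(bundle, out_dir)
  bundle
}

.simulate_denovo <- function(cfg, models, regions, truth) {
  n <- cfg$n_case + cfg$n_control
  gene_ids <- names(models)
  gid <- sample(gene_ids, n, replace = TRUE)
  cohort <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  rows <- vector("list", n)
  for (m in seq_len(n)) {
    gm <- models[[gid[m]]]
    cds <- sample.int(gm$cds_length, 1) - 1L
    pos <- .cds_pos_to_genomic(gm, cds)
    cons <- sample(c("synonymous", "missense", "canonical_splice", "stop_gain"),
                   1, prob = c(0.3, 0.6, 0.05, 0.05))
    pp2 <- NA_real_
    if (cons == "missense") {
      r <- regions[regions$gene_id == gid[m], , drop = FALSE]
      ridx <- assign_positions_to_regions(gm, r, pos)
      intol <- truth$intolerant[truth$gene_id == gid[m] &
                                truth$region_index == ridx]
      damaging_bias <- isTRUE(intol) && cohort[m] == "case"
      pp2 <- if (damaging_bias) stats::rbeta(1, 8, 1) else stats::runif(1)
    }
    rows[[m]] <- data.frame(
      chrom = gm$chrom, pos = pos, consequence = cons,
      polyphen2_humvar = pp2, cohort = cohort[m],
      in_both_siblings = stats::runif(1) < 0.02,
      institute_labels = sample(c("validated", "strong", "strong,weak"),
                                1, prob = c(0.7, 0.25, 0.05)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated cohort to disk
#'
#' Emits the cohort in the plain-text formats the package readers consume:
#' `genes.tsv`, `alignments.tsv`, `sites.tsv`, `conservation.tsv`,
#' `pathogenic.tsv`, `denovo.tsv`, `rate_table.tsv`, `gene_seqs.tsv`,
#' `truth.tsv` and `config.json`.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_gene_models(bundle$models, p("genes.tsv"))
  write_tsv_table(bundle$alignments, p("alignments.tsv"))
  write_tsv_table(bundle$sites, p("sites.tsv"))
  write_tsv_table(bundle$conservation, p("conservation.tsv"))
  write_tsv_table(bundle$pathogenic, p("pathogenic.tsv"))
  write_tsv_table(bundle$denovo, p("denovo.tsv"))
  write_tsv_table(bundle$config$rate_table, p("rate_table.tsv"))
  write_tsv_table(data.frame(gene_id = names(bundle$gene_seqs),
                             seq = unname(bundle$gene_seqs)), p("gene_seqs.tsv"))
  write_tsv_table(bundle$truth, p("truth.tsv"))
  cfg <- bundle$config
  cfg$rate_table <- NULL
  jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A bundle list mirroring [simulate_cohort()] (without `config`).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  seqs <- read_tsv_table(p("gene_seqs.tsv"))
  list(models = read_gene_models(p("genes.tsv")),
       gene_seqs = stats::setNames(seqs$seq, seqs$gene_id),
       alignments = read_tsv_table(p("alignments.tsv")),
       sites = read_tsv_table(p("sites.tsv")),
       conservation = read_tsv_table(p("conservation.tsv")),
       pathogenic = read_tsv_table(p("pathogenic.tsv")),
       denovo = read_tsv_table(p("denovo.tsv")),
       truth = read_tsv_table(p("truth.tsv")),
       rate_table = read_rate_table(p("rate_table.tsv")))
}

#' Standard-normal null scores for calibration tests
#'
#' @param n_regions number of scores.
#' @param seed RNG seed.
#' @return Numeric vector of iid standard-normal scores.
#' @export
simulate_null_scores <- function(n_regions, seed = 1) {
  stopifnot(n_regions >= 1)
  set.seed(as.integer(seed))
  stats::rnorm(n_regions)
}

#' Simulate gene-test inputs under (or away from) the multinomial null
#'
#' Generates per-gene pathogenic counts `Y` from
#' `Multinomial(N, w / sum(w))` with weights `w = Z * enrichment^intolerant`
#' over random region structures, mutation rates and scores — the exact
#' sampling scheme the gene-specific permutation test assumes under its
#' null when `enrichment = 1`.
#'
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @param n_regions_range inclusive range of regions per gene.
#' @param total_lambda Poisson mean of `sum(Y) - 1` per gene.
#' @param enrichment pathogenic weight multiplier in the lowest-score
#'   region (1 = null).
#' @return List of per-gene lists `gene_id`, `Y`, `Z`, `X`.
#' @export
simulate_gene_inputs <- function(n_genes, seed = 1, n_regions_range = c(2, 8),
                                 total_lambda = 2, enrichment = 1) {
  set.seed(as.integer(seed))
  lapply(seq_len(n_genes), function(i) {
    n_g <- sample(n_regions_range[1]:n_regions_range[2], 1)
    Z <- stats::rgamma(n_g, shape = 2, rate = 2)
    X <- stats::rnorm(n_g)
    w <- Z
    if (enrichment != 1) w[which.min(X)] <- w[which.min(X)] * enrichment
    N <- 1L + stats::rpois(1, total_lambda)
    Y <- as.integer(stats::rmultinom(1, N, w / sum(w)))
    list(gene_id = sprintf("SG%05d", i), Y = Y, Z = Z, X = X)
  })
}
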