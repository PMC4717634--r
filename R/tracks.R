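#' Average a per-base conservation track over sub-regions
#'
#' Computes, for each sub-region, the arithmetic mean of the available
#' per-base conservation scores (e.g. GERP++-style constraint values) across
#' its genomic blocks. The track may be sparse; bases without a score are
#' simply left out of the mean, and a region with no covered base gets `NA`.
#'
#' @param track data frame with columns `chrom`, `pos` (0-based) and `score`.
#' @param regions cohort [region_table].
#' @return Data frame `gene_id`, `region_index`, `subgerp`.
#' @export
compute_subgerp <- function(track, regions) {
  by_chrom <- split(track, track$chrom)
  mean_one <- function(i) {
    tr <- by_chrom[[regions$chrom[i]]]
    if (is.null(tr)) return(NA_real_)
    blocks <- parse_blocks(regions$blocks[i])
    pos <- unlist(lapply(seq_len(nrow(blocks)),
                         function(b) seq.int(blocks[b, "start"], blocks[b, "end"] - 1L)))
    hit <- match(pos, tr$pos)
    hit <- hit[!is.na(hit)]
    if (!length(hit)) NA_real_ else mean(tr$score[hit])
  }
  data.frame(gene_id = regions$gene_id, region_index = regions$region_index,
             subgerp = vapply(seq_len(nrow(regions)), mean_one, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Trinucleotide-context substitution rate table
#'
#' A rate table maps a (trinucleotide context, alternate base) pair to a
#' per-generation substitution rate; region mutation rates are sums of these
#' over all positions and all three possible substitutions. The default
#' table is a simple deterministic model — transitions faster than
#' transversions, CpG transitions strongly elevated — adequate as a
#' mutability covariate for synthetic cohorts; a calibrated table for real
#' data is supplied via [read_rate_table()].
#'
#' @return Data frame with columns `context` (64 trinucleotides), `alt` and
#'   `rate` (192 rows).
#' @export
default_rate_table <- function() {
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(prev = b, ref = b, nxt = b, alt = b,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$alt != grid$ref, ]
  transition <- (grid$ref == "A" & grid$alt == "G") |
    (grid$ref == "G" & grid$alt == "A") |
    (grid$ref == "C" & grid$alt == "T") |
    (grid$ref == "T" & grid$alt == "C")
  rate <- ifelse(transition, 1.2e-8, 4e-9)
  cpg <- (grid$ref == "C" & grid$nxt == "G" & grid$alt == "T") |
    (grid$ref == "G" & grid$prev == "C" & grid$alt == "A")
  rate[cpg] <- rate[cpg] * 10
  out <- data.frame(context = paste0(grid$prev, grid$ref, grid$nxt),
                    alt = grid$alt, rate = rate, stringsAsFactors = FALSE)
  out[order(out$context, out$alt), ]
}

#' Read a rate table from TSV
#' @param path TSV with columns `context`, `alt`, `rate`.
#' @return Rate table data frame.
#' @export
read_rate_table <- function(path) {
  df <- read_tsv_table(path)
  if (!all(c("context", "alt", "rate") %in% names(df)))
    .stopf("rate table %s must have columns context, alt, rate", path,
           class = "srvis_format_error")
  df
}

.rate_lookup <- function(rate_table) {
  stats::setNames(rate_table$rate, paste0(rate_table$context, ">", rate_table$alt))
}

#' Sequence-composition mutation rate of a region
#'
#' Sums, over every position of a region's sequence and every one of its
#' three possible single-nucleotide substitutions, the rate-table entry for
#' that (trinucleotide context, alternate) pair. The input sequence must
#' carry one flanking base on each side so terminal positions have a
#' context; the rate covers positions `2 .. nchar-1`.
#'
#' @param seq_with_flanks region sequence with 1-nt flanks (uppercase ACGTN).
#' @param rate_table a rate table (see [default_rate_table()]).
#' @return Non-negative rate. Positions whose context contains `N` are
#'   skipped; their count is attached as attribute `"skipped"`.
#' @examples
#' rt <- data.frame(context = c("ACG", "CGT"), alt = c("T", "A"),
#'                  rate = c(1e-8, 2e-8))
#' compute_mutation_rate("ACGT", rt)  # positions C and G only
#' @export
compute_mutation_rate <- function(seq_with_flanks, rate_table) {
  L <- nchar(seq_with_flanks)
  if (L <= 2) return(structure(0, skipped = 0L))
  chars <- strsplit(toupper(seq_with_flanks), "")[[1]]
  i <- 2:(L - 1)
  ctx <- paste0(chars[i - 1], chars[i], chars[i + 1])
  ok <- !grepl("N", ctx, fixed = TRUE)
  lut <- .rate_lookup(rate_table)
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (alt in bases) {
    use <- ok & chars[i] != alt
    r <- lut[paste0(ctx[use], ">", alt)]
    total <- total + sum(r, na.rm = TRUE)
  }
  structure(total, skipped = sum(!ok))
}

#' Mutation rates for all sub-regions of a cohort
#'
#' @param regions cohort [region_table].
#' @param gene_seqs named character vector of per-gene CDS sequences in CDS
#'   orientation, padded with one flanking base on each side (length
#'   `cds_length + 2`).
#' @param rate_table a rate table (default [default_rate_table()]).
#' @return Data frame `gene_id`, `region_index`, `mutation_rate`.
#' @export
region_mutation_rates <- function(regions, gene_seqs,
                                  rate_table = default_rate_table()) {
  rate_one <- function(i) {
    s <- gene_seqs[[regions$gene_id[i]]]
    # region [cds_start, cds_end) plus its 1-nt flanks within the padded seq
    sub <- substr(s, regions$cds_start[i] + 1L, regions$cds_end[i] + 2L)
    as.numeric(compute_mutation_rate(sub, rate_table))
  }
  data.frame(gene_id = regions$gene_id, region_index = regions$region_index,
             mutation_rate = vapply(seq_len(nrow(regions)), rate_one, numeric(1)),
             stringsAsFactors = FALSE)
}
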