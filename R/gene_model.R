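#' Gene model: ordered coding exons defining a CDS coordinate system
#'
#' A gene model holds the coding exon intervals of one gene's canonical
#' transcript, ordered in transcription direction, and defines the CDS
#' nucleotide coordinate system `[0, cds_length)` over their concatenation.
#' Genomic intervals are 0-based half-open (BED convention). For minus-strand
#' genes the first exon in transcription order is the 3'-most in genomic
#' coordinates.
#'
#' A CDS length that is not a multiple of 3 is tolerated (annotation slop) but
#' flagged with a warning, since domain alignments are given in protein
#' coordinates.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of genomic exon boundaries,
#'   0-based half-open, in any order; they are sorted internally.
#' @return An object of class `"gene_model"`: a list with elements `gene_id`,
#'   `chrom`, `strand`, `exons` (two-column matrix `start`,`end` in
#'   transcription order) and `cds_length`.
#' @examples
#' gm <- gene_model("G1", "chr1", "+", c(100, 300), c(200, 400))
#' gm$cds_length  # 200
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  stopifnot(length(gene_id) == 1, length(strand) == 1,
            length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1)
  if (!strand %in% c("+", "-")) .stopf("strand must be '+' or '-', got '%s'", strand)
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (any(exon_ends <= exon_starts)) .stopf("gene %s: empty or inverted exon", gene_id)
  ord <- order(exon_starts)
  exon_starts <- exon_starts[ord]; exon_ends <- exon_ends[ord]
  if (any(exon_starts[-1] < exon_ends[-length(exon_ends)]))
    .stopf("gene %s: overlapping coding exons", gene_id)
  if (strand == "-") { exon_starts <- rev(exon_starts); exon_ends <- rev(exon_ends) }
  exons <- cbind(start = exon_starts, end = exon_ends)
  cds_length <- sum(exons[, "end"] - exons[, "start"])
  if (cds_length %% 3L != 0L)
    warning(sprintf("gene %s: CDS length %d is not a multiple of 3", gene_id, cds_length))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds_length = as.integer(cds_length)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s(%s)  %d exon(s), CDS %d nt\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), x$cds_length))
  invisible(x)
}

# cumulative CDS offset at the start of each exon (transcription order)
.exon_offsets <- function(gene) {
  len <- gene$exons[, "end"] - gene$exons[, "start"]
  cumsum(c(0L, len[-length(len)]))
}

#' Map a CDS interval to genomic blocks
#'
#' Projects a 0-based half-open interval in CDS coordinate space onto the
#' genome. An interval spanning an exon junction splits into multiple blocks;
#' blocks are returned in transcription order, so for minus-strand genes they
#' descend in genomic coordinate. Block lengths always sum to the interval
#' length and [map_genomic_to_cds()] inverts the mapping base by base.
#'
#' @param gene a [gene_model()].
#' @param cds_start,cds_end 0-based half-open CDS interval,
#'   `0 <= cds_start < cds_end <= cds_length`.
#' @return Integer matrix with columns `start`, `end` (genomic, half-open),
#'   one row per block.
#' @export
map_cds_to_genomic <- function(gene, cds_start, cds_end) {
  stopifnot(inherits(gene, "gene_model"))
  if (cds_start < 0 || cds_end <= cds_start || cds_end > gene$cds_length)
    .stopf("gene %s: CDS interval [%s,%s) out of range [0,%d)",
           gene$gene_id, cds_start, cds_end, gene$cds_length)
  off <- .exon_offsets(gene)
  len <- gene$exons[, "end"] - gene$exons[, "start"]
  blocks <- NULL
  for (i in seq_len(nrow(gene$exons))) {
    lo <- max(cds_start, off[i]); hi <- min(cds_end, off[i] + len[i])
    if (lo >= hi) next
    if (gene$strand == "+") {
      gs <- gene$exons[i, "start"] + (lo - off[i])
      blocks <- rbind(blocks, c(gs, gs + (hi - lo)))
    } else {
      ge <- gene$exons[i, "end"] - (lo - off[i])
      blocks <- rbind(blocks, c(ge - (hi - lo), ge))
    }
  }
  colnames(blocks) <- c("start", "end")
  blocks
}

#' Map genomic positions to CDS coordinates
#'
#' @param gene a [gene_model()].
#' @param pos integer vector of genomic positions (0-based).
#' @return Integer vector of CDS positions; `NA` for positions outside the
#'   gene's coding exons.
#' @export
map_genomic_to_cds <- function(gene, pos) {
  stopifnot(inherits(gene, "gene_model"))
  off <- .exon_offsets(gene)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(gene$exons))) {
    s <- gene$exons[i, "start"]; e <- gene$exons[i, "end"]
    hit <- which(pos >= s & pos < e)
    if (!length(hit)) next
    out[hit] <- if (gene$strand == "+") off[i] + (pos[hit] - s)
                else off[i] + (e - 1L - pos[hit])
  }
  out
}

# vectorized single-position CDS -> genomic mapping (0-based)
.cds_pos_to_genomic <- function(gene, cds_pos) {
  off <- .exon_offsets(gene)
  idx <- findInterval(cds_pos, off)
  within <- cds_pos - off[idx]
  if (gene$strand == "+") gene$exons[idx, "start"] + within
  else gene$exons[idx, "end"] - 1L - within
}

#' Select the canonical transcript among several gene models
#'
#' When a gene has multiple coding transcripts the canonical one is taken to
#' be the transcript with the longest CDS; ties break to the lexicographically
#' smallest transcript identifier.
#'
#' @param models list of [gene_model()] objects for the same gene, named by
#'   transcript id (or carrying distinct `gene_id`s used as transcript ids).
#' @return The selected `gene_model`.
#' @export
select_canonical_transcript <- function(models) {
  stopifnot(length(models) >= 1)
  ids <- names(models)
  if (is.null(ids)) ids <- vapply(models, function(m) m$gene_id, character(1))
  lens <- vapply(models, function(m) m$cds_length, integer(1))
  ord <- order(-lens, ids)
  models[[ord[1]]]
}

#' Read gene models from a 4-column TSV
#'
#' Expected columns: `gene`, `chrom`, `strand`, `exons`, where `exons` is a
#' comma-separated list of `start-end` genomic intervals (0-based half-open).
#' When several rows share a gene id they are treated as alternative
#' transcripts and resolved with [select_canonical_transcript()].
#'
#' @param path TSV path.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_table(path)
  need <- c("gene", "chrom", "strand", "exons")
  if (!all(need %in% names(df)))
    .stopf("gene model file %s lacks columns: %s", path,
           paste(setdiff(need, names(df)), collapse = ", "), class = "srvis_format_error")
  parse_row <- function(i) {
    iv <- strsplit(strsplit(df$exons[i], ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    starts <- as.integer(vapply(iv, `[`, "", 1))
    ends   <- as.integer(vapply(iv, `[`, "", 2))
    gene_model(df$gene[i], df$chrom[i], df$strand[i], starts, ends)
  }
  rows <- lapply(seq_len(nrow(df)), parse_row)
  out <- list()
  for (g in unique(df$gene)) {
    idx <- which(df$gene == g)
    cand <- rows[idx]
    names(cand) <- if (!is.null(df$transcript)) df$transcript[idx] else as.character(idx)
    out[[g]] <- select_canonical_transcript(cand)
    out[[g]]$gene_id <- g
  }
  out
}

#' Write gene models to the 4-column TSV format
#'
#' @param models named list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m$exons
    ord <- order(ex[, "start"])  # serialize in genomic order
    data.frame(gene = m$gene_id, chrom = m$chrom, strand = m$strand,
               exons = paste(sprintf("%d-%d", ex[ord, "start"], ex[ord, "end"]),
                             collapse = ","),
               stringsAsFactors = FALSE)
  })
  write_tsv_table(do.call(rbind, rows), path)
}
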