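#' Sub-region tables
#'
#' A sub-region table is a data frame with one row per contiguous CDS interval
#' of a gene, the unit of analysis for all scoring and testing in this
#' package. Columns:
#' \describe{
#'   \item{gene_id}{gene identifier}
#'   \item{region_index}{1-based order within the gene (transcription order)}
#'   \item{label}{domain identifier, `"unaligned"`, or `exon<k>`}
#'   \item{cds_start,cds_end}{0-based half-open interval in CDS space}
#'   \item{chrom,strand}{genomic context}
#'   \item{blocks}{genomic projection as `start-end` pairs (0-based half-open)
#'     joined by `";"`, in transcription order; a CDS interval crossing an
#'     exon junction has several blocks}
#' }
#' Within a gene the CDS intervals tile `[0, cds_length)` with no gaps or
#' overlaps; [check_region_tiling()] asserts this.
#'
#' @name region_table
NULL

.blocks_to_string <- function(blocks) {
  paste(sprintf("%d-%d", blocks[, "start"], blocks[, "end"]), collapse = ";")
}

#' Expand a serialized block string to a matrix of genomic intervals
#' @param s a `blocks` string from a [region_table].
#' @return integer matrix with columns `start`, `end`.
#' @export
parse_blocks <- function(s) {
  iv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  cbind(start = as.integer(vapply(iv, `[`, "", 1)),
        end   = as.integer(vapply(iv, `[`, "", 2)))
}

.region_row <- function(gene, index, label, cds_start, cds_end) {
  blocks <- map_cds_to_genomic(gene, cds_start, cds_end)
  data.frame(gene_id = gene$gene_id, region_index = as.integer(index),
             label = label, cds_start = as.integer(cds_start),
             cds_end = as.integer(cds_end), chrom = gene$chrom,
             strand = gene$strand, blocks = .blocks_to_string(blocks),
             stringsAsFactors = FALSE)
}

#' Build domain-based sub-regions for one gene
#'
#' Converts profile-search domain alignments (protein coordinates, 1-based
#' inclusive) into a tiling of the gene's CDS: each kept alignment becomes a
#' domain region and every maximal unaligned stretch — including before the
#' first and after the last alignment — becomes an `"unaligned"` region.
#' Alignments with E-value above `max_evalue` are discarded. Overlaps are
#' resolved greedily in descending alignment bit score (ties: lower E-value,
#' then lexicographic domain id); an alignment overlapping an already-kept one
#' is dropped entirely.
#'
#' @param gene a [gene_model()].
#' @param alignments data frame with columns `gene_id`, `domain_id`,
#'   `aa_start`, `aa_end` (1-based inclusive protein coordinates), `evalue`,
#'   `score` (bit score).
#' @param max_evalue maximal E-value for an alignment to be considered
#'   (default `1e-2`).
#' @return A [region_table] for the gene. Alignments extending past the CDS
#'   (`aa_end*3 > cds_length`) are rejected with a warning and recorded in
#'   attribute `"rejected"`.
#' @examples
#' gm <- gene_model("G", "chr1", "+", 0, 900)
#' aln <- data.frame(gene_id = "G", domain_id = c("d1", "d2"),
#'                   aa_start = c(10, 120), aa_end = c(50, 200),
#'                   evalue = c(1e-10, 1e-8), score = c(100, 80))
#' build_domain_regions(gm, aln)$cds_start  # 0 27 150 357 600
#' @export
build_domain_regions <- function(gene, alignments, max_evalue = 1e-2) {
  stopifnot(inherits(gene, "gene_model"))
  rejected <- NULL
  aln <- alignments
  if (!is.null(aln) && nrow(aln) > 0) {
    if (!all(aln$gene_id == gene$gene_id))
      .stopf("alignments for foreign gene passed to %s", gene$gene_id)
    aln <- aln[aln$evalue <= max_evalue, , drop = FALSE]
    over <- aln$aa_end * 3L > gene$cds_length
    if (any(over)) {
      warning(sprintf("gene %s: %d alignment(s) extend past the CDS; rejected",
                      gene$gene_id, sum(over)))
      rejected <- aln[over, , drop = FALSE]
      aln <- aln[!over, , drop = FALSE]
    }
  }
  kept <- NULL
  if (!is.null(aln) && nrow(aln) > 0) {
    aln <- aln[order(-aln$score, aln$evalue, aln$domain_id), , drop = FALSE]
    nt_start <- (aln$aa_start - 1L) * 3L
    nt_end <- aln$aa_end * 3L
    taken <- logical(nrow(aln))
    for (i in seq_len(nrow(aln))) {
      if (i == 1L) { taken[1] <- TRUE; next }
      ov <- any(taken[seq_len(i - 1)] &
                nt_start[i] < nt_end[seq_len(i - 1)] &
                nt_end[i] > nt_start[seq_len(i - 1)])
      taken[i] <- !ov
    }
    kept <- data.frame(label = aln$domain_id[taken],
                       start = nt_start[taken], end = nt_end[taken])
    kept <- kept[order(kept$start), , drop = FALSE]
  }
  rows <- list(); idx <- 0L; cursor <- 0L
  emit <- function(label, s, e) {
    idx <<- idx + 1L
    rows[[idx]] <<- .region_row(gene, idx, label, s, e)
  }
  if (!is.null(kept) && nrow(kept) > 0) {
    for (i in seq_len(nrow(kept))) {
      if (kept$start[i] > cursor) emit("unaligned", cursor, kept$start[i])
      emit(kept$label[i], kept$start[i], kept$end[i])
      cursor <- kept$end[i]
    }
  }
  if (cursor < gene$cds_length) emit("unaligned", cursor, gene$cds_length)
  out <- do.call(rbind, rows)
  attr(out, "rejected") <- rejected
  out
}

#' Build exon-based sub-regions for one gene
#'
#' One sub-region per coding exon, in transcription order, labelled
#' `exon1 ... exonK`.
#'
#' @param gene a [gene_model()].
#' @return A [region_table] tiling the CDS.
#' @export
build_exon_regions <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  off <- .exon_offsets(gene)
  len <- gene$exons[, "end"] - gene$exons[, "start"]
  rows <- lapply(seq_along(len), function(i)
    .region_row(gene, i, sprintf("exon%d", i), off[i], off[i] + len[i]))
  do.call(rbind, rows)
}

#' Randomly permute the sizes of a gene's sub-regions
#'
#' Re-lays the same sub-regions (same labels, same size multiset, same count)
#' contiguously from CDS position 0 in a random order, producing a division
#' with identical size distribution but no biological boundary information.
#' Used to build the null distribution for the division permutation test.
#'
#' @param regions [region_table] rows for a single gene.
#' @param seed integer seed; the layout is deterministic given the seed.
#' @param gene the gene's [gene_model()], used to recompute genomic blocks.
#' @return A [region_table] with the same labels and sizes in permuted order.
#' @export
permute_region_sizes <- function(regions, seed, gene) {
  stopifnot(nrow(regions) >= 1, length(unique(regions$gene_id)) == 1)
  set.seed(as.integer(seed))
  ord <- sample.int(nrow(regions))
  sizes <- (regions$cds_end - regions$cds_start)[ord]
  labels <- regions$label[ord]
  ends <- cumsum(sizes); starts <- c(0L, ends[-length(ends)])
  rows <- lapply(seq_along(sizes), function(i)
    .region_row(gene, i, labels[i], starts[i], ends[i]))
  do.call(rbind, rows)
}

#' Assert that a gene's sub-regions tile its CDS
#'
#' @param regions [region_table] rows for one gene.
#' @param cds_length the gene's CDS length.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_region_tiling <- function(regions, cds_length) {
  r <- regions[order(regions$cds_start), , drop = FALSE]
  ok <- r$cds_start[1] == 0L &&
    r$cds_end[nrow(r)] == cds_length &&
    all(r$cds_end[-nrow(r)] == r$cds_start[-1]) &&
    all(r$cds_end > r$cds_start)
  if (!ok) .stopf("gene %s: sub-regions do not tile [0,%d)",
                  r$gene_id[1], cds_length)
  invisible(TRUE)
}

#' Assign genomic positions to sub-regions
#'
#' Positions are mapped through the gene's CDS coordinate system and assigned
#' to the region whose half-open CDS interval contains them.
#'
#' @param gene a [gene_model()].
#' @param regions the gene's [region_table].
#' @param pos genomic positions (0-based).
#' @return Integer vector of `region_index` values; `NA` for positions
#'   outside the coding exons.
#' @export
assign_positions_to_regions <- function(gene, regions, pos) {
  cds <- map_genomic_to_cds(gene, pos)
  r <- regions[order(regions$cds_start), , drop = FALSE]
  idx <- findInterval(cds, r$cds_start)
  out <- rep(NA_integer_, length(pos))
  inside <- !is.na(cds) & idx >= 1 & cds < r$cds_end[pmax(idx, 1)]
  out[inside] <- r$region_index[idx[inside]]
  out
}

#' Build a division for a whole cohort of genes
#'
#' @param models named list of [gene_model()] objects.
#' @param division `"domain"` or `"exon"`.
#' @param alignments data frame of domain alignments (required for
#'   `division = "domain"`).
#' @param max_evalue passed to [build_domain_regions()].
#' @return One [region_table] covering all genes.
#' @export
build_regions <- function(models, division = c("domain", "exon"),
                          alignments = NULL, max_evalue = 1e-2) {
  division <- match.arg(division)
  rows <- lapply(models, function(m) {
    if (division == "exon") build_exon_regions(m)
    else build_domain_regions(m,
      if (is.null(alignments)) NULL
      else alignments[alignments$gene_id == m$gene_id, , drop = FALSE],
      max_evalue = max_evalue)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permute every gene's division in a cohort
#'
#' @param regions cohort [region_table].
#' @param models named list of [gene_model()] objects.
#' @param seed run seed; each gene uses a deterministic substream derived
#'   from the seed and its gene id.
#' @return Permuted cohort [region_table].
#' @export
permute_regions <- function(regions, models, seed) {
  rows <- lapply(split(regions, regions$gene_id), function(r) {
    g <- models[[r$gene_id[1]]]
    permute_region_sizes(r, .gene_seed(seed, r$gene_id[1]), g)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
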