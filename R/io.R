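#' Read domain alignments
#'
#' Two layouts are supported: a headered TSV with columns `gene_id`,
#' `domain_id`, `aa_start`, `aa_end`, `evalue`, `score`, or headerless
#' 12-column BLAST tabular output (`-outfmt 6`), from which query id,
#' subject id, query start/end, E-value and bit score are taken. Protein
#' coordinates are 1-based inclusive in both layouts.
#'
#' @param path file path.
#' @param format `"tsv"` (headered) or `"blast6"`.
#' @return Data frame with the six alignment columns.
#' @export
read_alignments <- function(path, format = c("tsv", "blast6")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_table(path)
    need <- c("gene_id", "domain_id", "aa_start", "aa_end", "evalue", "score")
    if (!all(need %in% names(df)))
      .stopf("alignment file %s lacks columns: %s", path,
             paste(setdiff(need, names(df)), collapse = ", "),
             class = "srvis_format_error")
    return(df[, need])
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12)
    .stopf("BLAST tabular file %s has %d columns; expected 12", path, ncol(df),
           class = "srvis_format_error")
  data.frame(gene_id = df[[1]], domain_id = df[[2]],
             aa_start = as.integer(df[[7]]), aa_end = as.integer(df[[8]]),
             evalue = as.numeric(df[[11]]), score = as.numeric(df[[12]]),
             stringsAsFactors = FALSE)
}

#' Read and write sub-region tables
#'
#' The on-disk region table is the same TSV the [region_table] documentation
#' describes, one row per region with its CDS interval and serialized
#' genomic blocks.
#'
#' @param path file path.
#' @param regions a [region_table].
#' @return `read_regions()` returns a [region_table].
#' @export
read_regions <- function(path) {
  df <- read_tsv_table(path)
  need <- c("gene_id", "region_index", "label", "cds_start", "cds_end",
            "chrom", "strand", "blocks")
  if (!all(need %in% names(df)))
    .stopf("region file %s lacks columns: %s", path,
           paste(setdiff(need, names(df)), collapse = ", "),
           class = "srvis_format_error")
  df
}

#' @rdname read_regions
#' @export
write_regions <- function(regions, path) write_tsv_table(regions, path)

#' Export regions as BED-like intervals
#'
#' One row per genomic block: `chrom`, `start`, `end`, `gene_id`,
#' `region_index`, `label`, `strand`.
#'
#' @param regions a [region_table].
#' @param path output TSV path.
#' @export
write_region_bed <- function(regions, path) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    b <- parse_blocks(regions$blocks[i])
    data.frame(chrom = regions$chrom[i], start = b[, "start"], end = b[, "end"],
               gene_id = regions$gene_id[i],
               region_index = regions$region_index[i],
               label = regions$label[i], strand = regions$strand[i],
               stringsAsFactors = FALSE)
  })
  write_tsv_table(do.call(rbind, rows), path)
}

#' Read population site records
#'
#' @param path TSV with columns `chrom`, `pos`, `mean_coverage`,
#'   `filter_status`, `is_variant`, `alt_af`, `consequence`.
#' @return Data frame of site records.
#' @export
read_sites <- function(path) {
  df <- read_tsv_table(path)
  need <- c("chrom", "pos", "mean_coverage", "filter_status", "is_variant",
            "alt_af", "consequence")
  if (!all(need %in% names(df)))
    .stopf("site file %s lacks columns: %s", path,
           paste(setdiff(need, names(df)), collapse = ", "),
           class = "srvis_format_error")
  df$is_variant <- as.logical(df$is_variant)
  df
}

#' Read a per-base conservation track
#'
#' @param path TSV with columns `chrom`, `pos` (0-based), `score`.
#' @return Data frame track.
#' @export
read_conservation <- function(path) {
  df <- read_tsv_table(path)
  if (!all(c("chrom", "pos", "score") %in% names(df)))
    .stopf("conservation file %s needs columns chrom, pos, score", path,
           class = "srvis_format_error")
  df
}

#' Read clinical variant tables
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `source`,
#'   `clinical_label`, `canonical`, `consequence_terms`.
#' @return Data frame of clinical variants.
#' @export
read_clinical_variants <- function(path) {
  df <- read_tsv_table(path)
  need <- c("chrom", "pos", "ref", "alt", "source", "clinical_label",
            "canonical", "consequence_terms")
  if (!all(need %in% names(df)))
    .stopf("clinical variant file %s lacks columns: %s", path,
           paste(setdiff(need, names(df)), collapse = ", "),
           class = "srvis_format_error")
  df$canonical <- as.logical(df$canonical)
  df
}

#' Read de novo mutation tables
#'
#' @param path TSV with columns `chrom`, `pos`, `consequence`,
#'   `polyphen2_humvar`, `cohort` and optionally `in_both_siblings`,
#'   `institute_labels`.
#' @return Data frame of de novo mutations.
#' @export
read_denovo <- function(path) {
  df <- read_tsv_table(path)
  need <- c("chrom", "pos", "consequence", "polyphen2_humvar", "cohort")
  if (!all(need %in% names(df)))
    .stopf("de novo file %s lacks columns: %s", path,
           paste(setdiff(need, names(df)), collapse = ", "),
           class = "srvis_format_error")
  if (!is.null(df$in_both_siblings))
    df$in_both_siblings <- as.logical(df$in_both_siblings)
  df
}
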