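#' Filter clinical variants down to the pathogenic missense test set
#'
#' Keeps variants that (a) come from a clinical database with a confident
#' pathogenic assertion — ClinVar entries labelled `"Pathogenic"` or HGMD
#' entries tagged `"DM"` — and (b) are canonical-transcript missense calls
#' that do not touch a splice site or truncate the protein: the annotation
#' must contain `missense_variant` and none of `incomplete_terminal_codon_variant`,
#' `splice_region_variant`, `stop_gained`, `stop_lost`. Loss-of-function
#' classes are excluded because they damage the whole protein regardless of
#' where they fall, so they carry no localization signal. Records identical
#' at (chrom, pos, alt) across sources are deduplicated (first kept).
#'
#' The filter is idempotent: applying it twice equals applying it once.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `source` (`"clinvar"`, `"hgmd"`, other), `clinical_label`, `canonical`
#'   (logical) and `consequence_terms` (comma-separated annotation terms).
#' @return The filtered, deduplicated subset.
#' @export
filter_pathogenic <- function(variants) {
  if (nrow(variants) == 0) return(variants)
  terms <- strsplit(variants$consequence_terms, ",", fixed = TRUE)
  terms <- lapply(terms, trimws)
  excluded <- c("incomplete_terminal_codon_variant", "splice_region_variant",
                "stop_gained", "stop_lost")
  keep <- ((variants$source == "clinvar" & variants$clinical_label == "Pathogenic") |
           (variants$source == "hgmd" & variants$clinical_label == "DM")) &
    variants$canonical &
    vapply(terms, function(t) "missense_variant" %in% t, logical(1)) &
    !vapply(terms, function(t) any(excluded %in% t), logical(1))
  out <- variants[keep, , drop = FALSE]
  out[!duplicated(paste(out$chrom, out$pos, out$alt)), , drop = FALSE]
}

#' Tally pathogenic variants per sub-region
#'
#' Assigns each filtered pathogenic variant to the sub-region containing its
#' position and returns per-region counts plus the presence flag used by the
#' genome-wide model (`present = 1` iff `count >= 1`).
#'
#' @param variants filtered pathogenic variants (see [filter_pathogenic()]).
#' @param regions cohort [region_table] for one division.
#' @param models named list of [gene_model()] objects.
#' @return Data frame `gene_id`, `region_index`, `count`, `present`; attr
#'   `"unassigned"` counts variants falling outside every region.
#' @export
tally_pathogenic <- function(variants, regions, models) {
  out <- regions[, c("gene_id", "region_index")]
  out$count <- 0L
  unassigned <- 0L
  if (nrow(variants) > 0) {
    key <- paste(out$gene_id, out$region_index)
    for (gid in unique(out$gene_id)) {
      gm <- models[[gid]]
      span <- range(gm$exons)
      cand <- which(variants$chrom == gm$chrom &
                    variants$pos >= span[1] & variants$pos < span[2])
      if (!length(cand)) next
      ridx <- assign_positions_to_regions(
        gm, regions[regions$gene_id == gid, , drop = FALSE], variants$pos[cand])
      hit <- !is.na(ridx)
      unassigned <- unassigned + sum(!hit)
      if (!any(hit)) next
      tab <- table(paste(gid, ridx[hit]))
      out$count[match(names(tab), key)] <-
        out$count[match(names(tab), key)] + as.integer(tab)
    }
  }
  out$present <- as.integer(out$count >= 1L)
  attr(out, "unassigned") <- unassigned
  out
}

#' Disease-risk summary per domain type
#'
#' Aggregates, across all genes, the pathogenic-variant tally and cumulative
#' mutation rate of every domain type, and reports their ratio — an
#' approximate count of reported pathogenic mutations after controlling for
#' sequence mutability. Unaligned stretches aggregate under their own
#' `"unaligned"` label.
#'
#' @param regions domain-division [region_table].
#' @param pathogenic per-region counts from [tally_pathogenic()].
#' @param rates per-region rates from [region_mutation_rates()].
#' @return Data frame `domain_id`, `tally`, `cumulative_rate`, `risk`
#'   (`tally / cumulative_rate`; `NA` where the cumulative rate is zero),
#'   sorted by decreasing risk.
#' @export
domain_type_risk_table <- function(regions, pathogenic, rates) {
  key <- paste(regions$gene_id, regions$region_index)
  cnt <- pathogenic$count[match(key, paste(pathogenic$gene_id, pathogenic$region_index))]
  z <- rates$mutation_rate[match(key, paste(rates$gene_id, rates$region_index))]
  tally <- tapply(cnt, regions$label, sum)
  crate <- tapply(z, regions$label, sum)
  out <- data.frame(domain_id = names(tally),
                    tally = as.integer(tally),
                    cumulative_rate = as.numeric(crate),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$risk <- ifelse(out$cumulative_rate > 0, out$tally / out$cumulative_rate, NA_real_)
  out[order(-out$risk, out$domain_id, na.last = TRUE), ]
}
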