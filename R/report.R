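#' Per-gene score profile report
#'
#' Assembles the plot-ready profile of one gene: its ordered sub-regions
#' with labels and intolerance scores, and the pathogenic variants assigned
#' to the region containing them (half-open interval convention, so a
#' variant on a region's start position belongs to that region). Suitable
#' for drawing a score step function with variant markers.
#'
#' @param gene_id the gene.
#' @param regions cohort [region_table].
#' @param scores data frame `gene_id`, `region_index`, `score`.
#' @param variants filtered pathogenic variants (may be empty).
#' @param models named list of [gene_model()] objects.
#' @return List of class `"gene_profile"` with elements `regions` (region
#'   rows plus `score`) and `variants` (variant rows plus `region_index`,
#'   `cds_pos`).
#' @export
gene_profile_report <- function(gene_id, regions, scores, variants, models) {
  gm <- models[[gene_id]]
  if (is.null(gm)) .stopf("unknown gene: %s", gene_id)
  r <- regions[regions$gene_id == gene_id, , drop = FALSE]
  r <- r[order(r$region_index), , drop = FALSE]
  r$score <- scores$score[match(paste(gene_id, r$region_index),
                                paste(scores$gene_id, scores$region_index))]
  v <- variants[variants$chrom == gm$chrom, , drop = FALSE]
  if (nrow(v) > 0) {
    cds <- map_genomic_to_cds(gm, v$pos)
    keep <- !is.na(cds)
    v <- v[keep, , drop = FALSE]
    v$cds_pos <- cds[keep]
    v$region_index <- assign_positions_to_regions(gm, r, v$pos)
  } else {
    v$cds_pos <- integer(0)
    v$region_index <- integer(0)
  }
  structure(list(gene_id = gene_id, regions = r, variants = v),
            class = "gene_profile")
}

#' @export
print.gene_profile <- function(x, ...) {
  cat(sprintf("<gene_profile> %s: %d regions, %d assigned variant(s)\n",
              x$gene_id, nrow(x$regions), nrow(x$variants)))
  print(x$regions[, c("region_index", "label", "cds_start", "cds_end", "score")],
        row.names = FALSE)
  invisible(x)
}

#' Plot a gene's intolerance profile
#'
#' Draws the per-region score as a step function over CDS coordinates with
#' pathogenic variants marked as points at their containing region's score.
#'
#' @param x a [gene_profile_report()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gene_profile <- function(x, ...) {
  r <- x$regions
  graphics::plot(NA, xlim = c(0, max(r$cds_end)),
                 ylim = range(r$score, na.rm = TRUE) + c(-0.5, 0.5),
                 xlab = "CDS position (nt)", ylab = "intolerance score",
                 main = x$gene_id, ...)
  graphics::segments(r$cds_start, r$score, r$cds_end, r$score, lwd = 3)
  if (nrow(x$variants) > 0) {
    vs <- r$score[match(x$variants$region_index, r$region_index)]
    graphics::points(x$variants$cds_pos, vs, pch = 21, bg = "blue")
  }
  invisible(x)
}
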