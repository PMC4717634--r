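#' Qualify population site records for scoring
#'
#' Keeps sites with adequate sequencing coverage and, for variant sites, a
#' passing filter status. Defaults follow the reference-cohort conventions
#' used throughout the package: at least 10x mean coverage and a `"PASS"`
#' variant filter.
#'
#' @param sites data frame with columns `chrom`, `pos`, `mean_coverage`,
#'   `filter_status`, `is_variant`, `alt_af` (alternate allele frequency) and
#'   `consequence` (`"synonymous"`, `"nonsynonymous"` or `"other"`).
#' @param min_coverage minimal mean coverage (default 10).
#' @param required_filter filter status a variant must carry (default
#'   `"PASS"`); non-variant coverage records are not filter-checked.
#' @return The qualifying subset of `sites`, original order preserved.
#' @export
qualify_sites <- function(sites, min_coverage = 10, required_filter = "PASS") {
  if (nrow(sites) == 0) return(sites)
  keep <- sites$mean_coverage >= min_coverage &
    (!sites$is_variant | sites$filter_status == required_filter)
  sites[keep, , drop = FALSE]
}

#' Fold an allele frequency to a minor allele frequency
#' @param af alternate allele frequency in `[0, 1]`.
#' @return `pmin(af, 1 - af)`.
#' @export
fold_maf <- function(af) pmin(af, 1 - af)

#' Tally qualifying variants per sub-region
#'
#' Counts, for every sub-region, the total number of qualifying variant sites
#' and the subset that are common functional variants: non-synonymous with
#' folded minor allele frequency strictly above `maf_threshold`. These two
#' counts are the predictor and response of the intolerance regression
#' fitted by [subrvis()].
#'
#' @param sites qualified site records (see [qualify_sites()]).
#' @param regions cohort [region_table].
#' @param models named list of [gene_model()] objects.
#' @param maf_threshold common-variant threshold on minor allele frequency,
#'   strict inequality (default 0.001, i.e. 0.1%).
#' @return Data frame with columns `gene_id`, `region_index`, `label`,
#'   `total_variants`, `common_functional`, one row per region (zero counts
#'   included). Variant sites mapping to no region are counted nowhere; their
#'   number is recorded in attribute `"unmapped"`.
#' @export
tally_region_counts <- function(sites, regions, models, maf_threshold = 0.001) {
  out <- regions[, c("gene_id", "region_index", "label")]
  out$total_variants <- 0L
  out$common_functional <- 0L
  v <- sites[sites$is_variant, , drop = FALSE]
  unmapped <- 0L
  if (nrow(v) > 0) {
    key <- paste(out$gene_id, out$region_index)
    for (gid in unique(out$gene_id)) {
      gm <- models[[gid]]
      span <- range(gm$exons)
      cand <- which(v$chrom == gm$chrom & v$pos >= span[1] & v$pos < span[2])
      if (!length(cand)) next
      ridx <- assign_positions_to_regions(
        gm, regions[regions$gene_id == gid, , drop = FALSE], v$pos[cand])
      hit <- !is.na(ridx)
      unmapped <- unmapped + sum(!hit)
      if (!any(hit)) next
      vk <- paste(gid, ridx[hit])
      tot <- table(vk)
      out$total_variants[match(names(tot), key)] <-
        out$total_variants[match(names(tot), key)] + as.integer(tot)
      # strict inequality; the epsilon keeps folded frequencies like
      # 1 - 0.999 (= 0.001 + 9e-19 in floating point) on the boundary
      common <- v$consequence[cand][hit] == "nonsynonymous" &
        fold_maf(v$alt_af[cand][hit]) > maf_threshold + 1e-12
      if (any(common)) {
        cf <- table(vk[common])
        out$common_functional[match(names(cf), key)] <-
          out$common_functional[match(names(cf), key)] + as.integer(cf)
      }
    }
  }
  attr(out, "unmapped") <- unmapped
  out
}
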