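# internal helpers shared across modules

# Deterministic 31-bit string hash, for per-gene RNG substreams.
.hash_string <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Seed a gene-specific substream from the run seed so per-gene results are
# reproducible regardless of the order genes are processed in.
.gene_seed <- function(seed, gene_id) {
  as.integer((as.numeric(seed) + .hash_string(gene_id)) %% 2147483647)
}

# Population (n-denominator) standard deviation, used to scale score vectors
# so logistic effect sizes are per-SD.
.pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

.stopf <- function(fmt, ..., class = "srvis_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "srvis_error")))
}

.msg <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}

#' Read or write plain TSV tables
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()] with the
#' conventions used by every file this package emits: tab-separated, header
#' line, no quoting, no row names.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_tsv_table()` returns a data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
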