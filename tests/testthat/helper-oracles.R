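# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# Externally studentized residuals from first principles: hat matrix and
# leave-one-out variance, no lm()/rstudent().
oracle_ext_studentized <- function(x, y) {
  X <- cbind(1, x)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  e <- as.numeric(y - H %*% y)
  n <- length(y); p <- 2
  h <- diag(H)
  s2_loo <- (sum(e^2) - e^2 / (1 - h)) / (n - p - 1)
  e / sqrt(s2_loo * (1 - h))
}

# Two-sided Fisher exact p by brute-force hypergeometric enumeration:
# sum the probabilities of all tables (with fixed margins) no more likely
# than the observed one.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k)), numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact tail probability of the gene covariance test by full enumeration of
# multinomial outcomes (small n_g and total only).
oracle_gene_test_exact <- function(Y, Z, X) {
  N <- sum(Y); n_g <- length(Y)
  prob <- Z / sum(Z)
  E <- N * prob
  C_obs <- stats::cov(Y - E, X)
  # enumerate all compositions of N into n_g parts
  grid <- expand.grid(rep(list(0:N), n_g))
  grid <- grid[rowSums(grid) == N, , drop = FALSE]
  p_tail <- 0
  for (r in seq_len(nrow(grid))) {
    y <- as.numeric(grid[r, ])
    if (stats::cov(y - E, X) <= C_obs + 1e-12)
      p_tail <- p_tail + stats::dmultinom(y, prob = prob)
  }
  p_tail
}

# small deterministic gene models used across tests
toy_gene_plus <- function() gene_model("TGP", "chr1", "+", c(100, 500, 1000),
                                       c(199, 701, 1051))
toy_gene_minus <- function() gene_model("TGM", "chr2", "-", c(100, 500, 1000),
                                        c(199, 701, 1051))
single_exon_gene <- function(len = 900) gene_model("TGS", "chr3", "+", 0, len)

random_gene_model <- function(id, n_exons, strand = "+") {
  lens <- sample(30:120, n_exons, replace = TRUE) * 3L
  gaps <- sample(50:500, n_exons, replace = TRUE)
  starts <- cumsum(gaps) + cumsum(c(0L, lens[-n_exons]))
  gene_model(id, "chrR", strand, starts, starts + lens)
}
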