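# Independent oracles used to freeze expected values. Each is a direct,
# self-contained computation kept deliberately separate from the package's
# own code paths.

# P(X >= k) for X ~ Poisson(lambda), by explicit pmf summation upward from k
poisson_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  term <- exp(k * log(lambda) - lambda - lgamma(k + 1))
  total <- 0
  i <- k
  repeat {
    total <- total + term
    i <- i + 1
    term <- term * lambda / i
    if (term < total * 1e-18 && i > lambda + k) break
  }
  total
}

# Benjamini-Hochberg step-up, written out by hand
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  pmin(adj, 1)[order(o)]
}

# Welch two-sample t-test from the textbook formulas
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# upper-tail hypergeometric p by exhaustive enumeration of all C(N, n) draws
hyper_enum_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K carry the term
  mean(hits >= k)
}

iv <- function(chrom, start, end, ...) {
  dimorphatac:::make_intervals(chrom, start, end, ...)
}

# small deterministic count matrix for unit tests
toy_count_matrix <- function(counts, strata = "autosome",
                             conditions = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts); m <- ncol(counts)
  if (length(strata) == 1) strata <- rep(strata, n)
  if (is.null(conditions)) conditions <- paste0("c", seq_len(m))
  regions <- data.frame(chrom = ifelse(strata == "X", "chrX", "chr2"),
                        start = seq_len(n) * 1000,
                        end = seq_len(n) * 1000 + 500,
                        name = sprintf("r%03d", seq_len(n)),
                        stratum = strata, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("s", seq_len(m)),
                        condition = conditions, stringsAsFactors = FALSE)
  count_matrix(regions, samples, counts)
}
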