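random_pwm <- function(w, bg = rep(0.25, 4), pc = 0.1) {
  probs <- matrix(stats::rgamma(4 * w, 1), 4)
  probs <- sweep(probs, 2, colSums(probs), "/")
  pwm("rand", probs, background = bg, pseudocount = pc)
}

# brute-force tail over all 4^w background sequences, on the same grid
brute_force_tail <- function(dist, bg, s0) {
  w <- ncol(dist$lods_int)
  combs <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- rowSums(matrix(dist$lods_int[cbind(as.vector(combs),
                                           rep(seq_len(w), each = 4^w))],
                       ncol = w))
  pr <- apply(matrix(bg[combs], ncol = w), 1, prod)
  sum(pr[sc >= s0])
}

test_that("the width-1 distribution matches direct enumeration", {
  m <- pwm("a1", matrix(c(0.97, 0.01, 0.01, 0.01), 4), pseudocount = 0)
  d <- score_distribution(m)
  s_top <- round(log2(0.97 / 0.25) / d$epsilon)
  expect_equal(dimorphatac:::tail_p(d, s_top), 0.25)
  expect_equal(dimorphatac:::tail_p(d, min(d$lods_int)), 1)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
})

test_that("a motif equal to the background scores zero everywhere", {
  m <- pwm("null", matrix(0.25, 4, 4), pseudocount = 0)
  d <- score_distribution(m)
  expect_equal(dimorphatac:::tail_p(d, 0), 1)
  expect_equal(length(d$pmf), 1)  # all mass on score 0
})

test_that("DP tails equal brute-force enumeration for widths up to 6", {
  set.seed(71)
  for (i in 1:10) {
    w <- sample(1:6, 1)
    bg <- as.numeric(stats::rgamma(4, 2)); bg <- bg / sum(bg)
    m <- random_pwm(w, bg = bg)
    d <- score_distribution(m)
    # probe the full support plus off-support grid points
    probe <- sort(unique(c(as.vector(d$lods_int), 0L,
                           as.integer(round(seq(min(d$lods_int) * w,
                                                max(d$lods_int) * w,
                                                length.out = 25))))))
    for (s0 in probe)
      expect_equal(dimorphatac:::tail_p(d, s0),
                   brute_force_tail(d, bg, s0), tolerance = 1e-12)
  }
})

test_that("tail probabilities are non-increasing and sum correctly", {
  set.seed(72)
  m <- random_pwm(8)
  d <- score_distribution(m)
  expect_true(all(diff(d$tail) <= 1e-15))
  expect_equal(d$tail[1], 1, tolerance = 1e-12)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
})

test_that("best-hit scanning honours strands and tie-breaking", {
  m <- pwm("a1", matrix(c(0.97, 0.01, 0.01, 0.01), 4), pseudocount = 0)
  d <- score_distribution(m)
  h <- scan_best_hit("AAAA", d)
  expect_equal(h$position, 0)      # leftmost tie, + strand
  expect_equal(h$strand, "+")
  expect_equal(h$pvalue, 0.25)
  h2 <- scan_best_hit("TTTT", d)
  expect_equal(h2$strand, "-")
  expect_equal(h2$pvalue, 0.25)
  h3 <- scan_best_hit("GGAG", d)   # best is the single A at + position 2
  expect_equal(h3$position, 2)
  expect_equal(h3$strand, "+")
})

test_that("degenerate sequences are flagged", {
  m <- fru_like_motif()
  d <- score_distribution(m)
  short <- scan_best_hit("ACG", d)
  expect_equal(short$pvalue, 1)
  expect_true(short$flagged)
  amb <- scan_best_hit("ACGTNNAT", d)
  expect_true(amb$flagged)
  expect_error(scan_best_hit("NNNNNNA", d), "ambiguous")
})

test_that("extending a sequence never worsens the best p-value", {
  set.seed(73)
  m <- fru_like_motif()
  d <- score_distribution(m)
  base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  p_prev <- scan_best_hit(base, d)$pvalue
  for (add in 1:5) {
    base <- paste0(base, paste(sample(c("A", "C", "G", "T"), 20,
                                      replace = TRUE), collapse = ""))
    p_now <- scan_best_hit(base, d)$pvalue
    expect_lte(p_now, p_prev)
    p_prev <- p_now
  }
})

test_that("reverse-complementing every sequence leaves best p-values unchanged", {
  set.seed(74)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
          collapse = ""), "")
  names(seqs) <- paste0("s", 1:20)
  rc <- vapply(seqs, dimorphatac:::revcomp, "")
  names(rc) <- names(seqs)
  h1 <- motif_scan_set(seqs, fru_like_motif(), background = "uniform")
  h2 <- motif_scan_set(rc, fru_like_motif(), background = "uniform")
  expect_equal(h1$pvalue, h2$pvalue)
  expect_equal(h1$score_bits, h2$score_bits)
})

test_that("class comparisons report KS and Fisher structure correctly", {
  hits <- data.frame(
    class = rep(c("A", "B"), each = 5),
    pvalue = c(rep(1, 5), rep(1e-4, 5)),
    length = 300)
  cc <- class_comparison(hits, threshold = 1e-3)
  expect_equal(cc$pairs$ks_D, 1)
  expect_equal(cc$pairs$below_a, 0)
  expect_equal(cc$pairs$below_b, 5)
  same <- data.frame(class = rep(c("A", "B"), each = 4),
                     pvalue = rep(c(0.9, 0.5, 1e-4, 0.2), 2), length = 300)
  cs <- class_comparison(same, threshold = 1e-3)
  expect_equal(cs$pairs$ks_D, 0)
  expect_equal(cs$pairs$fisher_odds, 1)
  expect_error(class_comparison(hits[hits$class == "A", ]), "2 classes")
})

test_that("ECDFs are valid cumulative distributions", {
  set.seed(75)
  hits <- data.frame(class = rep(c("x", "y"), each = 50),
                     pvalue = stats::runif(100), length = 300)
  cc <- class_comparison(hits)
  for (cl in c("x", "y")) {
    e <- cc$ecdf[cc$ecdf$class == cl, ]
    expect_true(all(diff(e$cumfreq) > 0))
    expect_equal(max(e$cumfreq), 1)
  }
})

test_that("motifs planted in closed regions are detected as class enrichment", {
  cfg <- sim_config(seed = 76,
                    genome = genome_spec(c("chr2", "chr3"), c(3e6, 3e6),
                                         c("autosome", "autosome")),
                    n_peaks_per_chrom = 200, peak_width = 300,
                    n_open_planted = 0, n_closed_planted = 200,
                    motif_plant_prob = c(unchanged = 0.1, FruM_open = 0.1,
                                         FruM_closed = 0.8, DCC = 0.1))
  sim <- simulate_counts(cfg)
  sq <- simulate_sequences(cfg, sim, fru_like_motif())
  hits <- motif_scan_set(sq$sequences, fru_like_motif())
  hits$class <- ifelse(hits$class == "FruM_closed", "closed", "unchanged")
  cc <- class_comparison(hits, threshold = 1e-3)
  pair <- cc$pairs[1, ]
  expect_lt(pair$fisher_p, 1e-6)
  expect_lt(pair$ks_p, 1e-6)
  expect_gt(pair$below_a / pair$n_a, pair$below_b / pair$n_b)
})
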