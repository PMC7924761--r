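# The generator is first-class code: these tests pin its mean structure,
# its distributional assumptions and its determinism.

test_that("expected counts follow the dosage/effect/cell-fraction factorization", {
  cfg <- sim_config(seed = 3, n_peaks_per_chrom = 50)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  sm <- sim$counts$samples
  # recompute mu from the recorded factors, independently of the generator
  for (j in seq_len(nrow(sm))) {
    x <- ifelse(tr$stratum == "X" & sm$sex[j] == "female", 2, 1)
    d <- ifelse(tr$class == "DCC" & sm$sex[j] == "male", cfg$dcc_boost, 1)
    g <- ifelse(tr$class == "FruM_open" & sm$sex[j] == "male" &
                  sm$fru[j] == "fru+", 2^cfg$delta,
                ifelse(tr$class == "FruM_closed" & sm$sex[j] == "male" &
                         sm$fru[j] == "fru+", 2^(-cfg$delta), 1))
    base <- cfg$baseline_mu * tr$cell_fraction * x * d * g
    # sample factor is shared by all peaks: mu column / base is constant
    ratio <- sim$mu[, j] / base
    expect_lt(diff(range(ratio)), 1e-10)
    expect_true(all(ratio > 0.7 - 1e-9 & ratio < 1.4 + 1e-9))
  }
})

test_that("female/male expected-count ratio at a non-DCC X peak is exactly 2", {
  cfg <- sim_config(seed = 4, n_peaks_per_chrom = 30, dcc_boost = 1,
                    frac_dcc_sites_on_X = 0, n_open_planted = 0,
                    n_closed_planted = 0)
  sim <- simulate_counts(cfg)
  sm <- sim$counts$samples
  xi <- which(sim$truth$stratum == "X")[1]
  f1 <- which(sm$sex == "female")[1]
  m1 <- which(sm$sex == "male")[1]
  # strip the per-sample library factor before comparing
  a1 <- which(sim$truth$stratum == "autosome")[1]
  ratio <- (sim$mu[xi, f1] / sim$mu[a1, f1]) /
    (sim$mu[xi, m1] / sim$mu[a1, m1])
  expect_equal(ratio, 2)
})

test_that("empirical count means and Poisson limit match the mean model", {
  cfg <- sim_config(seed = 5, n_peaks_per_chrom = 40, replicates = 250L,
                    alpha = 0, n_open_planted = 0, n_closed_planted = 0,
                    dcc_boost = 1)
  sim <- simulate_counts(cfg)
  mu <- sim$mu
  # per-cell Monte-Carlo: mean of (count - mu) scaled by Poisson sd
  z <- (sim$counts$counts - mu) / sqrt(mu)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) * 3)
  # alpha = 0 degenerates to Poisson: variance/mean ratio near 1
  expect_equal(mean(z^2), 1, tolerance = 0.1)
})

test_that("negative-binomial dispersion inflates variance as mu + alpha mu^2", {
  cfg <- sim_config(seed = 6, n_peaks_per_chrom = 40, replicates = 250L,
                    alpha = 0.2, cell_fraction_range = c(1, 1),
                    n_open_planted = 0, n_closed_planted = 0, dcc_boost = 1)
  sim <- simulate_counts(cfg)
  mu <- sim$mu
  v <- (sim$counts$counts - mu)^2
  expect_equal(mean(v / (mu + 0.2 * mu^2)), 1, tolerance = 0.1)
})

test_that("the same seed reproduces counts, fragments and sequences exactly", {
  cfg <- sim_config(seed = 11, n_peaks_per_chrom = 25,
                    n_open_planted = 10, n_closed_planted = 10)
  s1 <- simulate_counts(cfg); s2 <- simulate_counts(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  f1 <- simulate_fragments(cfg, s1); f2 <- simulate_fragments(cfg, s2)
  expect_identical(f1, f2)
  q1 <- simulate_sequences(cfg, s1, fru_like_motif())
  q2 <- simulate_sequences(cfg, s2, fru_like_motif())
  expect_identical(as.character(q1$sequences), as.character(q2$sequences))
})

test_that("emitted fragment midpoints reproduce the count matrix exactly", {
  cfg <- sim_config(seed = 12, n_peaks_per_chrom = 40)
  sim <- simulate_counts(cfg)
  fr <- simulate_fragments(cfg, sim)
  pk <- sim$counts$regions
  for (j in c(1, 5)) {
    f <- fr[[j]]
    mid <- floor((f$start + f$end) / 2)
    cnt <- vapply(seq_len(nrow(pk)), function(i)
      sum(f$chrom == pk$chrom[i] & mid >= pk$start[i] & mid < pk$end[i] &
            f$name == pk$name[i]), 0)
    expect_identical(as.integer(cnt), as.integer(sim$counts$counts[, j]))
    # conservation: every fragment is a peak fragment or background
    expect_equal(nrow(f),
                 sum(sim$counts$counts[, j]) + sum(f$name == "background"))
  }
})

test_that("with zero background all fragments lie within peaks", {
  cfg <- sim_config(seed = 13, n_peaks_per_chrom = 10,
                    n_open_planted = 5, n_closed_planted = 5,
                    background_rate = 0)
  sim <- simulate_counts(cfg)
  fr <- simulate_fragments(cfg, sim)
  expect_true(all(fr[[1]]$name != "background"))
})

test_that("fragment lengths follow the bimodal mixture", {
  cfg <- sim_config(seed = 14, n_peaks_per_chrom = 300, baseline_mu = 120)
  sim <- simulate_counts(cfg)
  fr <- simulate_fragments(cfg, sim)
  len <- unlist(lapply(fr, function(f) f$end - f$start))
  len <- len[len > 20]  # drop the truncation atom
  mix <- cfg$fragment_length_mix
  Fmix <- function(x) {
    num <- mix$weights[1] * stats::pnorm(x, mix$mean[1], mix$sd[1]) +
      mix$weights[2] * stats::pnorm(x, mix$mean[2], mix$sd[2])
    den <- mix$weights[1] * stats::pnorm(20, mix$mean[1], mix$sd[1]) +
      mix$weights[2] * stats::pnorm(20, mix$mean[2], mix$sd[2])
    (num - den) / (1 - den)
  }
  xs <- sort(len)
  D <- max(abs(seq_along(xs) / length(xs) - Fmix(xs + 0.5)))
  expect_lt(D, 0.05)
  # two modes near the configured means
  dens <- stats::density(len)
  expect_gt(dens$y[which.min(abs(dens$x - 75))],
            dens$y[which.min(abs(dens$x - 140))])
  expect_gt(dens$y[which.min(abs(dens$x - 200))],
            dens$y[which.min(abs(dens$x - 140))])
})

test_that("motif planting honours per-class probabilities", {
  m <- fru_like_motif()
  cfg0 <- sim_config(seed = 15, n_peaks_per_chrom = 30,
                     n_open_planted = 10, n_closed_planted = 10,
                     motif_plant_prob = c(unchanged = 0, FruM_open = 0,
                                          FruM_closed = 0, DCC = 0))
  s0 <- simulate_counts(cfg0)
  q0 <- simulate_sequences(cfg0, s0, m)
  expect_false(any(q0$truth$motif_planted))

  cfg1 <- sim_config(seed = 16, n_peaks_per_chrom = 30,
                     n_open_planted = 0, n_closed_planted = 50,
                     motif_plant_prob = c(unchanged = 0, FruM_open = 0,
                                          FruM_closed = 1, DCC = 0))
  s1 <- simulate_counts(cfg1)
  q1 <- simulate_sequences(cfg1, s1, m)
  closed <- q1$truth$class == "FruM_closed"
  expect_true(all(q1$truth$motif_planted[closed]))
  cons <- dimorphatac:::pwm_consensus(m)
  rc <- dimorphatac:::revcomp(cons)
  has <- vapply(as.character(q1$sequences[closed]), function(s)
    grepl(cons, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), TRUE)
  expect_true(all(has))
})

test_that("observed planting frequency sits inside the binomial 99% CI", {
  p0 <- 0.8
  cfg <- sim_config(seed = 17,
                    genome = genome_spec(c("chr2", "chr3"), c(4e6, 4e6),
                                         c("autosome", "autosome")),
                    n_peaks_per_chrom = 1000, n_closed_planted = 2000,
                    n_open_planted = 0,
                    motif_plant_prob = c(unchanged = 0.1, FruM_open = 0.1,
                                         FruM_closed = p0, DCC = 0.1))
  sim <- simulate_counts(cfg)
  q <- simulate_sequences(cfg, sim, fru_like_motif())
  n <- sum(q$truth$class == "FruM_closed")
  obs <- mean(q$truth$motif_planted[q$truth$class == "FruM_closed"])
  half <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  expect_gt(obs, p0 - half)
  expect_lt(obs, p0 + half)
})

test_that("planting more peaks than available errors", {
  expect_error(simulate_counts(sim_config(seed = 1, n_peaks_per_chrom = 10,
                                          n_open_planted = 15,
                                          n_closed_planted = 10)),
               "exceed")
})
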