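test_that("consensus regions follow the coverage-support rule", {
  s1 <- iv("chr1", 100, 200)
  s2 <- iv("chr1", 150, 250)
  both <- build_consensus(list(s1, s2), min_samples = 2)
  expect_equal(c(both$start, both$end), c(150, 200))
  either <- build_consensus(list(s1, s2), min_samples = 1)
  expect_equal(c(either$start, either$end), c(100, 250))
  disjoint <- build_consensus(list(iv("chr1", 0, 10), iv("chr1", 50, 60)),
                              min_samples = 2)
  expect_equal(nrow(disjoint), 0)
  expect_error(build_consensus(list(s1), min_samples = 2), "min_samples")
})

test_that("midpoint counting respects half-open region boundaries", {
  regions <- iv("chr1", c(100, 200), c(200, 300),
                name = c("a", "b"))
  regions$stratum <- "autosome"
  # midpoints: 100 (on start of a), 200 (start of b, = end of a), 299
  frags <- list(s1 = iv("chr1", c(95, 195, 294), c(105, 205, 304)))
  cm <- count_in_regions(frags, regions)
  expect_equal(unname(cm$counts[, 1]), c(1, 2))
  expect_error(count_in_regions(frags, iv("chr1", c(0, 50), c(60, 100))),
               "overlap")
})

test_that("counting conserves fragments when regions tile the genome", {
  set.seed(31)
  tile <- iv("chr1", seq(0, 9900, by = 100), seq(0, 9900, by = 100) + 100)
  tile$stratum <- "autosome"
  s <- sample(0:9898, 400, replace = TRUE)
  frags <- list(s1 = iv("chr1", s, s + 1))
  cm <- count_in_regions(frags, tile)
  expect_equal(sum(cm$counts), 400)
})

test_that("median-of-ratios size factors reproduce the worked example", {
  cm <- toy_count_matrix(matrix(c(10, 20, 30, 20, 40, 60), 3, 2))
  sf <- size_factors(cm, "pooled")
  expect_equal(sf$sf, c(sqrt(0.5), sqrt(2)), tolerance = 1e-6)
  # geometric mean 1
  expect_equal(exp(mean(log(sf$sf))), 1, tolerance = 1e-9)
  same <- toy_count_matrix(matrix(c(5, 9, 13, 5, 9, 13), 3, 2))
  expect_equal(size_factors(same, "pooled")$sf, c(1, 1))
})

test_that("doubling one sample's counts doubles its size factor", {
  set.seed(32)
  m <- matrix(stats::rpois(300, 60), 100, 3)
  cm1 <- toy_count_matrix(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  cm2 <- toy_count_matrix(m2)
  s1 <- size_factors(cm1, "pooled")$sf
  s2 <- size_factors(cm2, "pooled")$sf
  # ratio structure: sample 2 doubled relative to the others
  expect_equal((s2[2] / s2[1]) / (s1[2] / s1[1]), 2, tolerance = 1e-9)
})

test_that("all-zero-containing strata are rejected with advice", {
  cm <- toy_count_matrix(matrix(c(0, 1, 2, 0), 2, 2))
  expect_error(size_factors(cm, "pooled"), "depth")
})

test_that("method-of-moments dispersion matches the hand computation", {
  mat <- matrix(c(10, 20), 1, 2)
  d <- estimate_dispersion(mat, c(1, 1), list(1:2))
  # m = 15, v = 50, raw = (50 - 15) / 225
  expect_equal(d$raw[1], 35 / 225, tolerance = 1e-12)
  expect_gte(d$final[1], 1e-4)
})

test_that("Poisson counts drive the raw dispersion toward zero", {
  set.seed(33)
  mat <- matrix(stats::rpois(2000 * 50, 100), 2000, 50)
  d <- estimate_dispersion(mat, rep(1, 50), list(1:25, 26:50))
  expect_lt(stats::median(d$raw), 0.02)
})

test_that("the 1/mean trend recovers planted dispersion coefficients", {
  set.seed(34)
  n <- 2000; reps <- 10
  mu <- exp(stats::runif(n, log(5), log(500)))
  alpha <- 0.05 + 2 / mu
  mat <- matrix(stats::rnbinom(n * 2 * reps, mu = mu, size = 1 / alpha),
                n, 2 * reps)
  d <- estimate_dispersion(mat, rep(1, 2 * reps),
                           list(1:reps, reps + 1:reps))
  expect_lt(abs(d$a1 - 2) / 2, 0.2)
  expect_lt(abs(d$a0 - 0.05), 0.03)
})

test_that("the Wald test is symmetric and antisymmetric as required", {
  set.seed(35)
  mat <- matrix(stats::rpois(100 * 4, 50), 100, 4)
  sf <- rep(1, 4)
  al <- rep(0.05, 100)
  mat[1, ] <- c(40, 60, 40, 60)        # identical group means
  r <- nb_wald_test(mat, sf, al, 1:2, 3:4)
  expect_equal(r$log2fc[1], 0)
  expect_equal(r$pvalue[1], 1)
  rswap <- nb_wald_test(mat, sf, al, 3:4, 1:2)
  expect_equal(rswap$log2fc, -r$log2fc)
  expect_equal(rswap$pvalue, r$pvalue, tolerance = 1e-12)
})

test_that("null simulations give calibrated raw p-values", {
  set.seed(36)
  mat <- matrix(stats::rnbinom(2000 * 4, mu = 80, size = 1 / 0.05), 2000, 4)
  sf <- dimorphatac:::median_ratio_sf(mat)
  d <- estimate_dispersion(mat, sf, list(1:2, 3:4))
  r <- nb_wald_test(mat, sf, d$final, 1:2, 3:4)
  expect_gte(mean(r$pvalue < 0.05), 0.02)
  expect_lte(mean(r$pvalue < 0.05), 0.08)
})

test_that("stratified runs treat identical strata identically", {
  set.seed(37)
  m <- matrix(stats::rpois(50 * 4, 60), 50, 4)
  cm <- toy_count_matrix(rbind(m, m), strata = rep(c("autosome", "X"),
                                                   each = 50),
                         conditions = c("a", "a", "b", "b"))
  da <- stratified_differential(cm, list(id = "t", target = "b",
                                         reference = "a"),
                                mode = "stratified")
  A <- da[da$stratum == "autosome", ]
  X <- da[da$stratum == "X", ]
  expect_equal(A$log2fc, X$log2fc)
  expect_equal(A$fdr, X$fdr)
})

test_that("stratified normalization removes the X-dosage artifact pooled mode shows", {
  cfg <- bias_demo_config(seed = 38)
  sim <- simulate_counts(cfg)
  cmp <- list(id = "sex", target = "female_fru-", reference = "male_fru-")
  pooled <- stratified_differential(sim$counts, cmp, mode = "pooled")
  strat <- stratified_differential(sim$counts, cmp, mode = "stratified")
  cl <- sim$truth$class[match(pooled$name, sim$truth$name)]
  ndX <- pooled$stratum == "X" & cl != "DCC"
  expect_gt(mean(pooled$fdr[ndX] < 0.05 & pooled$log2fc[ndX] > 0), 0.5)
  expect_lte(mean(strat$fdr[ndX] < 0.05), 0.05)
  # the pooled artifact also leaks male bias onto the autosomes
  auto <- pooled$stratum == "autosome"
  expect_lt(mean(pooled$log2fc[auto]), 0)
  expect_lte(mean(strat$fdr[auto] < 0.05), 0.05)
})

test_that("rescaling one sample leaves fold changes invariant", {
  set.seed(39)
  m <- matrix(stats::rnbinom(400 * 4, mu = 150, size = 20), 400, 4)
  cm1 <- toy_count_matrix(m, conditions = c("a", "a", "b", "b"))
  m2 <- m; m2[, 3] <- m2[, 3] * 3L
  cm2 <- toy_count_matrix(m2, conditions = c("a", "a", "b", "b"))
  cmp <- list(id = "t", target = "b", reference = "a")
  r1 <- stratified_differential(cm1, cmp, mode = "pooled")
  r2 <- stratified_differential(cm2, cmp, mode = "pooled")
  keep <- r1$base_mean > 50
  expect_lt(max(abs(r1$log2fc[keep] - r2$log2fc[keep])), 0.01)
})

test_that("every region appears exactly once with finite log2fc", {
  cfg <- sim_config(seed = 40, n_peaks_per_chrom = 60)
  sim <- simulate_counts(cfg)
  da <- stratified_differential(sim$counts,
                                list(id = "fru", target = "male_fru+",
                                     reference = "male_fru-"),
                                mode = "stratified")
  expect_equal(sort(da$name), sort(sim$counts$regions$name))
  expect_true(all(is.finite(da$log2fc)))
  mh <- manhattan_table(da, cfg$genome)
  expect_equal(nrow(mh), nrow(da))
  expect_true(all(mh$bias %in% c("target_up", "target_down", "ns")))
})
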