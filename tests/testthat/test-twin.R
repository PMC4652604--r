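test_that("closed-form mean squares equal the lm/aov decomposition", {
  # hand case: pairs (1,3) and (5,7)
  ms <- anova_mean_squares(c(1, 3, 5, 7), c("p1", "p1", "p2", "p2"))
  expect_equal(ms$ms_within, 2)     # ((1-3)^2/2 + (5-7)^2/2) / 2
  expect_equal(ms$ms_among, 16)     # 2 * ((2-4)^2 + (6-4)^2) / 1
  expect_equal(ms$df_among, 1)
  expect_equal(ms$df_within, 2)
  # cross-check against the standard ANOVA fit on random data
  set.seed(23)
  for (rep in 1:5) {
    v <- rnorm(20)
    p <- rep(paste0("p", 1:10), each = 2)
    ours <- anova_mean_squares(v, p)
    ref <- anova(lm(v ~ factor(p)))
    expect_equal(ours$ms_among, ref$`Mean Sq`[1], tolerance = 1e-12)
    expect_equal(ours$ms_within, ref$`Mean Sq`[2], tolerance = 1e-12)
  }
  expect_equal(anova_mean_squares(c(2, 2, 5, 5),
                                  c("a", "a", "b", "b"))$ms_within, 0)
  all_eq <- anova_mean_squares(rep(3, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(all_eq$ms_among, 0)
  expect_equal(all_eq$ms_within, 0)
  expect_error(anova_mean_squares(1:3, c("a", "a", "b")),
               "exactly two members")
})

test_that("maximal heritability yields a large positive GWT", {
  # MZ pairs identical within pair, DZ members differing, built so
  # both groups have exactly equal total variance: the F' ratio is 1,
  # GWT is selected, MSW_MZ = 0 and the genetic p-value vanishes.
  mk <- function(z, means, diffs) {
    data.frame(pair_id = rep(paste0(z, seq_along(means)), each = 2),
               zygosity = z, member = rep(c("a", "b"), length(means)),
               night = 1,
               value = as.vector(rbind(means + diffs / 2,
                                       means - diffs / 2)))
  }
  q20 <- qnorm(ppoints(20))
  q10 <- qnorm(ppoints(10))
  msa_mz <- 2 * var(q20)
  msw_dz <- 0.5                       # constant within-pair difference 1
  a <- sqrt((msa_mz - msw_dz) / (2 * var(q10)))
  d <- rbind(mk("MZ", 4 + q20, rep(0, 20)),
             mk("DZ", 4 + a * q10, rep(1, 10)))
  g <- gva(d)
  expect_true(g$prerequisites$passed)
  expect_equal(g$estimator, "GWT")
  expect_equal(g$estimate, msw_dz, tolerance = 1e-9)
  expect_lt(g$genetic_p, 0.001)
  # the generator's maximal-heritability regime agrees
  sim <- generate_twin_dataset(twin_sim_spec(
    20, 10, var_genetic = 1, var_shared = 0, var_unique = 0.02,
    night_noise_sd = 0.01, seed = 24))
  gs <- gva(sim)
  expect_gt(gs$ms$DZ$ms_within, gs$ms$MZ$ms_within)
})

test_that("gva enforces its preconditions and prerequisites", {
  d <- generate_twin_dataset(twin_sim_spec(4, 2, seed = 3))
  expect_error(gva(d), "fewer than 3 pairs")
  # heavily shifted DZ means abort the genetic test
  d2 <- generate_twin_dataset(twin_sim_spec(16, 8, seed = 4))
  d2$value[d2$zygosity == "DZ"] <- d2$value[d2$zygosity == "DZ"] + 50
  g2 <- gva(d2)
  expect_false(g2$prerequisites$passed)
  expect_lt(g2$prerequisites$means_t_p, 0.05)
  expect_true(is.na(g2$genetic_p))
})

test_that("identical group variance structures give a null GWT", {
  # MZ and DZ groups built with exactly equal within-pair and
  # among-pair mean squares: the F' ratio is 1 (GWT selected), the
  # GWT estimate is exactly 0 and its p-value is the central
  # P(F(n_DZ, n_MZ) > 1).
  set.seed(25)
  scale_to <- function(x, target_var) {
    x <- x - mean(x)
    x * sqrt(target_var / (sum(x^2) / (length(x) - 1)))
  }
  mk <- function(z, means, diffs) {
    data.frame(pair_id = rep(paste0(z, seq_along(means)), each = 2),
               zygosity = z, member = rep(c("a", "b"), length(means)),
               night = 1,
               value = as.vector(rbind(means + diffs / 2,
                                       means - diffs / 2)))
  }
  mz_means <- 4 + scale_to(rnorm(16), 1)
  dz_means <- 4 + scale_to(rnorm(8), 1)     # MSA equal by construction
  d <- rbind(mk("MZ", mz_means, rep(0.7, 16)),
             mk("DZ", dz_means, rep(0.7, 8)))
  g <- gva(d)
  expect_gt(g$f_prime_p, 0.8)               # total-variance ratio is 1
  expect_equal(g$estimator, "GWT")
  expect_equal(g$estimate, 0, tolerance = 1e-9)
  expect_equal(g$genetic_p, pf(1, 8, 16, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("gva type-I error stays near the nominal 5% under the null", {
  sim <- shared_gva_type1()
  expect_gt(sim$performed, 1500)
  expect_gte(sim$rate, 0.03)
  expect_lte(sim$rate, 0.07)
})

test_that("gva power at 80% heritability matches the F-ratio expectation", {
  # GWT branch: MSW_DZ/MSW_MZ has true ratio (0.5*0.8 + 0.2)/0.2 = 3;
  # analytic branch power P(F(14,32) > qF(.95)/3) bounds the procedure
  branch_power <- pf(qf(0.95, 14, 32) / 3, 14, 32, lower.tail = FALSE)
  expect_gt(branch_power, 0.7)    # oracle for the simulation band below
  hit <- 0L; done <- 0L
  for (r in 1:400) {
    d <- generate_twin_dataset(twin_sim_spec(
      32, 14, var_genetic = 0.8, var_shared = 0, var_unique = 0.2,
      night_noise_sd = 0.05, seed = 20000 + r))
    g <- gva(d)
    if (g$prerequisites$passed) {
      done <- done + 1L
      if (g$genetic_p < 0.05) hit <- hit + 1L
    }
  }
  expect_gte(hit / done, 0.60)
  expect_lte(hit / done, branch_power + 0.07)
})

test_that("the ICC is affine-invariant and recovers known values", {
  v <- c(1, 2, 4, 5, 7, 9, 2, 3)
  p <- rep(paste0("p", 1:4), each = 2)
  r <- icc(v, p)
  expect_equal(icc(3 * v + 10, p), r, tolerance = 1e-12)
  # identical members: 1
  expect_equal(icc(c(2, 2, 7, 7, 4, 4), rep(c("a", "b", "c"), each = 2)), 1)
  # members mirrored around the grand mean: -1
  expect_equal(icc(c(-1, 1, -3, 3, -2, 2), rep(c("a", "b", "c"), each = 2)),
               -1)
  # parameter recovery at 500 pairs
  d <- generate_twin_dataset(twin_sim_spec(500, 0, var_genetic = 0.8,
    var_shared = 0, var_unique = 0.2, night_noise_sd = 0, seed = 26))
  s <- aggregate(value ~ pair_id + member, d, mean)
  expect_equal(icc(s$value, s$pair_id), 0.8, tolerance = 0.05)
  expect_error(icc(rep(1, 6), rep(c("a", "b", "c"), each = 2)),
               "degenerate")
})

test_that("the bootstrap stops at exactly 1000 positive ICCs", {
  set.seed(27)
  v <- rnorm(64)
  b <- bootstrap_icc_null(v, seed = 5)
  expect_equal(b$n_positive, 1000)
  expect_gte(b$n_draws, 1000)
  expect_gt(b$boot_p01, b$boot_median)
  expect_error(bootstrap_icc_null(rep(2, 10)), "constant")
  # deterministic given the seed
  b2 <- bootstrap_icc_null(v, seed = 5)
  expect_equal(b$boot_p01, b2$boot_p01)
})

test_that("smaller samples give larger bootstrap thresholds", {
  set.seed(28)
  p01 <- vapply(c(14, 32, 64), function(n)
    bootstrap_icc_null(rnorm(2 * n), seed = 6)$boot_p01, numeric(1))
  expect_true(all(diff(p01) < 0))
})

test_that("independent data rarely beat the bootstrap threshold", {
  set.seed(29)
  hits <- vapply(1:40, function(r) {
    v <- rnorm(28)                       # 14 pseudo-pairs
    orig <- icc(v, rep(1:14, each = 2))
    b <- bootstrap_icc_null(v, seed = 100 + r)
    orig < b$boot_p01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("twin ICC analysis distinguishes resemblance from stability", {
  d <- generate_twin_dataset(twin_sim_spec(32, 14, var_genetic = 0.8,
    var_shared = 0, var_unique = 0.2, night_noise_sd = 0.1, seed = 30))
  res <- twin_icc_analysis(d, "MZ", seed = 7)
  expect_gt(res$within_pair$icc, 0.6)
  expect_gt(res$night_stability$icc, 0.9)   # night noise is small
  expect_true(res$within_pair$label %in%
                c("substantial", "almost perfect"))
  res_dz <- twin_icc_analysis(d, "DZ", seed = 7)
  expect_lt(res_dz$within_pair$icc, res$within_pair$icc)
})
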