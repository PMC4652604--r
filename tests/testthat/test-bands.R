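test_that("the scan grid covers 9-16 Hz in 71 bins", {
  grid <- spindle_frequency_grid()
  expect_length(grid, 71)
  expect_equal(grid[1], 9)
  expect_equal(grid[71], 16)
  expect_equal(unique(round(diff(grid), 10)), 0.1)
})

test_that("signals without sigma activity give empty scan vectors", {
  set.seed(12)
  fs <- 100
  x <- 15 * sin(2 * pi * 3 * (0:(90 * fs - 1)) / fs) +
    rnorm(90 * fs, sd = 0.5)
  clean <- extract_stage_signal(x, fs, hypnogram(rep("S2", 3)), "S2")
  thr <- detection_thresholds(0.1)
  scan <- activity_scan(clean, clean, thr, thr)
  expect_equal(sum(scan$vec_slow), 0)
  expect_equal(sum(scan$vec_fast), 0)
})

test_that("the relation vector is antisymmetric and damped", {
  grid <- spindle_frequency_grid()
  mk <- function(vs, vf) {
    structure(list(freq_grid = grid, vec_slow = vs, vec_fast = vf),
              class = "activity_scan")
  }
  equal <- relation_vector(mk(rep(5, 71), rep(5, 71)))
  expect_equal(equal$vec_rel, rep(0, 71), tolerance = 1e-12)

  set.seed(13)
  vs <- rpois(71, 4); vf <- rpois(71, 4)
  a <- relation_vector(mk(vs, vf))
  b <- relation_vector(mk(vf, vs))
  expect_equal(a$vec_rel, -b$vec_rel, tolerance = 1e-12)

  spike <- rep(0, 71); spike[40] <- 50
  c <- relation_vector(mk(rep(0, 71), spike))
  expect_true(all(is.finite(c$vec_rel)))   # damping prevents blow-up
  expect_gt(c$vec_rel[40], 0)
})

test_that("sparse scans fall back to the fixed bands", {
  grid <- spindle_frequency_grid()
  scan <- structure(list(freq_grid = grid,
                         vec_slow = c(0, rep(1, 20), rep(0, 50)),
                         vec_fast = rep(2, 71)),
                    class = "activity_scan")
  b <- estimate_bands(scan)          # 20 < 30 frontal spindles
  expect_equal(b$source, "fixed_fallback")
  expect_equal(b$slow, c(11, 12.9))
  expect_equal(b$fast, c(13.1, 15))
  expect_equal(b$stop_detect, 9)
  # events in the 9-Hz bin do not count toward the minimum
  scan2 <- scan
  scan2$vec_slow <- c(100, rep(1, 20), rep(0, 50))
  expect_equal(estimate_bands(scan2)$source, "fixed_fallback")
})

test_that("band estimation recovers well-separated planted activity", {
  # idealized scan: Gaussian humps at 11.5 Hz (frontal) / 13.5 Hz
  # (parietal), as the planted trains produce
  grid <- spindle_frequency_grid()
  vs <- round(60 * exp(-((grid - 11.5) / 0.35)^2))
  vf <- round(60 * exp(-((grid - 13.5) / 0.35)^2))
  scan <- structure(list(freq_grid = grid, vec_slow = vs, vec_fast = vf),
                    class = "activity_scan")
  b <- estimate_bands(scan)
  expect_equal(b$source, "adjusted")
  expect_lt(abs(b$slow_cntr - 11.5), 0.3)
  expect_lt(abs(b$fast_cntr - 13.5), 0.3)
  expect_true(b$slow[1] <= 11.5 && 11.5 <= b$slow[2])
  expect_true(b$fast[1] <= 13.5 && 13.5 <= b$fast[2])
})

test_that("estimated bands always satisfy the ordering invariant", {
  set.seed(14)
  grid <- spindle_frequency_grid()
  for (rep in 1:25) {
    c1 <- runif(1, 10, 12.5); c2 <- runif(1, c1 + 0.8, 15.5)
    w1 <- runif(1, 0.2, 0.8); w2 <- runif(1, 0.2, 0.8)
    vs <- rpois(71, 2) + round(80 * exp(-((grid - c1) / w1)^2))
    vf <- rpois(71, 2) + round(80 * exp(-((grid - c2) / w2)^2))
    scan <- structure(list(freq_grid = grid, vec_slow = vs,
                           vec_fast = vf), class = "activity_scan")
    b <- estimate_bands(scan)
    expect_true(9 <= b$stop_detect)
    expect_true(b$stop_detect <= b$slow[1])
    expect_lt(b$slow[1], b$slow[2])
    expect_lt(b$slow[2], b$fast[1])
    expect_lt(b$fast[1], b$fast[2])
    expect_lte(b$fast[2], 16)
    expect_gte(b$slow[2] - b$slow[1], 0.5 - 1e-9)
    expect_gte(b$fast[2] - b$fast[1], 0.5 - 1e-9)
  }
})

test_that("dominance assigns each scanned event to at most one bin", {
  # one strong clean tone burst train: total accepted spindles must not
  # exceed the number of planted bursts
  set.seed(15)
  fs <- 100
  n <- 120 * fs
  x <- rnorm(n, sd = 0.8)
  starts <- seq(5, 110, by = 5)
  for (s in starts) {
    idx <- (s * fs):(s * fs + 99)
    x[idx] <- x[idx] + 12 * hann_window(100) *
      sin(2 * pi * 12.4 * (0:99) / fs)
  }
  clean <- extract_stage_signal(x, fs, hypnogram(rep("S2", 4)), "S2")
  thr <- detection_thresholds(basic_threshold(clean))
  scan <- activity_scan(clean, clean, thr, thr)
  # every burst is accepted exactly once at its true bin; bin-specific
  # event fragments may add a stray neighbour count but never inflate
  # the total beyond a few percent
  peak_bin <- scan$freq_grid[which.max(scan$vec_slow)]
  expect_lt(abs(peak_bin - 12.4), 0.3)
  expect_equal(max(scan$vec_slow), length(starts))
  expect_lte(sum(scan$vec_slow), ceiling(1.1 * length(starts)))
})

test_that("invalid band specifications are rejected", {
  expect_error(spindle_bands(c(12, 11), c(13, 14)), "invalid")
  expect_error(spindle_bands(c(11, 13.5), c(13, 14)), "invalid")
  expect_error(spindle_bands(c(11, 12), c(13, 16.5)), "invalid")
  expect_error(spindle_bands(c(11, 12), c(13, 13.2)), "invalid")
  expect_error(spindle_bands(c(11, 12), c(13, 14), stop_detect = 8),
               "invalid")
  b <- spindle_bands(c(11, 12.9), c(13.1, 16))
  expect_s3_class(b, "spindle_bands")
})
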