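test_that("band envelopes are selective maxima over their grids", {
  fs <- 100
  bands <- fixed_spindle_bands()
  expect_equal(max(band_envelopes(rep(0, 2000), bands, fs)$cwt_all), 0)

  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- 10 * sin(2 * pi * 13.5 * t)
  env <- band_envelopes(x, spindle_bands(c(11, 12), c(13, 14)), fs)
  mid <- 500:1500
  expect_true(all(env$cwt_fast[mid] > env$cwt_slow[mid]))
  expect_equal(env$cwt_all, pmax(env$cwt_slow, env$cwt_fast))
})

test_that("scoring accepts planted spindles and rejects low bursts", {
  set.seed(16)
  fs <- 100
  n <- 40 * fs
  x <- rnorm(n, sd = 1)
  add_burst <- function(x, at, freq, amp = 15, dur = 1) {
    idx <- (at * fs):(at * fs + dur * fs - 1)
    x[idx] <- x[idx] + amp * hann_window(length(idx)) *
      sin(2 * pi * freq * seq_along(idx) / fs)
    x
  }
  x <- add_burst(x, 5, 13.5)     # fast spindle
  x <- add_burst(x, 15, 11.5)    # slow spindle
  x <- add_burst(x, 25, 9)       # at the stop frequency: not a spindle
  bands <- fixed_spindle_bands()
  env <- band_envelopes(x, bands, fs)
  thr <- detection_thresholds(basic_threshold(x, min_duration = 30))

  all_ev <- score_all(env, thr)
  expect_equal(nrow(all_ev), 2)
  expect_true(any(abs(all_ev$onset - 5) < 0.5) &&
                any(abs(all_ev$onset - 15) < 0.5))

  fast_ev <- score_fast(env, thr)
  slow_ev <- score_slow(env, thr)
  expect_true(any(abs(fast_ev$onset - 5) < 0.5))
  expect_false(any(abs(fast_ev$onset - 15) < 0.5))
  expect_true(any(abs(slow_ev$onset - 15) < 0.5))
  expect_false(any(abs(slow_ev$onset - 5) < 0.5))

  # subthreshold signal scores nothing
  env0 <- band_envelopes(rnorm(n, sd = 1), bands, fs)
  expect_equal(nrow(score_all(env0, thr)), 0)
})

test_that("the stop-frequency comparison rejects sub-spindle bursts", {
  set.seed(17)
  fs <- 100
  n <- 30 * fs
  x <- rnorm(n, sd = 0.5)
  idx <- (10 * fs):(11.5 * fs)
  x[idx] <- x[idx] + 20 * hann_window(length(idx)) *
    sin(2 * pi * 9.2 * seq_along(idx) / fs)
  bands <- spindle_bands(c(10.5, 12), c(13, 14.5),
                         stop_detect = 9.3, source = "user_fixed")
  env <- band_envelopes(x, bands, fs)
  thr <- detection_thresholds(basic_threshold(x, min_duration = 20))
  # the 9.2 Hz burst leaks into the slow band envelope but its mean at
  # the stop frequency dominates
  expect_equal(nrow(score_all(env, thr)), 0)
  expect_equal(nrow(score_slow(env, thr)), 0)
})

test_that("fast and slow spindles never overlap in time", {
  # overlapping slow and fast bursts: dominance runs partition time, so
  # the two scorers may abut but never overlap
  set.seed(31)
  fs <- 100
  n <- 60 * fs
  x <- rnorm(n, sd = 0.8)
  for (at in seq(5, 50, by = 9)) {
    i1 <- (at * fs):((at + 1.5) * fs)           # slow burst
    i2 <- ((at + 1.0) * fs):((at + 2.5) * fs)   # fast burst, 0.5 s overlap
    x[i1] <- x[i1] + 18 * hann_window(length(i1)) *
      sin(2 * pi * 11.5 * seq_along(i1) / fs)
    x[i2] <- x[i2] + 18 * hann_window(length(i2)) *
      sin(2 * pi * 13.5 * seq_along(i2) / fs)
  }
  env <- band_envelopes(x, fixed_spindle_bands(), fs)
  thr <- detection_thresholds(basic_threshold(x, min_duration = 50))
  f <- score_fast(env, thr)
  s <- score_slow(env, thr)
  expect_gt(nrow(f), 0)
  expect_gt(nrow(s), 0)
  expect_equal(nrow(event_overlap_sets(f, s, 1e-6)$consensus), 0)
})

test_that("event measurement reports 0.1 Hz spectra and true tones", {
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- 12 * sin(2 * pi * 13 * t)
  m <- measure_event(x, 10, 11, fs)
  expect_equal(m$frequency, 13, tolerance = 0.1 + 1e-9)
  expect_equal(round(m$frequency / 0.1) * 0.1, m$frequency,
               tolerance = 1e-9)                  # on the 0.1 Hz grid
  expect_gt(m$amplitude, 4)                       # Hann-tapered tone
  expect_error(measure_event(rep(0, 3000), 10, 11, fs), "degenerate")
  expect_error(measure_event(x, 5, 16, fs), "10-s")
})

test_that("measured frequencies of planted spindles are accurate", {
  run <- shared_run_fixed()
  g <- shared_synth()
  errs <- c()
  for (ch in c("F3A2", "P3A2")) {
    det <- run$events[run$events$type == "all" &
                        run$events$channel == ch, ]
    gt <- g$ground_truth[g$ground_truth$channel == ch &
                           g$ground_truth$weight == 1, ]
    m <- event_overlap_sets(gt, det, 0.3)
    errs <- c(errs, det$frequency[m$consensus$index_b] -
                gt$frequency[m$consensus$index_a])
  }
  expect_gte(length(errs), 50)
  expect_lte(median(abs(errs)), 0.2)
})

test_that("summaries report densities and a consistent activity index", {
  hyp <- hypnogram(c("S2", "S2", "REM"))
  ev <- data.frame(onset = seq(1, 50, length.out = 8))
  ev$offset <- ev$onset + 1
  ev$channel <- "C3A2"
  ev$type <- "all"
  ev$amplitude <- 10
  ev$frequency <- 13
  ev$stage <- "S2"
  s <- summarize_spindles(ev, hyp, "S2")
  row <- s[s$type == "all", ]
  expect_equal(row$count, 8)
  expect_equal(row$density, 4)
  expect_equal(row$activity,
               row$count * row$mean_amplitude * row$mean_duration)
  none <- summarize_spindles(ev[0, ], hyp, "S2")
  expect_equal(none$count, rep(0, 3))
  expect_true(all(is.na(none$mean_amplitude)))
})
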