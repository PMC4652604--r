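test_that("resampling to 100 Hz preserves sample count and content", {
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "C3A2")
  out <- resample_100hz(rec)
  expect_equal(out$fs, 100)
  expect_equal(ncol(out$data), 6000)
  rec100 <- eeg_recording(matrix(rnorm(1000), 1), 100, "C3A2")
  expect_identical(resample_100hz(rec100), rec100)
  rec10 <- eeg_recording(matrix(rnorm(100), 1), 10, "C3A2")
  expect_error(resample_100hz(rec10), "unsupported")
})

test_that("a grid-aligned 1-s EMG burst masks exactly 7 s", {
  fs <- 100
  n <- 60 * fs
  x <- rep(0, n)
  t <- (0:(n - 1)) / fs
  idx <- t >= 20 & t < 21
  x[idx] <- 11.3 * sin(2 * pi * 30 * (t[idx] - 20))  # in-band SD ~8 uV
  m <- emg_artifact_mask(x, fs)
  expect_equal(masked_seconds(m), 7)
  expect_true(all(m$reason[m$flags] == "emg"))
  # the masked run is the exceeding window padded by 3 s on each side
  run <- range(which(m$flags))
  expect_equal((run[1] - 1) / fs, 17)
  expect_equal(run[2] / fs, 24)
})

test_that("EMG masking ignores signals below the SD criterion", {
  expect_equal(masked_seconds(emg_artifact_mask(rep(0, 6000))), 0)
  # stationary in-band signal with SD 5.0 in every window: the rolling
  # SD oracle confirms no window exceeds 5.75
  fs <- 100
  t <- (0:(60 * fs - 1)) / fs
  x <- 5 * sqrt(2) * sin(2 * pi * 30 * t)     # in-band SD 5.0
  filt <- fir_design(c(19.8, 45.5), fs, "pass", 201L)
  xf <- fir_apply(x, filt)
  sds <- vapply(seq(1, length(x) - fs + 1, by = fs / 2),
                function(s) sd(xf[s:(s + fs - 1)]), numeric(1))
  expect_true(all(sds < 5.75))                # oracle precondition
  expect_lt(max(abs(sds[5:100] - 5.0)), 0.1)
  expect_equal(masked_seconds(emg_artifact_mask(x, fs)), 0)
})

test_that("EMG masking is monotone in artifact amplitude", {
  fs <- 100
  n <- 60 * fs
  t <- (0:(n - 1)) / fs
  base <- rep(0, n)
  idx <- t >= 30 & t < 31.5
  masked <- sapply(c(10, 20, 40), function(a) {
    x <- base
    x[idx] <- a * sin(2 * pi * 30 * t[idx])
    masked_seconds(emg_artifact_mask(x, fs))
  })
  expect_true(all(diff(masked) >= 0))
  expect_gt(masked[1], 0)
})

test_that("alpha exclusion masks alpha-dominated segments only", {
  fs <- 100
  n <- 60 * fs
  t <- (0:(n - 1)) / fs
  # pure delta: never excluded
  expect_equal(masked_seconds(alpha_exclusion_mask(
    20 * sin(2 * pi * 3 * t), fs)), 0)
  # delta background with an embedded strong 10 Hz segment
  x <- 10 * sin(2 * pi * 3 * t)
  mid <- t >= 15 & t < 45
  x[mid] <- x[mid] + 30 * sin(2 * pi * 10 * t[mid])
  m <- alpha_exclusion_mask(x, fs)
  expect_gte(masked_seconds(m), 15)
  masked_t <- t[m$flags]
  expect_true(all(masked_t > 5 & masked_t < 55))  # central region only
  # equal alpha and delta mean band amplitudes: 1.1 factor not exceeded
  # (bands hold 9 and 17 quarter-Hz bins, so amplitudes 9 and 17 give
  # identical per-bin means)
  x_eq <- 9 * sin(2 * pi * 3 * t) + 17 * sin(2 * pi * 10 * t)
  expect_equal(masked_seconds(alpha_exclusion_mask(x_eq, fs)), 0)
})

test_that("stage extraction keeps clean in-stage runs", {
  fs <- 100
  n <- 120 * fs
  x <- rnorm(n)
  hyp_all <- hypnogram(rep("S2", 4))
  seg <- extract_stage_signal(x, fs, hyp_all, "S2")
  expect_length(seg$segments, 1)
  expect_length(seg$segments[[1]], n)
  expect_equal(seg$onsets, 0)

  hyp_alt <- hypnogram(c("S2", "REM", "S2", "REM"))
  seg2 <- extract_stage_signal(x, fs, hyp_alt, "S2")
  expect_length(seg2$segments, 2)
  expect_equal(seg2$onsets, c(0, 60))
  expect_equal(lengths(seg2$segments), rep(30 * fs, 2))

  # a 7-s central mask splits one epoch into two segments of 23 s total
  hyp1 <- hypnogram("S2")
  x1 <- rnorm(30 * fs)
  flags <- rep(FALSE, 30 * fs)
  flags[(11 * fs + 1):(18 * fs)] <- TRUE
  m <- exclusion_mask(flags, fs)
  seg3 <- extract_stage_signal(x1, fs, hyp1, "S2", m)
  expect_length(seg3$segments, 2)
  expect_equal(sum(lengths(seg3$segments)) / fs, 23)

  hyp_rem <- hypnogram(rep("REM", 4))
  expect_error(extract_stage_signal(x, fs, hyp_rem, "S2"),
               "no samples")
})

test_that("clean plus masked-or-offstage durations partition the recording", {
  set.seed(21)
  fs <- 100
  n <- 150 * fs
  x <- rnorm(n)
  hyp <- hypnogram(c("S2", "SWS", "REM", "S2", "Wake"))
  flags <- rep(FALSE, n)
  flags[sample(n, 2000)] <- TRUE
  m <- exclusion_mask(flags, fs)
  seg <- extract_stage_signal(x, fs, hyp, c("S2", "SWS"), m)
  t_sec <- (seq_len(n) - 1) / fs
  in_stage <- stage_at(hyp, t_sec) %in% c("S2", "SWS")
  expect_equal(sum(lengths(seg$segments)), sum(in_stage & !flags))
})
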