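# Individual adjustment of slow and fast spindle frequency ranges by
# comparing frontal and parietal spindle-event frequency distributions.

#' Frequency grid of the spindle activity scan
#'
#' @param lo,hi,step grid limits and step in Hz.
#' @return numeric vector: 9.0, 9.1, ..., 16.0 (71 bins) by default.
#' @export
spindle_frequency_grid <- function(lo = 9, hi = 16, step = 0.1) {
  round(seq(lo, hi, by = step), 10)
}

#' Spindle activity scan over the 9-16 Hz range
#'
#' For each 0.1 Hz bin of the scan grid, spindle events are detected on
#' that bin's CWT envelope (two-threshold rule) in the frontal and the
#' parietal channel separately, each channel using its own thresholds.
#' An event is counted for a bin only if that bin is dominant for the
#' event: its mean envelope over the event fragment strictly exceeds
#' the event's mean envelope at every other bin. The per-bin counts
#' form `vec_slow` (frontal channel) and `vec_fast` (parietal channel).
#'
#' @param frontal_clean,parietal_clean [extract_stage_signal()] results
#'   for the frontal and parietal channel.
#' @param thr_frontal,thr_parietal [detection_thresholds()] per channel.
#' @param freq_grid scan grid in Hz.
#' @param fs sampling rate in Hz.
#' @param f0 Morlet central frequency parameter.
#' @param min_duration minimum event duration in seconds.
#' @return object of class `activity_scan`: list with `freq_grid`,
#'   `vec_slow`, `vec_fast` (accepted-spindle counts per bin).
#' @export
activity_scan <- function(frontal_clean, parietal_clean,
                          thr_frontal, thr_parietal,
                          freq_grid = spindle_frequency_grid(),
                          fs = 100, f0 = 2, min_duration = 0.5) {
  scan_one <- function(clean, thr) {
    counts <- numeric(length(freq_grid))
    for (seg in clean$segments) {
      half_max <- morlet_kernel(min(freq_grid), f0, fs)$half
      if (length(seg) <= 2L * half_max) next
      env <- cwt_magnitude(seg, freq_grid, fs, f0)
      for (j in seq_along(freq_grid)) {
        ev <- detect_events(env[j, ], thr, fs, min_duration)
        if (!nrow(ev)) next
        for (i in seq_len(nrow(ev))) {
          cols <- (round(ev$onset[i] * fs) + 1L):round(ev$offset[i] * fs)
          m <- rowMeans(env[, cols, drop = FALSE])
          if (m[j] > max(m[-j])) counts[j] <- counts[j] + 1
        }
      }
    }
    counts
  }
  structure(list(freq_grid = freq_grid,
                 vec_slow = scan_one(frontal_clean, thr_frontal),
                 vec_fast = scan_one(parietal_clean, thr_parietal)),
            class = "activity_scan")
}

#' @export
print.activity_scan <- function(x, ...) {
  cat(sprintf(
    "<activity_scan> %d bins %.1f-%.1f Hz; %d frontal / %d parietal spindles\n",
    length(x$freq_grid), min(x$freq_grid), max(x$freq_grid),
    sum(x$vec_slow), sum(x$vec_fast)))
  invisible(x)
}

# Centered moving average; the window shrinks at the edges.
smooth_ma <- function(v, window_bins = 7L) {
  n <- length(v)
  half <- window_bins %/% 2L
  vapply(seq_len(n), function(i)
    mean(v[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' Relation vector between parietal and frontal spindle activity
#'
#' Prepares the activity vectors (9-Hz bin zeroed, two passes of a
#' 0.7 Hz moving average) and computes the antisymmetric damped ratio
#' `vec_rel`: with `v_f = vec_fast + 0.5 * mean_act` and
#' `v_s = vec_slow + 0.5 * mean_act`,
#' `vec_rel = v_f/v_s - 1` where `v_f >= v_s` and
#' `-(v_s/v_f - 1)` otherwise, followed by one smoothing pass.
#' `mean_act` is the grand mean of both smoothed activity vectors; the
#' damping keeps `vec_rel` finite and small where few spindles were
#' counted. `vec_rel` is positive where parietal (fast) activity
#' dominates and negative where frontal (slow) activity dominates.
#'
#' @param scan an [activity_scan()].
#' @param damp damping fraction of `mean_act` added to both vectors.
#' @param smooth_hz moving-average window in Hz.
#' @return the scan, augmented with `vs_smooth`, `vf_smooth`,
#'   `mean_act` and `vec_rel`.
#' @export
relation_vector <- function(scan, damp = 0.5, smooth_hz = 0.7) {
  stopifnot(inherits(scan, "activity_scan"))
  step <- scan$freq_grid[2] - scan$freq_grid[1]
  wbins <- max(1L, round(smooth_hz / step))
  vs <- scan$vec_slow
  vf <- scan$vec_fast
  vs[1] <- 0                              # 9-Hz bin aliases lower bursts
  vf[1] <- 0
  vs <- smooth_ma(smooth_ma(vs, wbins), wbins)
  vf <- smooth_ma(smooth_ma(vf, wbins), wbins)
  mean_act <- mean(c(vs, vf))
  dvf <- vf + damp * mean_act
  dvs <- vs + damp * mean_act
  rel <- ifelse(dvf >= dvs, dvf / dvs - 1, -(dvs / dvf - 1))
  rel[!is.finite(rel)] <- 0               # all-zero scan
  scan$vs_smooth <- vs
  scan$vf_smooth <- vf
  scan$mean_act <- mean_act
  scan$vec_rel <- smooth_ma(rel, wbins)
  scan
}

#' Slow/fast spindle frequency bands
#'
#' Constructor validating the band invariant chain
#' `9 <= stop_detect <= slow[1] < slow[2] < fast[1] < fast[2] <= 16`
#' with each band at least 0.5 Hz wide.
#'
#' @param slow,fast numeric `c(lo, hi)` in Hz.
#' @param stop_detect frequency in Hz below which events are treated as
#'   non-spindles and used as the rejection reference.
#' @param slow_cntr,fast_cntr central frequencies in Hz (optional).
#' @param source `"adjusted"`, `"fixed_fallback"` or `"user_fixed"`.
#' @return object of class `spindle_bands`.
#' @export
spindle_bands <- function(slow, fast, stop_detect = 9,
                          slow_cntr = mean(slow), fast_cntr = mean(fast),
                          source = c("adjusted", "fixed_fallback",
                                     "user_fixed")) {
  source <- match.arg(source)
  ok <- 9 - 1e-9 <= stop_detect && stop_detect <= slow[1] + 1e-9 &&
    slow[1] < slow[2] && slow[2] < fast[1] && fast[1] < fast[2] &&
    fast[2] <= 16 + 1e-9 &&
    slow[2] - slow[1] >= 0.5 - 1e-9 && fast[2] - fast[1] >= 0.5 - 1e-9
  if (!ok)
    stop("invalid spindle bands: need 9 <= stop_detect <= slow.lo < ",
         "slow.hi < fast.lo < fast.hi <= 16 with widths >= 0.5 Hz")
  structure(list(slow = slow, fast = fast, stop_detect = stop_detect,
                 slow_cntr = slow_cntr, fast_cntr = fast_cntr,
                 source = source),
            class = "spindle_bands")
}

#' @export
print.spindle_bands <- function(x, ...) {
  cat(sprintf(
    "<spindle_bands> slow %.1f-%.1f Hz (cntr %.1f), fast %.1f-%.1f Hz (cntr %.1f), stop %.1f Hz [%s]\n",
    x$slow[1], x$slow[2], x$slow_cntr, x$fast[1], x$fast[2],
    x$fast_cntr, x$stop_detect, x$source))
  invisible(x)
}

#' Fixed spindle frequency bands
#'
#' The fixed ranges used when only central derivations are available:
#' slow 11-12.9 Hz, fast 13.1-16 Hz, stop frequency 9 Hz.
#' @param slow,fast,stop_detect band limits in Hz.
#' @export
fixed_spindle_bands <- function(slow = c(11, 12.9), fast = c(13.1, 16),
                                stop_detect = 9) {
  spindle_bands(slow, fast, stop_detect, source = "user_fixed")
}

#' Estimate individual spindle bands from an activity scan
#'
#' Implements the frontal-vs-parietal comparison: the minimum of
#' `vec_rel` gives the slow spindle central frequency; the maximum of
#' `vec_rel` above it, shifted to the nearest local maximum of the
#' smoothed parietal activity vector, gives the fast central frequency.
#' The fast band spans the zero crossings of the second derivative of
#' the smoothed parietal vector flanking the fast centre; the slow band
#' extends up to the highest bin below the fast band where frontal
#' activity exceeds parietal, and down to the first bin (descending)
#' where `vec_rel` has recovered to 60% of its minimum. `stop_detect`
#' is the highest bin below the slow band where parietal activity
#' exceeds frontal, or 9 Hz. Bands are widened symmetrically to at
#' least 0.5 Hz. With fewer than `min_spindles` accepted events in
#' either channel the fixed fallback bands (slow 11-12.9, fast 13.1-15,
#' stop 9) are returned with `source = "fixed_fallback"`.
#'
#' @param scan an [activity_scan()].
#' @param min_spindles minimum accepted spindles per channel.
#' @param recover_frac `vec_rel` recovery fraction defining the lower
#'   slow edge (0.6 = "40% higher than the minimum").
#' @return a [spindle_bands()].
#' @export
estimate_bands <- function(scan, min_spindles = 30, recover_frac = 0.6) {
  stopifnot(inherits(scan, "activity_scan"))
  grid <- scan$freq_grid
  n <- length(grid)
  raw_s <- scan$vec_slow; raw_s[1] <- 0
  raw_f <- scan$vec_fast; raw_f[1] <- 0
  if (sum(raw_s) < min_spindles || sum(raw_f) < min_spindles)
    return(spindle_bands(c(11, 12.9), c(13.1, 15), 9,
                         source = "fixed_fallback"))
  if (is.null(scan$vec_rel)) scan <- relation_vector(scan)
  rel <- scan$vec_rel
  vs <- scan$vs_smooth
  vf <- scan$vf_smooth
  step <- grid[2] - grid[1]

  i_slow <- which.min(rel)
  above <- seq_len(n) > i_slow
  i_fast_cand <- which(above)[which.max(rel[above])]

  # shift the fast centre to the nearest local maximum of vf within 1 Hz
  is_locmax <- vapply(seq_len(n), function(i) {
    l <- if (i > 1L) vf[i - 1L] else -Inf
    r <- if (i < n) vf[i + 1L] else -Inf
    vf[i] >= l && vf[i] >= r
  }, logical(1))
  cand <- which(is_locmax & abs(grid - grid[i_fast_cand]) <= 1 + 1e-9 &
                  seq_len(n) > i_slow)
  i_fast <- if (length(cand)) {
    d <- abs(cand - i_fast_cand)
    cand[d == min(d)][1]                 # tie -> lower frequency
  } else i_fast_cand

  # fast band: second-derivative zero crossings flanking the centre
  d2 <- c(NA, diff(vf, differences = 2), NA)
  sgn <- sign(d2)
  crossing <- which(sgn[-n] * sgn[-1] <= 0 & is.finite(sgn[-n] * sgn[-1]))
  left <- crossing[crossing < i_fast]
  right <- crossing[crossing >= i_fast]
  i_flo <- if (length(left)) max(left) + 1L else
    min(n, max(i_slow + 1L, i_fast - round(0.5 / step)))
  i_fhi <- if (length(right)) min(right) else n
  fast_lo <- grid[min(i_flo, i_fast)]
  fast_hi <- grid[max(i_fhi, i_fast)]

  # slow upper edge: highest bin below the fast band with vs > vf
  below_fast <- which(grid < fast_lo - 1e-9 & vs > vf)
  slow_hi <- if (length(below_fast)) grid[max(below_fast)]
             else grid[i_slow]

  # slow lower edge: vec_rel recovered to recover_frac of its minimum
  thr_rel <- recover_frac * rel[i_slow]   # rel[i_slow] < 0 in practice
  j <- i_slow
  while (j > 1L && rel[j] < thr_rel) j <- j - 1L
  slow_lo <- grid[j]

  # widen to the minimum width around the centres
  widen <- function(lo, hi, cntr, min_width = 0.5) {
    lo <- min(lo, cntr); hi <- max(hi, cntr)
    while (hi - lo < min_width - 1e-9) {
      lo <- round(lo - step, 10); hi <- round(hi + step, 10)
    }
    c(max(9, lo), min(16, hi))
  }
  fast <- widen(fast_lo, fast_hi, grid[i_fast])
  slow <- widen(slow_lo, slow_hi, grid[i_slow])

  # resolve the chain slow.lo < slow.hi < fast.lo < fast.hi
  if (slow[2] >= fast[1]) slow[2] <- round(fast[1] - step, 10)
  if (slow[2] - slow[1] < 0.5) slow[1] <- round(slow[2] - 0.5, 10)
  if (slow[1] < 9) {
    slow[1] <- 9
    slow[2] <- max(slow[2], 9.5)
    if (slow[2] >= fast[1]) fast[1] <- round(slow[2] + step, 10)
    if (fast[2] - fast[1] < 0.5) fast[2] <- min(16, fast[1] + 0.5)
  }

  # stop frequency: highest bin below the slow band with vf > vs
  below_slow <- which(grid < slow[1] - 1e-9 & vf > vs)
  stop_f <- if (length(below_slow)) grid[max(below_slow)] else 9
  stop_f <- min(stop_f, slow[1])

  spindle_bands(round(slow, 1), round(fast, 1), round(stop_f, 1),
                slow_cntr = grid[i_slow], fast_cntr = grid[i_fast],
                source = "adjusted")
}
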