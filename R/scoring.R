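# Classification of detected events into all/slow/fast spindles, and
# measurement of spindle amplitude and frequency.

#' Band envelopes used for spindle scoring
#'
#' `cwt_slow` and `cwt_fast` are, at each time point, the maximum CWT
#' magnitude over the slow and fast band's 0.1 Hz frequency grid
#' (endpoints inclusive); `cwt_stop` is the envelope at the single
#' `stop_detect` frequency; `cwt_all` is the pointwise maximum of
#' `cwt_slow` and `cwt_fast`.
#'
#' @param x numeric signal segment at `fs` Hz.
#' @param bands a [spindle_bands()].
#' @param fs sampling rate in Hz.
#' @param f0 Morlet central frequency parameter.
#' @param grid_step envelope frequency grid step in Hz.
#' @return object of class `band_envelopes`: list with `cwt_slow`,
#'   `cwt_fast`, `cwt_stop`, `cwt_all`, `fs`, `bands`.
#' @export
band_envelopes <- function(x, bands, fs = 100, f0 = 2, grid_step = 0.1) {
  stopifnot(inherits(bands, "spindle_bands"))
  gs <- seq(bands$slow[1], bands$slow[2], by = grid_step)
  gf <- seq(bands$fast[1], bands$fast[2], by = grid_step)
  env <- cwt_magnitude(x, c(gs, gf, bands$stop_detect), fs, f0)
  i_s <- seq_along(gs)
  i_f <- length(gs) + seq_along(gf)
  cwt_slow <- apply(env[i_s, , drop = FALSE], 2, max)
  cwt_fast <- apply(env[i_f, , drop = FALSE], 2, max)
  structure(list(cwt_slow = cwt_slow, cwt_fast = cwt_fast,
                 cwt_stop = env[nrow(env), ],
                 cwt_all = pmax(cwt_slow, cwt_fast),
                 fs = fs, bands = bands),
            class = "band_envelopes")
}

# Mean of an envelope over an event's samples.
event_mean <- function(env, onset, offset, fs) {
  mean(env[(round(onset * fs) + 1L):round(offset * fs)])
}

#' Score all sleep spindles (no slow/fast distinction)
#'
#' Events are detected on `cwt_all` with the two-threshold rule, then a
#' marked fragment is accepted only if its mean `cwt_all` exceeds its
#' mean envelope at the `stop_detect` frequency, rejecting bursts whose
#' activity peaks below the spindle range.
#'
#' @param env a [band_envelopes()].
#' @param thr [detection_thresholds()] for this channel.
#' @param min_duration minimum event duration in seconds.
#' @return data.frame with `onset`, `offset` in segment seconds.
#' @export
score_all <- function(env, thr, min_duration = 0.5) {
  ev <- detect_events(env$cwt_all, thr, env$fs, min_duration)
  if (!nrow(ev)) return(ev)
  keep <- vapply(seq_len(nrow(ev)), function(i)
    event_mean(env$cwt_all, ev$onset[i], ev$offset[i], env$fs) >
      event_mean(env$cwt_stop, ev$onset[i], ev$offset[i], env$fs),
    logical(1))
  ev[keep, , drop = FALSE]
}

# Shared machinery for the slow/fast scorers: events are maximal runs
# where the primary envelope strictly dominates the rival AND exceeds
# SA; kept if >= min_duration and the primary peak exceeds SP.
score_dominant <- function(primary, rival, thr, fs, min_duration) {
  runs <- run_bounds(primary > rival & primary > thr$SA)
  if (!nrow(runs)) return(empty_intervals())
  min_len <- ceiling(min_duration * fs - 1e-9)
  keep <- vapply(seq_len(nrow(runs)), function(i)
    (runs$end[i] - runs$start[i] + 1L) >= min_len &&
      max(primary[runs$start[i]:runs$end[i]]) > thr$SP, logical(1))
  runs <- runs[keep, , drop = FALSE]
  data.frame(onset = (runs$start - 1L) / fs, offset = runs$end / fs)
}

#' Score fast sleep spindles
#'
#' Fast spindles are maximal runs where `cwt_fast` is continuously
#' higher than `cwt_slow` and the spindle criteria hold for `cwt_fast`.
#' No `stop_detect` comparison is applied for fast spindles.
#'
#' @inheritParams score_all
#' @export
score_fast <- function(env, thr, min_duration = 0.5) {
  score_dominant(env$cwt_fast, env$cwt_slow, thr, env$fs, min_duration)
}

#' Score slow sleep spindles
#'
#' Like [score_fast()] with the roles of the envelopes swapped, plus
#' the `stop_detect` mean comparison: a fragment is accepted only if
#' its mean `cwt_slow` exceeds its mean `cwt_stop`.
#'
#' @inheritParams score_all
#' @export
score_slow <- function(env, thr, min_duration = 0.5) {
  ev <- score_dominant(env$cwt_slow, env$cwt_fast, thr, env$fs,
                       min_duration)
  if (!nrow(ev)) return(ev)
  keep <- vapply(seq_len(nrow(ev)), function(i)
    event_mean(env$cwt_slow, ev$onset[i], ev$offset[i], env$fs) >
      event_mean(env$cwt_stop, ev$onset[i], ev$offset[i], env$fs),
    logical(1))
  ev[keep, , drop = FALSE]
}

#' Measure spindle amplitude and dominant frequency
#'
#' The raw segment is band-pass filtered (-3 dB at 8.7 and 18.5 Hz), a
#' Hann window spanning exactly the event fragment is applied, the
#' fragment is zero-padded to a 10-s window and the amplitude spectrum
#' computed, giving 0.1 Hz resolution. The height and location of the
#' maximum spectral peak within the spindle range are returned. The
#' spectrum is scaled as `2|FFT|/sum(hann)`, so a pure tone of
#' amplitude A filling the fragment reports approximately A.
#'
#' @param x raw signal segment (unfiltered) at `fs` Hz.
#' @param onset,offset event bounds in seconds within the segment.
#' @param fs sampling rate in Hz.
#' @param filter_band -3 dB points of the measurement pre-filter (Hz).
#' @param pad_seconds zero-padding target in seconds (sets the 0.1 Hz
#'   grid); events longer than this are unsupported.
#' @param search_band frequency range searched for the peak (Hz).
#' @return list with `amplitude` (uV) and `frequency` (Hz).
#' @export
measure_event <- function(x, onset, offset, fs = 100,
                          filter_band = c(8.7, 18.5),
                          pad_seconds = 10, search_band = c(9, 16)) {
  stopifnot(offset > onset, onset >= 0)
  if (offset - onset > pad_seconds)
    stop("event longer than the ", pad_seconds, "-s measurement window")
  s <- round(onset * fs) + 1L
  e <- round(offset * fs)
  stopifnot(e <= length(x))
  filt <- fir_cached(filter_band, fs, "pass", 201L)
  xf <- fir_apply(x, filt)
  frag <- xf[s:e]
  if (all(abs(frag) < 1e-12))
    stop("degenerate event fragment: no spectral peak")
  sp <- amplitude_spectrum(frag, fs, window = hann_window(length(frag)),
                           n_fft = round(pad_seconds * fs))
  sel <- which(sp$freq >= search_band[1] - 1e-9 &
                 sp$freq <= search_band[2] + 1e-9)
  i <- sel[which.max(sp$amplitude[sel])]
  list(amplitude = sp$amplitude[i], frequency = round(sp$freq[i], 10))
}

#' Summarize detected spindles per type and stage
#'
#' Events are assigned to the 30-s epoch containing their onset. For
#' every spindle type the summary reports the count, the density
#' (spindles per analysed epoch), mean duration, mean amplitude, mean
#' frequency, and the spindle activity index
#' `count * mean amplitude * mean duration`.
#'
#' @param events event data.frame (with `type`, optionally `amplitude`,
#'   `frequency`).
#' @param hyp a [hypnogram()].
#' @param stages stage labels analysed (defines the epoch denominator).
#' @param types spindle types to summarize.
#' @return data.frame, one row per type, with `n_epochs` attached.
#' @export
summarize_spindles <- function(events, hyp, stages = c("S2"),
                               types = c("all", "slow", "fast")) {
  n_epochs <- sum(hyp$stages %in% stages)
  if (n_epochs == 0) stop("no epochs of the requested stage(s)")
  rows <- lapply(types, function(ty) {
    ev <- events[events$type == ty, , drop = FALSE]
    cnt <- nrow(ev)
    mdur <- if (cnt) mean(ev$offset - ev$onset) else NA_real_
    mamp <- if (cnt && !is.null(ev$amplitude)) mean(ev$amplitude)
            else NA_real_
    mfreq <- if (cnt && !is.null(ev$frequency)) mean(ev$frequency)
             else NA_real_
    data.frame(type = ty, count = cnt, density = cnt / n_epochs,
               mean_duration = mdur, mean_amplitude = mamp,
               mean_frequency = mfreq,
               activity = if (cnt) cnt * mamp * mdur else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_epochs") <- n_epochs
  out
}
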