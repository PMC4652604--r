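# Preprocessing: resampling to the 100 Hz working rate and exclusion of
# muscle-artifact and alpha-dominated segments.

.fir_cache <- new.env(parent = emptyenv())

# Cached calibrated FIR designs (the same few filters are reused for
# every channel).
fir_cached <- function(f3db, fs, type, n_taps) {
  key <- paste(c(format(f3db, digits = 10), fs, type, n_taps),
               collapse = "|")
  if (is.null(.fir_cache[[key]]))
    .fir_cache[[key]] <- fir_design(f3db, fs, type, n_taps)
  .fir_cache[[key]]
}

#' Resample a recording to the 100 Hz working rate
#'
#' Fourier (band-limited, anti-aliased) resampling of every channel.
#' The detector operates at 100 Hz throughout, giving a time resolution
#' of 0.01 s.
#'
#' @param rec an [eeg_recording()] with `fs >= 100`.
#' @param fs_out output rate in Hz.
#' @return an `eeg_recording` at `fs_out`; returned unchanged when the
#'   input already has that rate.
#' @export
resample_100hz <- function(rec, fs_out = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs == fs_out) return(rec)
  if (rec$fs < fs_out)
    stop("sampling rate below ", fs_out,
         " Hz is unsupported (got ", rec$fs, " Hz)")
  rows <- lapply(seq_len(nrow(rec$data)), function(i)
    fft_resample(rec$data[i, ], rec$fs, fs_out))
  eeg_recording(do.call(rbind, rows), fs_out, rec$channel_labels,
                rec$channel_role, rec$start_time)
}

#' Mask segments contaminated by muscle (EMG) artifacts
#'
#' The channel is band-pass filtered to the EMG-sensitive range
#' (-3 dB at 19.8 and 45.5 Hz by default) and the standard deviation is
#' computed over a 1-s sliding window stepped by 0.5 s. Windows whose
#' in-band SD exceeds `sd_limit` microvolts define exceedance
#' fragments; each fragment, padded by `pad` seconds on both sides and
#' clipped to the signal bounds, is excluded from further analysis.
#'
#' @param x single-channel signal at `fs` Hz, in microvolts.
#' @param fs sampling rate in Hz.
#' @param sd_limit SD threshold in microvolts.
#' @param band -3 dB points of the EMG band-pass in Hz.
#' @param window,step SD window length and step in seconds.
#' @param pad padding around each exceedance fragment in seconds.
#' @return an [exclusion_mask()] with reason `"emg"`.
#' @export
emg_artifact_mask <- function(x, fs = 100, sd_limit = 5.75,
                              band = c(19.8, 45.5), window = 1,
                              step = 0.5, pad = 3) {
  n <- length(x)
  flags <- rep(FALSE, n)
  wlen <- round(window * fs)
  if (n >= wlen) {
    filt <- fir_cached(band, fs, "pass", 201L)
    xf <- fir_apply(x, filt)
    starts <- seq(1L, n - wlen + 1L, by = round(step * fs))
    for (s in starts) {
      if (stats::sd(xf[s:(s + wlen - 1L)]) > sd_limit) {
        lo <- max(1L, s - round(pad * fs))
        hi <- min(n, s + wlen - 1L + round(pad * fs))
        flags[lo:hi] <- TRUE
      }
    }
  }
  exclusion_mask(flags, fs, ifelse(flags, "emg", "none"))
}

#' Mask segments dominated by alpha activity
#'
#' Long runs of alpha waves (8-12 Hz) resemble spindle trains and are
#' excluded by comparing alpha with delta activity. The signal is
#' high-pass filtered (-3 dB at 1.4 Hz), amplitude spectra are computed
#' on 4-s Hann windows stepped by 1 s, and per-second mean amplitudes
#' are stored for the 2-4 Hz (delta) and 8-12 Hz (alpha) bands. A 15-s
#' sliding window (step 1 s) then Hann-weights and averages the 15
#' per-second values of each band, yielding `alpha_activity` and
#' `delta_activity`; the whole 15-s fragment is excluded whenever
#' `alpha_activity > ratio * delta_activity` (strict).
#'
#' @param x single-channel signal at `fs` Hz.
#' @param fs sampling rate in Hz.
#' @param ratio exclusion factor (alpha vs delta), default 1.1.
#' @param spec_window spectral window length in seconds.
#' @param compare_window comparison window length in seconds.
#' @param alpha_band,delta_band band limits in Hz (inclusive).
#' @return an [exclusion_mask()] with reason `"alpha"`; its
#'   `"profile"` attribute carries the per-second band amplitudes and
#'   the per-window `alpha_activity` / `delta_activity` values.
#' @export
alpha_exclusion_mask <- function(x, fs = 100, ratio = 1.1,
                                 spec_window = 4, compare_window = 15,
                                 alpha_band = c(8, 12),
                                 delta_band = c(2, 4)) {
  n <- length(x)
  flags <- rep(FALSE, n)
  wlen <- round(spec_window * fs)
  prof <- NULL
  if (n >= compare_window * fs) {
    filt <- fir_cached(1.4, fs, "high", 401L)
    xf <- fir_apply(x, filt)
    starts <- seq(1L, n - wlen + 1L, by = round(fs))  # one per second
    taper <- hann_window(wlen)
    band_mean <- function(sp, band) {
      sel <- sp$freq >= band[1] - 1e-9 & sp$freq <= band[2] + 1e-9
      mean(sp$amplitude[sel])
    }
    alpha <- delta <- numeric(length(starts))
    for (i in seq_along(starts)) {
      sp <- amplitude_spectrum(xf[starts[i]:(starts[i] + wlen - 1L)],
                               fs, window = taper)
      alpha[i] <- band_mean(sp, alpha_band)
      delta[i] <- band_mean(sp, delta_band)
    }
    m <- length(alpha)
    w <- hann_window(compare_window)
    alpha_act <- delta_act <- rep(NA_real_, max(0L, m - compare_window + 1L))
    if (m >= compare_window) {
      for (i in seq_len(m - compare_window + 1L)) {
        seg <- i:(i + compare_window - 1L)
        alpha_act[i] <- sum(alpha[seg] * w) / sum(w)
        delta_act[i] <- sum(delta[seg] * w) / sum(w)
        if (alpha_act[i] > ratio * delta_act[i]) {
          lo <- (i - 1L) * fs + 1L
          hi <- min(n, (i - 1L + compare_window) * fs)
          flags[lo:hi] <- TRUE
        }
      }
    }
    prof <- list(second = seq_along(starts) - 1L, alpha = alpha,
                 delta = delta, alpha_activity = alpha_act,
                 delta_activity = delta_act)
  }
  m <- exclusion_mask(flags, fs, ifelse(flags, "alpha", "none"))
  attr(m, "profile") <- prof
  m
}

#' Extract clean signal segments belonging to selected sleep stages
#'
#' Returns the maximal contiguous runs of samples whose epoch stage is
#' in `stages` and which are not excluded by the mask -- exactly the
#' signal used for threshold estimation and spindle detection.
#'
#' @param x single-channel signal at `fs` Hz.
#' @param fs sampling rate in Hz.
#' @param hyp a [hypnogram()] covering (at most) the recording.
#' @param stages character vector of stage labels to keep.
#' @param mask optional [exclusion_mask()] for this channel.
#' @return object of class `clean_segments`: list with `segments` (list
#'   of numeric vectors), `onsets` (seconds from recording start, one
#'   per segment) and `fs`. Total clean duration is reported by
#'   `sum(lengths(x$segments)) / x$fs`.
#' @export
extract_stage_signal <- function(x, fs, hyp, stages = c("S2"),
                                 mask = NULL) {
  n <- length(x)
  t_sec <- (seq_len(n) - 1L) / fs
  keep <- stage_at(hyp, t_sec) %in% stages
  if (!is.null(mask)) {
    stopifnot(length(mask$flags) == n, mask$fs == fs)
    keep <- keep & !mask$flags
  }
  if (!any(keep))
    stop("no samples remain after stage selection and exclusion")
  runs <- run_bounds(keep)
  segs <- lapply(seq_len(nrow(runs)), function(i)
    x[runs$start[i]:runs$end[i]])
  structure(list(segments = segs, onsets = (runs$start - 1L) / fs,
                 fs = fs),
            class = "clean_segments")
}

#' @export
print.clean_segments <- function(x, ...) {
  cat(sprintf("<clean_segments> %d segment(s), %.1f s total at %g Hz\n",
              length(x$segments),
              sum(lengths(x$segments)) / x$fs, x$fs))
  invisible(x)
}
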