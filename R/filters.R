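# Linear-phase FIR filtering and spectral helpers shared across the detector.

#' Design a linear-phase FIR filter with calibrated -3 dB points
#'
#' Windowed-sinc (Hamming) design whose ideal cutoffs are iteratively
#' adjusted so that the measured half-power (-3 dB) frequencies of the
#' realized filter match the requested ones. The detector's filtering
#' stages are specified by their -3 dB points, not by ideal cutoffs, so
#' calibration is part of the design.
#'
#' @param f3db numeric vector of target -3 dB frequencies in Hz: length 1
#'   for `type = "low"`/`"high"`, length 2 (low, high) for `"pass"`.
#' @param fs sampling rate in Hz.
#' @param type filter type: `"low"`, `"high"` or `"pass"`.
#' @param n_taps odd number of taps (default 201; use more for edges
#'   below ~2 Hz so the transition band can resolve).
#' @param tol calibration tolerance in Hz on each -3 dB point.
#' @return object of class `fir_filter`: list with `h` (coefficients),
#'   `fs`, `f3db_target`, `f3db_measured`, `type`.
#' @export
fir_design <- function(f3db, fs, type = c("pass", "low", "high"),
                       n_taps = 201L, tol = 0.05) {
  type <- match.arg(type)
  n_edges <- if (type == "pass") 2L else 1L
  stopifnot(length(f3db) == n_edges, all(f3db > 0), all(f3db < fs / 2))
  if (type == "pass" && f3db[1] >= f3db[2])
    stop("band-pass -3 dB points must be increasing")
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L

  build <- function(cut) {
    cut <- pmin(pmax(cut, 1e-3), fs / 2 - 1e-3)
    w <- switch(type,
      low  = cut / (fs / 2),
      high = cut / (fs / 2),
      pass = sort(cut) / (fs / 2))
    as.numeric(signal::fir1(n_taps - 1L, w, type = type,
                            window = signal::hamming(n_taps)))
  }

  cut <- f3db
  for (i in seq_len(40L)) {
    h <- build(cut)
    meas <- fir_3db_points(h, fs, f3db, type)
    err <- f3db - meas
    if (all(is.finite(err)) && max(abs(err)) < tol) break
    err[!is.finite(err)] <- 0
    cut <- cut + err
  }
  meas <- fir_3db_points(h, fs, f3db, type)
  if (any(!is.finite(meas)) || max(abs(f3db - meas)) > 4 * tol)
    stop("FIR calibration failed to reach requested -3 dB points; ",
         "increase n_taps")
  structure(list(h = h, fs = fs, f3db_target = f3db,
                 f3db_measured = meas, type = type),
            class = "fir_filter")
}

# Measured -3 dB crossings of a realized FIR near the requested edges.
fir_3db_points <- function(h, fs, near, type) {
  nfft <- max(2^15, stats::nextn(length(h) * 8, 2))
  H <- abs(stats::fft(c(h, rep(0, nfft - length(h)))))[1:(nfft / 2)]
  f <- (seq_along(H) - 1) * fs / nfft
  target <- 1 / sqrt(2)
  vapply(seq_along(near), function(k) {
    # rising edge for high-pass / lower band edge; falling otherwise
    rising <- (type == "high") || (type == "pass" && k == 1L)
    win <- f > max(0, near[k] - fs / 8) & f < min(fs / 2, near[k] + fs / 8)
    idx <- which(win)
    Hk <- H[idx]
    cross <- if (rising) which(Hk[-1] >= target & Hk[-length(Hk)] < target)
             else which(Hk[-1] <= target & Hk[-length(Hk)] > target)
    if (!length(cross)) return(NA_real_)
    # crossing nearest the requested edge, linearly interpolated
    j <- cross[which.min(abs(f[idx][cross] - near[k]))]
    f0 <- f[idx][j]; f1 <- f[idx][j + 1]
    y0 <- Hk[j];     y1 <- Hk[j + 1]
    f0 + (target - y0) * (f1 - f0) / (y1 - y0)
  }, numeric(1))
}

#' Apply a linear-phase FIR filter with group-delay compensation
#'
#' Convolves the signal with the filter and removes the (n_taps-1)/2
#' sample group delay, so filtered features stay time-aligned with the
#' raw signal. Edges are computed with implicit zero padding.
#'
#' @param x numeric signal vector.
#' @param filt `fir_filter` from [fir_design()].
#' @return filtered signal, same length as `x`.
#' @export
fir_apply <- function(x, filt) {
  stopifnot(inherits(filt, "fir_filter"))
  h <- filt$h
  n <- length(x)
  half <- (length(h) - 1L) %/% 2L
  y <- fft_conv(x, h)
  y[(half + 1L):(half + n)]
}

# Real linear convolution via FFT, full length n + L - 1.
fft_conv <- function(x, h) {
  n <- length(x); L <- length(h)
  nfft <- stats::nextn(n + L - 1L, 2)
  y <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                  stats::fft(c(h, rep(0, nfft - L))), inverse = TRUE)
  Re(y[1:(n + L - 1L)]) / nfft
}

# Complex linear convolution via FFT (for wavelet kernels).
fft_conv_complex <- function(x, h) {
  n <- length(x); L <- length(h)
  nfft <- stats::nextn(n + L - 1L, 2)
  y <- stats::fft(stats::fft(c(as.complex(x), rep(0i, nfft - n))) *
                  stats::fft(c(as.complex(h), rep(0i, nfft - L))),
                  inverse = TRUE)
  y[1:(n + L - 1L)] / nfft
}

#' Resample a signal by Fourier interpolation
#'
#' Band-limited resampling: the spectrum is truncated at the output
#' Nyquist frequency (ideal anti-aliasing) and inverse-transformed on the
#' new sample grid. The input is trimmed by at most a fraction of an
#' input sample so that the duration maps to an integer number of output
#' samples.
#'
#' @param x numeric signal.
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return numeric vector of length `floor(length(x) * fs_out / fs_in)`.
#' @export
fft_resample <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (fs_in == fs_out) return(x)
  r <- fs_out / fs_in
  n_out <- floor(length(x) * r)
  # trim input so n_in * fs_out / fs_in is an integer
  n_in <- floor(n_out / r + 1e-9)
  x <- x[seq_len(n_in)]
  X <- stats::fft(x)
  Y <- complex(n_out)
  half <- n_out %/% 2L
  Y[1] <- X[1]
  if (half > 1L) {
    k <- seq_len(half - 1L)
    Y[k + 1L] <- X[k + 1L]
    Y[n_out - k + 1L] <- X[n_in - k + 1L]
  }
  if (n_out %% 2L == 0L) Y[half + 1L] <- Re(X[half + 1L])
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

#' One-sided amplitude spectrum of a (windowed) fragment
#'
#' Returns the single-sided amplitude spectrum scaled so that a pure
#' tone of amplitude A that fills the fragment reports approximately A:
#' `2 * |FFT| / sum(window)`. With `window = NULL` a rectangular window
#' (sum = length) is used.
#'
#' @param x numeric fragment.
#' @param fs sampling rate in Hz.
#' @param window optional taper of the same length as `x`, applied
#'   before the FFT.
#' @param n_fft FFT length (zero-padding if larger than `length(x)`).
#' @return list with `freq` (Hz) and `amplitude` vectors.
#' @export
amplitude_spectrum <- function(x, fs, window = NULL, n_fft = length(x)) {
  n <- length(x)
  stopifnot(n_fft >= n)
  if (!is.null(window)) {
    stopifnot(length(window) == n)
    x <- x * window
    denom <- sum(window)
  } else denom <- n
  X <- stats::fft(c(x, rep(0, n_fft - n)))
  half <- n_fft %/% 2L
  amp <- 2 * Mod(X[seq_len(half + 1L)]) / denom
  amp[1] <- amp[1] / 2
  if (n_fft %% 2L == 0L) amp[half + 1L] <- amp[half + 1L] / 2
  list(freq = (0:half) * fs / n_fft, amplitude = amp)
}

#' Hann (raised-cosine) window
#'
#' Symmetric Hann taper `0.5 * (1 - cos(2*pi*k/(n-1)))`, the envelope
#' used both for spectral estimation windows and for the waxing-waning
#' envelope of generated spindles.
#'
#' @param n window length in samples.
#' @return numeric vector of length `n`.
#' @export
hann_window <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}
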