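# Complex Morlet wavelet, CWT magnitude envelopes and the two-threshold
# event detector -- the heart of the spindle detector.

#' Sampled complex Morlet wavelet for a target frequency
#'
#' Builds the mother wavelet
#' `psi(u) = pi^(-1/4) * exp(i*2*pi*f0*u) * exp(-u^2)`, `u = (t - b)/a`,
#' dilated to the scale `a = f0 / freq` so that the carrier frequency of
#' the kernel equals `freq`. With the default central frequency
#' `f0 = 2` the wavelet holds a handful of oscillations under its
#' Gaussian envelope and closely resembles a spindle. The support is
#' truncated where the envelope falls below 1e-6 of its peak, and the
#' kernel is L1-normalized (`sum(|psi|) * dt = 2`) so that a sinusoid of
#' amplitude A at the kernel frequency yields a steady-state CWT
#' magnitude of approximately A in signal units.
#'
#' @param freq target (carrier) frequency in Hz; must lie in (0, fs/2).
#' @param f0 central frequency parameter of the mother wavelet.
#' @param fs sampling rate in Hz.
#' @return object of class `morlet_kernel`: list with complex `kernel`,
#'   `freq`, `f0`, `scale` (a, seconds), `fs` and `half` (half-support
#'   in samples).
#' @export
morlet_kernel <- function(freq, f0 = 2, fs = 100) {
  if (!is.finite(freq) || freq <= 0 || freq >= fs / 2)
    stop("freq must lie strictly between 0 and fs/2")
  a <- f0 / freq
  dt <- 1 / fs
  u_max <- sqrt(log(1e6))          # envelope < 1e-6 of peak beyond this
  half <- as.integer(ceiling(u_max * a * fs))
  u <- ((-half):half) * dt / a
  psi <- pi^(-1 / 4) * exp(1i * 2 * pi * f0 * u) * exp(-u^2)
  psi <- psi * (2 / (sum(Mod(psi)) * dt))
  structure(list(kernel = psi, freq = freq, f0 = f0, scale = a,
                 fs = fs, half = half),
            class = "morlet_kernel")
}

#' CWT magnitude envelopes of a signal at a set of frequencies
#'
#' Convolves the signal with the complex Morlet kernel at each requested
#' frequency and returns the modulus. Edges are computed with implicit
#' zero padding; the number of edge samples affected at each end equals
#' the kernel half-support and is reported per frequency in the
#' `edge_samples` attribute.
#'
#' @param x numeric signal (a single clean segment).
#' @param freqs frequencies of interest in Hz.
#' @param fs sampling rate in Hz.
#' @param f0 Morlet central frequency parameter.
#' @return numeric matrix `length(freqs) x length(x)` of envelope
#'   magnitudes in signal units, with attributes `freqs`, `fs` and
#'   `edge_samples`.
#' @export
cwt_magnitude <- function(x, freqs, fs = 100, f0 = 2) {
  stopifnot(length(freqs) >= 1, all(is.finite(x)))
  kernels <- lapply(freqs, morlet_kernel, f0 = f0, fs = fs)
  max_half <- max(vapply(kernels, `[[`, integer(1), "half"))
  n <- length(x)
  if (n <= 2L * max_half)
    stop("segment shorter than the wavelet support at the lowest frequency")
  dt <- 1 / fs
  nfft <- stats::nextn(n + 2L * max_half, 2)
  X <- stats::fft(c(as.complex(x), rep(0i, nfft - n)))
  env <- matrix(0, nrow = length(freqs), ncol = n)
  for (j in seq_along(freqs)) {
    k <- kernels[[j]]
    # correlation with the kernel: h[m] = Conj(psi(-m dt / a))
    h <- Conj(rev(k$kernel))
    H <- stats::fft(c(h, rep(0i, nfft - length(h))))
    w <- stats::fft(X * H, inverse = TRUE) / nfft
    env[j, ] <- Mod(w[(k$half + 1L):(k$half + n)]) * dt
  }
  attr(env, "freqs") <- freqs
  attr(env, "fs") <- fs
  attr(env, "edge_samples") <-
    vapply(kernels, `[[`, integer(1), "half")
  env
}

#' Two-threshold event detection on a CWT envelope
#'
#' An event is a maximal run of samples where the envelope strictly
#' exceeds the spindle activity threshold SA; the run is kept only if it
#' lasts at least `min_duration` seconds and the envelope exceeds the
#' spindle peak threshold SP at least once within it. Ties with either
#' threshold break toward non-detection. The event is marked over the
#' whole fragment where the envelope exceeds SA.
#'
#' @param env numeric envelope vector (one frequency/band).
#' @param thr `detection_thresholds` object (see
#'   [detection_thresholds()]) or a list with elements `SA` and `SP`.
#' @param fs sampling rate in Hz.
#' @param min_duration minimum event duration in seconds.
#' @return data.frame with columns `onset`, `offset` (seconds from the
#'   start of `env`, half-open intervals), sorted and disjoint.
#' @export
detect_events <- function(env, thr, fs = 100, min_duration = 0.5) {
  stopifnot(is.numeric(env), thr$SA > 0, thr$SP > thr$SA)
  runs <- run_bounds(env > thr$SA)
  if (!nrow(runs)) return(empty_intervals())
  min_len <- ceiling(min_duration * fs - 1e-9)
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    len <- runs$end[i] - runs$start[i] + 1L
    keep[i] <- len >= min_len &&
      max(env[runs$start[i]:runs$end[i]]) > thr$SP
  }
  runs <- runs[keep, , drop = FALSE]
  data.frame(onset = (runs$start - 1L) / fs, offset = runs$end / fs)
}

# Maximal runs of TRUE in a logical vector: data.frame(start, end),
# 1-based inclusive sample indices.
run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

empty_intervals <- function() {
  data.frame(onset = numeric(0), offset = numeric(0))
}
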