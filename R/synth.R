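# Synthetic polysomnographic EEG with ground-truth spindles, and
# synthetic twin phenotypes with known variance components. Every other
# module is testable against these generators.

#' Specification of a synthetic EEG recording
#'
#' Defaults describe a plausible NREM recording at 250 Hz: a pink-noise
#' floor, delta waves strongest in slow wave sleep, two spindle trains
#' (a slow ~11.5 Hz train weighted toward frontal channels and a fast
#' ~13.5 Hz train weighted toward parietal channels, both with
#' waxing-waning Hann envelopes and 0.5-2 s durations), occasional
#' alpha bursts and broadband EMG bursts.
#'
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param channels named character vector label -> role.
#' @param background list: `pink_amp` (SD of the pink-noise floor, uV)
#'   and `delta_amp` (SD of 0.5-4 Hz delta activity in SWS, uV; scaled
#'   by 0.5 in S2 and 0.25 elsewhere).
#' @param spindle_trains list of trains; each a list with `frequency`
#'   (Hz), `density` (events per 30-s epoch in eligible stages),
#'   `duration` (range in s), `amplitude` (peak uV), `weights` (named
#'   numeric per role), `stages` (eligible stage labels).
#' @param alpha_bursts list: `frequency` (Hz), `amplitude` (peak uV),
#'   `length` (s), `rate` (bursts per minute; 0 disables), `stages`
#'   (stage labels in which alpha may appear; bursts are only placed
#'   in epochs of these stages).
#' @param emg_bursts list: `band` (Hz), `sd` (uV), `length` (s),
#'   `rate` (bursts per minute; 0 disables).
#' @param hypnogram_plan stage label per 30-s epoch; recycled to cover
#'   the duration. Default alternates blocks of S2 and SWS.
#' @param seed integer; fixes the output exactly.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(duration = 600,
                       fs = 250,
                       channels = c(F3A2 = "frontal", P3A2 = "parietal"),
                       background = list(pink_amp = 7, delta_amp = 25),
                       spindle_trains = list(
                         list(frequency = 11.5, density = 3,
                              duration = c(0.7, 1.6), amplitude = 22,
                              weights = c(frontal = 1, central = 0.6,
                                          parietal = 0.2, other = 0.5),
                              stages = c("S2", "SWS")),
                         list(frequency = 13.5, density = 3,
                              duration = c(0.7, 1.6), amplitude = 22,
                              weights = c(frontal = 0.2, central = 0.6,
                                          parietal = 1, other = 0.5),
                              stages = c("S2", "SWS"))),
                       alpha_bursts = list(frequency = 10, amplitude = 20,
                                           length = 3, rate = 0.5,
                                           stages = c("Wake", "S1", "REM")),
                       emg_bursts = list(band = c(20, 45), sd = 15,
                                         length = 2, rate = 0.5),
                       hypnogram_plan = NULL,
                       seed = 1L) {
  stopifnot(duration > 0, fs > 0, length(channels) >= 1,
            !is.null(names(channels)),
            all(channels %in% CHANNEL_ROLES))
  n_epochs <- ceiling(duration / 30)
  if (is.null(hypnogram_plan))
    hypnogram_plan <- rep(c(rep("S2", 5), rep("SWS", 5)),
                          length.out = n_epochs)
  structure(list(duration = duration, fs = fs, channels = channels,
                 background = background,
                 spindle_trains = spindle_trains,
                 alpha_bursts = alpha_bursts, emg_bursts = emg_bursts,
                 hypnogram_plan = rep(hypnogram_plan,
                                      length.out = n_epochs),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Gaussian noise with power spectrum ~ 1/f^slope, unit variance,
# via spectral shaping with random phases.
pink_noise <- function(n, fs, slope = 1, f_floor = 0.5) {
  nfft <- stats::nextn(n, 2)
  f <- c(1e-12, seq_len(nfft - 1)) * fs / nfft
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  amp <- 1 / pmax(f, f_floor)^(slope / 2)
  amp[1] <- 0
  ph <- stats::runif(nfft, 0, 2 * pi)
  X <- amp * exp(1i * ph)
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

# Band-limited Gaussian noise, unit variance.
band_noise <- function(n, fs, band) {
  nfft <- stats::nextn(n, 2)
  f <- (seq_len(nfft) - 1) * fs / nfft
  f <- pmin(f, fs - f)
  keep <- f >= band[1] & f <= band[2]
  X <- complex(modulus = as.numeric(keep),
               argument = stats::runif(nfft, 0, 2 * pi))
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic EEG recording with ground-truth spindles
#'
#' Deterministic given `spec$seed`. Every planted spindle is returned
#' in the ground-truth table with its true channel, onset, duration,
#' peak amplitude on that channel, frequency and stage; a spindle
#' appears on every channel whose role weight is positive, scaled by
#' the weight, so the table holds one row per event per channel.
#'
#' @param spec a [synth_spec()].
#' @return list with `recording` (an [eeg_recording()]),
#'   `ground_truth` (event data.frame with `train` and `weight`
#'   columns in addition to the standard event fields) and `hypnogram`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n <- round(spec$duration * fs)
  hyp <- hypnogram(spec$hypnogram_plan)
  t_sec <- (seq_len(n) - 1) / fs
  stage <- stage_at(hyp, t_sec)
  stage[is.na(stage)] <- spec$hypnogram_plan[length(spec$hypnogram_plan)]
  labels <- names(spec$channels)
  roles <- unname(spec$channels)
  dat <- matrix(0, nrow = length(labels), ncol = n)

  delta_scale <- c(Wake = 0.25, S1 = 0.25, S2 = 0.5, SWS = 1,
                   REM = 0.25, MT = 0.25)[stage]
  for (ch in seq_along(labels)) {
    bg <- spec$background$pink_amp * pink_noise(n, fs)
    dl <- spec$background$delta_amp * delta_scale *
      band_noise(n, fs, c(0.5, 4))
    dat[ch, ] <- bg + dl
  }

  # ---- spindle trains -------------------------------------------------
  # Events are drawn per epoch across all eligible trains and placed
  # jointly with at least `guard` seconds between events (uniform-gap
  # placement), so any feasible configuration is placed and only a
  # genuinely infeasible density errors.
  gt <- list()
  occupied <- rep(FALSE, n)
  guard <- 0.5
  epoch_starts <- (seq_along(hyp$stages) - 1) * hyp$epoch_length
  for (e in seq_along(hyp$stages)) {
    trains <- integer(0)
    durs <- numeric(0)
    for (k in seq_along(spec$spindle_trains)) {
      tr <- spec$spindle_trains[[k]]
      if (!(hyp$stages[e] %in% tr$stages)) next
      n_ev <- stats::rpois(1, tr$density)
      if (!n_ev) next
      trains <- c(trains, rep(k, n_ev))
      durs <- c(durs, stats::runif(n_ev, tr$duration[1], tr$duration[2]))
    }
    n_ev <- length(trains)
    if (!n_ev) next
    if (n_ev > 1L) {
      ord <- sample.int(n_ev)            # interleave the trains
      trains <- trains[ord]; durs <- durs[ord]
    }
    free <- hyp$epoch_length - sum(durs) - guard * (n_ev + 1)
    if (free < 0)
      stop("spindle density too high: trains overlap irresolvably")
    u <- sort(stats::runif(n_ev, 0, free))
    onsets <- epoch_starts[e] + u + guard * seq_len(n_ev) +
      c(0, cumsum(durs))[seq_len(n_ev)]
    for (i in seq_len(n_ev)) {
      tr <- spec$spindle_trains[[trains[i]]]
      s <- round(onsets[i] * fs) + 1L
      eidx <- min(n, s + round(durs[i] * fs) - 1L)
      if (eidx <= s) next                # event beyond recording end
      occupied[s:eidx] <- TRUE
      len <- eidx - s + 1L
      phase <- stats::runif(1, 0, 2 * pi)
      wav <- hann_window(len) *
        sin(2 * pi * tr$frequency * (0:(len - 1)) / fs + phase)
      for (ch in seq_along(labels)) {
        w <- tr$weights[[roles[ch]]]
        if (is.null(w) || is.na(w) || w <= 0) next
        dat[ch, s:eidx] <- dat[ch, s:eidx] + tr$amplitude * w * wav
        gt[[length(gt) + 1L]] <- data.frame(
          onset = (s - 1L) / fs, offset = eidx / fs,
          channel = labels[ch],
          type = if (tr$frequency < 13) "slow" else "fast",
          amplitude = tr$amplitude * w, frequency = tr$frequency,
          stage = hyp$stages[e], train = trains[i], weight = w)
      }
    }
  }

  # ---- alpha and EMG bursts ------------------------------------------
  add_bursts <- function(make_wave, len_s, rate, stages_ok = NULL) {
    n_b <- stats::rpois(1, rate * spec$duration / 60)
    for (i in seq_len(n_b)) {
      for (try in seq_len(40L)) {
        onset <- stats::runif(1, 0, spec$duration - len_s)
        s <- round(onset * fs) + 1L
        eidx <- s + round(len_s * fs) - 1L
        if (eidx > n) next
        if (!is.null(stages_ok) &&
            !all(stage[c(s, eidx)] %in% stages_ok)) next
        if (!any(occupied[s:eidx])) {
          occupied[s:eidx] <<- TRUE
          wav <- make_wave(eidx - s + 1L)
          for (ch in seq_along(labels)) dat[ch, s:eidx] <<-
              dat[ch, s:eidx] + wav
          break
        }
      }
    }
  }
  ab <- spec$alpha_bursts
  if (ab$rate > 0)
    add_bursts(function(len) ab$amplitude * hann_window(len) *
                 sin(2 * pi * ab$frequency * (0:(len - 1)) / fs),
               ab$length, ab$rate,
               stages_ok = if (is.null(ab$stages)) NULL else ab$stages)
  eb <- spec$emg_bursts
  if (eb$rate > 0)
    add_bursts(function(len) eb$sd * hann_window(len) *
                 band_noise(len, fs, eb$band),
               eb$length, eb$rate)

  ground_truth <- if (length(gt)) do.call(rbind, gt) else
    data.frame(onset = numeric(0), offset = numeric(0),
               channel = character(0), type = character(0),
               amplitude = numeric(0), frequency = numeric(0),
               stage = character(0), train = integer(0),
               weight = numeric(0))
  ground_truth <- ground_truth[order(ground_truth$channel,
                                     ground_truth$onset), ]
  rownames(ground_truth) <- NULL
  list(recording = eeg_recording(dat, fs, labels, roles),
       ground_truth = ground_truth,
       hypnogram = hyp)
}

#' Specification of a synthetic twin dataset
#'
#' Additive model: each subject's trait is
#' `mean + g + c + e`, with the genetic component `g` shared entirely
#' within MZ pairs and correlated 0.5 within DZ pairs, the shared
#' environment `c` common to both members of a pair, and `e` unique per
#' subject. Each subject is observed on two nights that differ only by
#' independent night noise.
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param mean trait mean.
#' @param var_genetic,var_shared,var_unique variance components
#'   (trait units squared).
#' @param night_noise_sd SD of per-night measurement noise.
#' @param seed integer seed.
#' @return object of class `twin_sim_spec`.
#' @export
twin_sim_spec <- function(n_mz = 32, n_dz = 14, mean = 4,
                          var_genetic = 0.8, var_shared = 0,
                          var_unique = 0.2, night_noise_sd = 0.1,
                          seed = 1L) {
  stopifnot(n_mz >= 1, n_dz >= 0, var_genetic >= 0, var_shared >= 0,
            var_unique >= 0, night_noise_sd >= 0)
  structure(list(n_mz = n_mz, n_dz = n_dz, mean = mean,
                 var_genetic = var_genetic, var_shared = var_shared,
                 var_unique = var_unique,
                 night_noise_sd = night_noise_sd,
                 seed = as.integer(seed)),
            class = "twin_sim_spec")
}

#' Generate a synthetic twin dataset
#'
#' @param spec a [twin_sim_spec()].
#' @return data.frame with columns `pair_id`, `zygosity` (`"MZ"` /
#'   `"DZ"`), `member` (`"a"` / `"b"`), `night` (1, 2) and `value`.
#' @export
generate_twin_dataset <- function(spec) {
  stopifnot(inherits(spec, "twin_sim_spec"))
  set.seed(spec$seed)
  sg <- sqrt(spec$var_genetic)
  sc <- sqrt(spec$var_shared)
  se <- sqrt(spec$var_unique)
  one_zyg <- function(n_pairs, zyg) {
    if (!n_pairs) return(NULL)
    rows <- vector("list", n_pairs)
    for (p in seq_len(n_pairs)) {
      if (zyg == "MZ") {
        g <- rep(sg * stats::rnorm(1), 2)
      } else {
        shared <- stats::rnorm(1)
        g <- sg * (sqrt(0.5) * shared + sqrt(0.5) * stats::rnorm(2))
      }
      cc <- sc * stats::rnorm(1)
      e <- se * stats::rnorm(2)
      subj <- spec$mean + g + cc + e
      night <- matrix(rep(subj, each = 2) +
                        spec$night_noise_sd * stats::rnorm(4),
                      nrow = 2)
      rows[[p]] <- data.frame(
        pair_id = paste0(zyg, p),
        zygosity = zyg,
        member = rep(c("a", "b"), each = 2),
        night = rep(1:2, 2),
        value = c(night[, 1], night[, 2]))
    }
    do.call(rbind, rows)
  }
  out <- rbind(one_zyg(spec$n_mz, "MZ"), one_zyg(spec$n_dz, "DZ"))
  rownames(out) <- NULL
  out
}
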