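# Run configuration: channel roles, stages, band mode and all algorithm
# constants, with YAML round-trip for the command line.

#' Detection run configuration
#'
#' Bundles every tunable constant of the detector with its default
#' value. Defaults are the published operating point of the method;
#' they are exposed so that any stage can be recalibrated explicitly.
#'
#' @param channels optional character vector restricting analysis to
#'   these channel labels.
#' @param roles named character vector label -> role, overriding roles
#'   read from the file.
#' @param stages sleep stages analysed (epoch selection).
#' @param band_mode `"auto"` (individual adjustment from one frontal +
#'   one parietal channel) or `"fixed"`.
#' @param fixed_bands a [spindle_bands()] used when `band_mode` is
#'   `"fixed"` and as documentation of the fallback.
#' @param working_fs working sampling rate in Hz.
#' @param emg_sd_limit EMG exclusion SD threshold in microvolts.
#' @param emg_band EMG band-pass -3 dB points in Hz.
#' @param emg_pad padding around EMG exceedances in seconds.
#' @param alpha_ratio alpha/delta exclusion factor.
#' @param sa_factor,sp_factor threshold multipliers on BT.
#' @param min_duration minimum spindle duration in seconds.
#' @param f0 Morlet central frequency parameter.
#' @param grid_step frequency grid step in Hz.
#' @param smooth_hz activity-vector smoothing window in Hz.
#' @param min_scan_spindles minimum accepted spindles per channel for
#'   band adjustment.
#' @param min_overlap event consensus overlap in seconds.
#' @param agreement_resolution agreement timeline bin width in seconds.
#' @param min_bt_duration minimum clean duration for BT in seconds.
#' @param bt_scale amplitude calibration constant for BT (see
#'   [basic_threshold()]).
#' @param seed integer seed for any randomized component.
#' @return object of class `spindle_config` (a list).
#' @export
spindle_config <- function(channels = NULL,
                           roles = NULL,
                           stages = c("S2"),
                           band_mode = c("auto", "fixed"),
                           fixed_bands = fixed_spindle_bands(),
                           working_fs = 100,
                           emg_sd_limit = 5.75,
                           emg_band = c(19.8, 45.5),
                           emg_pad = 3,
                           alpha_ratio = 1.1,
                           sa_factor = 55,
                           sp_factor = 80,
                           min_duration = 0.5,
                           f0 = 2,
                           grid_step = 0.1,
                           smooth_hz = 0.7,
                           min_scan_spindles = 30,
                           min_overlap = 0.3,
                           agreement_resolution = 0.1,
                           min_bt_duration = 60,
                           bt_scale = 0.3,
                           seed = 1L) {
  band_mode <- match.arg(band_mode)
  cfg <- list(channels = channels, roles = roles, stages = stages,
              band_mode = band_mode, fixed_bands = fixed_bands,
              working_fs = working_fs, emg_sd_limit = emg_sd_limit,
              emg_band = emg_band, emg_pad = emg_pad,
              alpha_ratio = alpha_ratio, sa_factor = sa_factor,
              sp_factor = sp_factor, min_duration = min_duration,
              f0 = f0, grid_step = grid_step, smooth_hz = smooth_hz,
              min_scan_spindles = min_scan_spindles,
              min_overlap = min_overlap,
              agreement_resolution = agreement_resolution,
              min_bt_duration = min_bt_duration,
              bt_scale = bt_scale,
              seed = as.integer(seed))
  num <- c("working_fs", "emg_sd_limit", "emg_pad", "alpha_ratio",
           "sa_factor", "sp_factor", "min_duration", "f0", "grid_step",
           "smooth_hz", "min_scan_spindles", "min_overlap",
           "agreement_resolution", "min_bt_duration", "bt_scale")
  for (k in num)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stop("config constant '", k, "' must be a single positive number")
  if (cfg$sp_factor <= cfg$sa_factor)
    stop("sp_factor must exceed sa_factor")
  stopifnot(all(cfg$stages %in% STAGE_LEVELS),
            inherits(cfg$fixed_bands, "spindle_bands"))
  structure(cfg, class = "spindle_config")
}

#' Read a run configuration from a YAML file
#'
#' Any field of [spindle_config()] may appear; `fixed_bands` is given
#' as a mapping with `slow`, `fast`, `stop_detect`.
#'
#' @param path YAML file.
#' @return a `spindle_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$fixed_bands))
    raw$fixed_bands <- spindle_bands(
      as.numeric(raw$fixed_bands$slow),
      as.numeric(raw$fixed_bands$fast),
      if (is.null(raw$fixed_bands$stop_detect)) 9
      else raw$fixed_bands$stop_detect,
      source = "user_fixed")
  if (!is.null(raw$roles)) raw$roles <- unlist(raw$roles)
  do.call(spindle_config, raw)
}
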