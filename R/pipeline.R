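# End-to-end orchestration: preprocessing -> thresholds -> band
# adjustment -> scoring, with all intermediates returned for inspection.

#' Run the full spindle detection pipeline
#'
#' Stage order: (1) resample to the working rate; (2) per-channel EMG
#' artifact and alpha exclusion masks; (3) per-channel clean-segment
#' extraction for the analysed stages; (4) per-channel background
#' threshold BT and the derived SA/SP thresholds; (5) spindle band
#' selection -- individually adjusted from one frontal and one parietal
#' channel when `band_mode = "auto"`, otherwise the configured fixed
#' bands; (6) scoring of all/slow/fast spindles per channel with
#' amplitude and frequency measurement; (7) per-channel summaries.
#'
#' @param rec an [eeg_recording()].
#' @param hyp a [hypnogram()].
#' @param config a [spindle_config()].
#' @return object of class `spindle_run`: list with `events`,
#'   `summaries`, `bands`, `thresholds` (per channel), `masks` (per
#'   channel), `scan` (the activity scan when bands were adjusted),
#'   `clean_seconds` (per channel), `config`.
#' @export
run_detection <- function(rec, hyp, config = spindle_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (missing(hyp) || !inherits(hyp, "hypnogram"))
    stop("a hypnogram is required")
  if (!is.null(config$roles)) {
    hit <- match(rec$channel_labels, names(config$roles))
    rec$channel_role[!is.na(hit)] <- unname(config$roles[hit[!is.na(hit)]])
  }
  if (!is.null(config$channels)) {
    sel <- match(config$channels, rec$channel_labels)
    if (anyNA(sel)) stop("channel(s) not in recording: ",
                         paste(config$channels[is.na(sel)], collapse = ", "))
    rec$data <- rec$data[sel, , drop = FALSE]
    rec$channel_labels <- rec$channel_labels[sel]
    rec$channel_role <- rec$channel_role[sel]
  }
  fs <- config$working_fs
  rec <- resample_100hz(rec, fs)
  nch <- nrow(rec$data)
  labels <- rec$channel_labels

  masks <- vector("list", nch)
  cleans <- vector("list", nch)
  thresholds <- vector("list", nch)
  names(masks) <- names(cleans) <- names(thresholds) <- labels
  for (ch in seq_len(nch)) {
    x <- rec$data[ch, ]
    masks[[ch]] <- combine_masks(
      emg_artifact_mask(x, fs, config$emg_sd_limit, config$emg_band,
                        pad = config$emg_pad),
      alpha_exclusion_mask(x, fs, config$alpha_ratio))
    cleans[[ch]] <- extract_stage_signal(x, fs, hyp, config$stages,
                                         masks[[ch]])
    thresholds[[ch]] <- detection_thresholds(
      basic_threshold(cleans[[ch]],
                      min_duration = config$min_bt_duration,
                      scale = config$bt_scale),
      config$sa_factor, config$sp_factor)
  }

  scan <- NULL
  if (config$band_mode == "auto") {
    i_f <- which(rec$channel_role == "frontal")[1]
    i_p <- which(rec$channel_role == "parietal")[1]
    if (is.na(i_f) || is.na(i_p))
      stop("band_mode 'auto' needs one frontal and one parietal ",
           "channel; use band_mode 'fixed' for this montage")
    scan <- activity_scan(
      cleans[[i_f]], cleans[[i_p]], thresholds[[i_f]],
      thresholds[[i_p]],
      spindle_frequency_grid(step = config$grid_step),
      fs, config$f0, config$min_duration)
    scan <- relation_vector(scan, smooth_hz = config$smooth_hz)
    bands <- estimate_bands(scan, config$min_scan_spindles)
  } else {
    bands <- config$fixed_bands
  }

  all_events <- list()
  summaries <- vector("list", nch)
  names(summaries) <- labels
  for (ch in seq_len(nch)) {
    ev_ch <- list()
    cl <- cleans[[ch]]
    for (k in seq_along(cl$segments)) {
      seg <- cl$segments[[k]]
      half_max <- morlet_kernel(bands$stop_detect, config$f0, fs)$half
      if (length(seg) <= 2L * half_max) next
      env <- band_envelopes(seg, bands, fs, config$f0, config$grid_step)
      for (ty in c("all", "slow", "fast")) {
        ev <- switch(ty,
          all  = score_all(env, thresholds[[ch]], config$min_duration),
          slow = score_slow(env, thresholds[[ch]], config$min_duration),
          fast = score_fast(env, thresholds[[ch]], config$min_duration))
        if (!nrow(ev)) next
        meas <- lapply(seq_len(nrow(ev)), function(i)
          measure_event(seg, ev$onset[i], ev$offset[i], fs))
        ev$channel <- labels[ch]
        ev$type <- ty
        ev$amplitude <- vapply(meas, `[[`, numeric(1), "amplitude")
        ev$frequency <- vapply(meas, `[[`, numeric(1), "frequency")
        ev$onset <- ev$onset + cl$onsets[k]     # back to recording time
        ev$offset <- ev$offset + cl$onsets[k]
        ev$stage <- stage_at(hyp, ev$onset)
        ev_ch[[length(ev_ch) + 1L]] <- ev
      }
    }
    ev_ch <- if (length(ev_ch)) do.call(rbind, ev_ch) else
      data.frame(onset = numeric(0), offset = numeric(0),
                 channel = character(0), type = character(0),
                 amplitude = numeric(0), frequency = numeric(0),
                 stage = character(0))
    ev_ch <- ev_ch[order(ev_ch$type, ev_ch$onset), ]
    rownames(ev_ch) <- NULL
    all_events[[ch]] <- ev_ch
    summaries[[ch]] <- summarize_spindles(ev_ch, hyp, config$stages)
  }
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  structure(list(events = events, summaries = summaries, bands = bands,
                 thresholds = thresholds, masks = masks, scan = scan,
                 clean_seconds = vapply(cleans, function(cl)
                   sum(lengths(cl$segments)) / fs, numeric(1)),
                 config = config),
            class = "spindle_run")
}

#' @export
print.spindle_run <- function(x, ...) {
  cat(sprintf("<spindle_run> %d events on %d channel(s); bands [%s]\n",
              nrow(x$events), length(x$summaries), x$bands$source))
  print(x$bands)
  for (ch in names(x$thresholds)) {
    thr <- x$thresholds[[ch]]
    cat(sprintf("  %s: BT=%.4g SA=%.4g SP=%.4g, clean %.0f s\n",
                ch, thr$BT, thr$SA, thr$SP, x$clean_seconds[[ch]]))
  }
  invisible(x)
}
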