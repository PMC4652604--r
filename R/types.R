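# Shared domain containers: recordings, hypnograms, events, masks.

STAGE_LEVELS <- c("Wake", "S1", "S2", "SWS", "REM", "MT")
CHANNEL_ROLES <- c("frontal", "central", "parietal", "other")
SPINDLE_TYPES <- c("slow", "fast", "all")

#' Multi-channel EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of 10-20 style labels
#'   (e.g. "F3A2"), one per row of `data`.
#' @param channel_role per-channel role, one of
#'   `"frontal"`, `"central"`, `"parietal"`, `"other"`.
#' @param start_time recording start offset in seconds (0 if unknown).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          channel_role = rep("other", nrow(data)),
                          start_time = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (length(channel_labels) != nrow(data))
    stop("one label per channel required")
  channel_role <- match.arg(channel_role, CHANNEL_ROLES,
                            several.ok = TRUE)
  if (length(channel_role) == 1L)
    channel_role <- rep(channel_role, nrow(data))
  if (length(channel_role) != nrow(data))
    stop("one role per channel required")
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 channel_role = channel_role,
                 start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s), %.1f s at %g Hz\n",
              nrow(x$data), ncol(x$data) / x$fs, x$fs))
  cat("  ", paste(x$channel_labels, sprintf("(%s)", x$channel_role),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Hypnogram of 30-s sleep stages
#'
#' @param stages character vector of stage labels, one per epoch, each
#'   one of `"Wake"`, `"S1"`, `"S2"`, `"SWS"`, `"REM"`, `"MT"`.
#' @param epoch_length epoch length in seconds.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length = 30) {
  stopifnot(epoch_length > 0, length(stages) >= 1)
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(list(stages = as.character(stages),
                 epoch_length = epoch_length),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs of %g s\n",
              length(x$stages), x$epoch_length))
  print(table(factor(x$stages, levels = STAGE_LEVELS)))
  invisible(x)
}

#' Stage label of the epoch containing each time point
#'
#' Times beyond the hypnogram get NA.
#' @param hyp a `hypnogram`.
#' @param times numeric vector of seconds from recording start.
#' @export
stage_at <- function(hyp, times) {
  idx <- floor(times / hyp$epoch_length) + 1L
  out <- rep(NA_character_, length(times))
  ok <- idx >= 1L & idx <= length(hyp$stages)
  out[ok] <- hyp$stages[idx[ok]]
  out
}

#' Per-sample exclusion mask
#'
#' @param flags logical vector, TRUE where the sample is excluded.
#' @param fs sampling rate in Hz.
#' @param reason per-sample reason, one of `"none"`, `"emg"`, `"alpha"`;
#'   recycled from `"none"` where `flags` is FALSE.
#' @return object of class `exclusion_mask`.
#' @export
exclusion_mask <- function(flags, fs, reason = NULL) {
  stopifnot(is.logical(flags), fs > 0)
  if (is.null(reason)) reason <- rep("none", length(flags))
  stopifnot(length(reason) == length(flags))
  structure(list(flags = flags, fs = fs, reason = reason),
            class = "exclusion_mask")
}

#' Combine exclusion masks (union of excluded samples)
#' @param ... `exclusion_mask` objects of equal length and rate.
#' @export
combine_masks <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1)
  n <- length(ms[[1]]$flags)
  fs <- ms[[1]]$fs
  flags <- rep(FALSE, n)
  reason <- rep("none", n)
  for (m in ms) {
    stopifnot(length(m$flags) == n, m$fs == fs)
    new <- m$flags & !flags
    reason[new] <- m$reason[new]
    flags <- flags | m$flags
  }
  exclusion_mask(flags, fs, reason)
}

#' Total masked duration in seconds
#' @param mask an `exclusion_mask`.
#' @export
masked_seconds <- function(mask) sum(mask$flags) / mask$fs

#' Validate a table of spindle events
#'
#' Checks the event invariants: duration at least `min_duration`
#' seconds, onset non-negative, frequency (when present and finite)
#' within 9-16 Hz, and known type/stage labels.
#'
#' @param events data.frame with at least `onset`, `offset`, `channel`,
#'   `type`; optional `amplitude`, `frequency`, `stage`.
#' @param min_duration minimum event duration in seconds.
#' @return the events, invisibly, if valid; otherwise an error.
#' @export
validate_events <- function(events, min_duration = 0.5) {
  stopifnot(is.data.frame(events))
  req <- c("onset", "offset", "channel", "type")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("events missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(events)) return(invisible(events))
  if (any(events$onset < 0)) stop("event onset before recording start")
  dur <- events$offset - events$onset
  if (any(dur < min_duration - 1e-9))
    stop("event shorter than the minimum duration of ",
         min_duration, " s")
  if (!all(events$type %in% SPINDLE_TYPES))
    stop("unknown spindle type")
  if (!is.null(events$frequency)) {
    f <- events$frequency[is.finite(events$frequency)]
    if (length(f) && (any(f < 9 - 1e-9) || any(f > 16 + 1e-9)))
      stop("event frequency outside the 9-16 Hz spindle range")
  }
  if (!is.null(events$stage)) {
    s <- events$stage[!is.na(events$stage)]
    if (!all(s %in% STAGE_LEVELS)) stop("unknown stage label in events")
  }
  invisible(events)
}
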