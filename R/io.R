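# Readers and writers: EDF/EDF+ and delimited recordings, plain-text
# hypnograms, CSV event lists.

#' Read a polysomnographic recording
#'
#' Reads either an EDF/EDF+ file (binary, 16-bit; extension `.edf` or
#' `.rec`) or a delimited numeric file (CSV/TSV with one column per
#' channel and a header row of channel labels). All requested channels
#' must share one sampling rate. Values are assumed to be in microvolts
#' (EDF physical dimensions are not converted).
#'
#' @param path file to read.
#' @param role_map named character vector mapping channel labels to
#'   roles (`"frontal"`, `"central"`, `"parietal"`, `"other"`); labels
#'   absent from the map default to `"other"`.
#' @param channels optional character vector restricting which channels
#'   to load.
#' @param fs sampling rate in Hz, required for delimited files (EDF
#'   files carry their own).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, role_map = NULL, channels = NULL,
                           fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size == 0) stop("empty recording file: ", path)
  ext <- tolower(tools::file_ext(path))
  rec <- if (ext %in% c("edf", "rec")) read_edf(path, channels)
         else read_delimited_recording(path, channels, fs)
  if (!is.null(role_map)) {
    stopifnot(!is.null(names(role_map)),
              all(role_map %in% CHANNEL_ROLES))
    hit <- match(rec$channel_labels, names(role_map))
    rec$channel_role[!is.na(hit)] <-
      unname(role_map[hit[!is.na(hit)]])
  }
  rec
}

# Minimal EDF/EDF+ (continuous) reader: 256-byte header, per-signal
# header blocks, little-endian 16-bit data records scaled to physical
# units. Annotation signals are skipped.
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_txt(8)
  if (!identical(version, "0"))
    stop("not an EDF file (bad version field): ", path)
  invisible(hdr_txt(80)); invisible(hdr_txt(80))       # patient, recording
  invisible(hdr_txt(8)); invisible(hdr_txt(8))         # date, time
  invisible(hdr_txt(8)); invisible(hdr_txt(44))        # header bytes, reserved
  n_rec <- as.integer(hdr_txt(8))
  rec_dur <- as.numeric(hdr_txt(8))
  ns <- as.integer(hdr_txt(4))
  if (is.na(ns) || ns < 1) stop("EDF header reports no signals")
  field <- function(n) vapply(seq_len(ns), function(i) hdr_txt(n), "")
  labels <- field(16)
  invisible(field(80)); invisible(field(8))            # transducer, dim
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  invisible(field(80))                                 # prefiltering
  spr <- as.integer(field(8))                          # samples per record
  invisible(field(32))
  is_annot <- grepl("EDF Annotations", labels, fixed = TRUE)
  sel <- which(!is_annot)
  if (!is.null(channels)) {
    sel <- match(channels, labels)
    if (anyNA(sel)) stop("channel(s) not in file: ",
                         paste(channels[is.na(sel)], collapse = ", "))
  }
  if (!length(sel)) stop("no data signals in EDF file")
  if (length(unique(spr[sel])) != 1L)
    stop("mixed sampling rates across requested channels are unsupported")
  fs <- spr[sel[1]] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * sum(spr))
    stop("truncated EDF data section: ", path)
  offs <- c(0L, cumsum(spr))
  dat <- matrix(0, nrow = length(sel), ncol = n_rec * spr[sel[1]])
  for (k in seq_along(sel)) {
    s <- sel[k]
    idx <- as.vector(outer(offs[s] + seq_len(spr[s]),
                           (seq_len(n_rec) - 1L) * sum(spr), `+`))
    g <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
    dat[k, ] <- (raw[idx] - dmin[s]) * g + pmin[s]
  }
  eeg_recording(dat, fs, labels[sel])
}

read_delimited_recording <- function(path, channels = NULL, fs = NULL) {
  if (is.null(fs))
    stop("fs must be given when reading a delimited recording")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (!ncol(tab) || !nrow(tab)) stop("no data in file: ", path)
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("non-numeric column in recording file: ", path)
  if (!is.null(channels)) {
    miss <- setdiff(channels, names(tab))
    if (length(miss)) stop("channel(s) not in file: ",
                           paste(miss, collapse = ", "))
    tab <- tab[, channels, drop = FALSE]
  }
  eeg_recording(t(as.matrix(tab)), fs, names(tab))
}

#' Default Rechtschaffen & Kales stage-code mapping
#'
#' Numeric codes 0-5 plus common letter codes; stages 3 and 4 both map
#' to SWS, which is analysed as a single class.
#' @return named character vector code -> stage label.
#' @export
default_stage_map <- function() {
  c("0" = "Wake", "1" = "S1", "2" = "S2", "3" = "SWS", "4" = "SWS",
    "5" = "REM", "W" = "Wake", "R" = "REM", "M" = "MT", "MT" = "MT",
    Wake = "Wake", S1 = "S1", S2 = "S2", SWS = "SWS", REM = "REM")
}

#' Read a plain-text hypnogram
#'
#' One stage code per line (a trailing comma-separated single line is
#' also accepted). Codes are translated through `stage_map`.
#'
#' @param path text file.
#' @param stage_map named vector code -> stage label; defaults to
#'   [default_stage_map()].
#' @param epoch_length epoch length in seconds.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, stage_map = default_stage_map(),
                           epoch_length = 30) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 1L && grepl(",", lines))
    lines <- trimws(strsplit(lines, ",")[[1]])
  if (!length(lines)) stop("empty hypnogram file: ", path)
  hit <- match(lines, names(stage_map))
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1]
    stop(sprintf("unknown stage code '%s' at line %d of %s",
                 lines[bad], bad, path))
  }
  hypnogram(unname(stage_map[hit]), epoch_length)
}

#' Write / read spindle events as CSV
#'
#' The on-disk format is a CSV with header
#' `onset,duration,channel,type,amplitude,frequency,stage` (duration in
#' seconds rather than offset, as annotation tools expect). Reading
#' back reproduces the event table up to 1e-6 s.
#'
#' @param events data.frame of events as produced by the detector.
#' @param path file to write / read.
#' @param validate check event invariants before writing.
#' @return `write_events`: the path, invisibly. `read_events`: the
#'   event data.frame with columns `onset`, `offset`, `channel`,
#'   `type`, `amplitude`, `frequency`, `stage`.
#' @export
write_events <- function(events, path, validate = TRUE) {
  if (validate) validate_events(events)
  out <- data.frame(
    onset = events$onset,
    duration = events$offset - events$onset,
    channel = events$channel,
    type = events$type,
    amplitude = if (is.null(events$amplitude)) NA_real_ else events$amplitude,
    frequency = if (is.null(events$frequency)) NA_real_ else events$frequency,
    stage = if (is.null(events$stage)) NA_character_ else events$stage)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("onset", "duration", "channel", "type")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("event file missing column(s): ", paste(miss, collapse = ", "))
  data.frame(
    onset = tab$onset,
    offset = tab$onset + tab$duration,
    channel = as.character(tab$channel),
    type = as.character(tab$type),
    amplitude = if (is.null(tab$amplitude)) NA_real_ else tab$amplitude,
    frequency = if (is.null(tab$frequency)) NA_real_ else tab$frequency,
    stage = if (is.null(tab$stage)) NA_character_
            else as.character(tab$stage))
}
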