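# Minimal EDF writer used only to build test fixtures at run time.
# (The package itself does not write EDF.)
write_test_edf <- function(path, data, fs, labels,
                           phys_range = c(-500, 500)) {
  stopifnot(is.matrix(data), length(labels) == nrow(data))
  ns <- nrow(data)
  rec_dur <- 1
  spr <- as.integer(fs * rec_dur)
  n_rec <- floor(ncol(data) / spr)
  data <- data[, seq_len(n_rec * spr), drop = FALSE]
  dmin <- -32768L; dmax <- 32767L
  pmin <- phys_range[1]; pmax <- phys_range[2]
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    s <- formatC(as.character(x), width = -n)
    writeChar(substr(s, 1, n), con, nchars = n, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 * (1 + ns), 8); pad("", 44)
  pad(n_rec, 8); pad(rec_dur, 8); pad(ns, 4)
  for (l in labels) pad(l, 16)
  for (i in 1:ns) pad("AgAgCl", 80)
  for (i in 1:ns) pad("uV", 8)
  for (i in 1:ns) pad(pmin, 8)
  for (i in 1:ns) pad(pmax, 8)
  for (i in 1:ns) pad(dmin, 8)
  for (i in 1:ns) pad(dmax, 8)
  for (i in 1:ns) pad("", 80)
  for (i in 1:ns) pad(spr, 8)
  for (i in 1:ns) pad("", 32)
  g <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- data[s, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((seg - pmin) * g + dmin))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
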