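# Minimal reader/writer for continuous European Data Format (EDF) files:
# fixed-width ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian 16-bit integers, scaled channel-wise by the
# physical/digital calibration ranges. Covers plain continuous EDF with a
# common sampling rate across channels — the layout EEG amplifiers export —
# not EDF+ annotations or variable-rate signals.

edf_field <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a continuous EDF recording
#'
#' @param path Path to an EDF file. All signals must share one sampling
#'   rate; EDF+ annotation channels are not supported.
#' @return An [eeg_recording()] with channel labels from the EDF header.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  invisible(readBin(con, "raw", 80 + 80 + 8 + 8))   # patient, recording, date, time
  n_header <- as.integer(edf_field(con, 8))
  reserved <- edf_field(con, 44)
  if (grepl("EDF\\+D", reserved)) stop("discontinuous EDF+ is not supported")
  n_records <- as.integer(edf_field(con, 8))
  record_s <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16), character(1))
  invisible(readBin(con, "raw", ns * (80 + 8)))     # transducer, dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), numeric(1))
  invisible(readBin(con, "raw", ns * 80))           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(edf_field(con, 8)), integer(1))
  invisible(readBin(con, "raw", ns * 32))           # reserved
  if (length(unique(spr)) != 1)
    stop("signals with differing sampling rates are not supported")
  if (record_s <= 0) stop("invalid record duration")
  fs <- spr[1] / record_s
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  X <- matrix(0, ns, n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      X[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (d - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  eeg_recording(X, fs, labels)
}

pad_field <- function(x, n) {
  s <- formatC(as.character(x), width = -n)
  if (nchar(s) > n) stop("EDF header field too long: ", x)
  s
}

# shortest numeric rendering that fits an 8-byte header field
num_field <- function(v) {
  for (d in 6:1) {
    s <- formatC(v, format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot render ", v, " in 8 bytes")
}

#' Write a recording as a continuous EDF file
#'
#' One-second data records, 16-bit encoding with channel-wise physical
#' calibration spanning the observed amplitude range.
#'
#' @param rec An [eeg_recording()] whose sampling rate is an integer and
#'   whose length is a whole number of seconds.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  spr <- as.integer(round(rec$fs))
  if (abs(spr - rec$fs) > 1e-9) stop("EDF export requires an integer sampling rate")
  n_records <- ncol(rec$samples) / spr
  if (abs(n_records - round(n_records)) > 1e-9)
    stop("EDF export requires a whole number of 1-s records")
  n_records <- as.integer(round(n_records))
  phys_max <- pmax(apply(rec$samples, 1, function(x) max(abs(x))), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(pad_field(x, n)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_records, 8); wr("1", 8); wr(ns, 4)
  for (s in seq_len(ns)) wr(rec$labels[s], 16)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr("uV", 8)
  for (s in seq_len(ns)) wr(num_field(-phys_max[s]), 8)
  for (s in seq_len(ns)) wr(num_field(phys_max[s]), 8)
  for (s in seq_len(ns)) wr(-32768, 8)
  for (s in seq_len(ns)) wr(32767, 8)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr(spr, 8)
  for (s in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- rec$samples[s, ((r - 1) * spr + 1):(r * spr)]
      d <- as.integer(round((seg + phys_max[s]) / (2 * phys_max[s]) * 65535 - 32768))
      writeBin(pmin(pmax(d, -32768L), 32767L), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
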