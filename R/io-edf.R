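# Minimal EDF+C writer/reader for synthetic EEG recordings. EDF stores
# 16-bit samples in 1 s data records plus an annotations channel carrying
# time-stamped text lists (TALs) used here for condition-onset triggers.
# No EDF package ships with this R installation, and only the subset of the
# format needed for round-tripping recordings is implemented: one fixed-rate
# signal group, one annotations channel, contiguous (EDF+C) records.

edf_pad <- function(x, n) {
  x <- substr(x, 1, n)
  paste0(x, strrep(" ", n - nchar(x)))
}

edf_num <- function(x, n) edf_pad(format(x, scientific = FALSE, trim = TRUE), n)

#' Write an EEG recording to an EDF+ file
#'
#' Signals are scaled per channel to the 16-bit digital range; trigger
#' events are stored in an "EDF Annotations" channel as `code:condition`
#' text annotations at their exact onset times. The final data record is
#' zero-padded to a whole second. Header date/time fields are fixed so that
#' output is byte-identical for identical input.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop2("EDF writer requires an integer sampling rate")
  nch <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- ceiling(n / fs)
  ann_spr <- 120L  # annotation samples (2 bytes each) per record

  phys_max <- apply(abs(rec$data), 1, max)
  phys_max[phys_max == 0] <- 1
  phys_max <- signif(phys_max * 1.0000001, 7)

  con <- file(path, "wb")
  on.exit(close(con))
  ns <- nch + 1L
  header_bytes <- 256L * (1L + ns)
  # fixed-format global header
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80),
    edf_pad("Startdate 01-JAN-2000 X X X", 80),
    "01.01.00", "00.00.00",
    edf_num(header_bytes, 8), edf_pad("EDF+C", 44),
    edf_num(n_rec, 8), edf_num(1, 8), edf_num(ns, 4)),
    con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, "", n = width), collapse = ""),
              con, eos = NULL)
  }
  labels <- c(rec$labels, "EDF Annotations")
  field(labels, 16)
  field(rep("", ns), 80)                                  # transducer
  field(c(rep("uV", nch), ""), 8)                         # physical dimension
  field(c(sprintf("%.7g", -phys_max), "-1"), 8)           # phys min
  field(c(sprintf("%.7g", phys_max), "1"), 8)             # phys max
  field(c(rep("-32767", nch), "-32768"), 8)               # dig min
  field(rep("32767", ns), 8)                              # dig max
  field(rep("", ns), 80)                                  # prefiltering
  field(c(rep(fs, nch), ann_spr), 8)                      # samples per record
  field(rep("", ns), 32)

  dig <- matrix(0L, nch, n_rec * fs)
  dig[, seq_len(n)] <- round(sweep(rec$data, 1, 32767 / phys_max, "*"))
  storage.mode(dig) <- "integer"

  ev <- rec$events
  ev_rec <- if (nrow(ev)) ((ev$sample - 1L) %/% fs) + 1L else integer(0)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.vector(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
    raw_tal <- c(charToRaw(sprintf("+%d\x14\x14", r - 1L)), as.raw(0))
    for (i in which(ev_rec == r)) {
      onset <- (ev$sample[i] - 1L) / fs
      raw_tal <- c(raw_tal,
                   charToRaw(sprintf("+%.4f\x14%d:%s\x14", onset,
                                     ev$code[i], ev$condition[i])),
                   as.raw(0))
    }
    if (length(raw_tal) > 2L * ann_spr)
      stop2("too many triggers in one EDF record")
    writeBin(c(raw_tal, raw(2L * ann_spr - length(raw_tal))), con)
  }
  invisible(path)
}

#' Read an EDF(+) file into an `eeg_recording`
#'
#' @param path EDF file path.
#' @return An `eeg_recording` (data in physical units; trigger events parsed
#'   from the annotations channel when present).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8))
  if (version != "0") stop2("not an EDF file: %s", path)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop2("corrupt EDF header in %s", path)
  sig_field <- function(width, type = trimws)
    vapply(seq_len(ns), function(i) type(rd(width)), "")
  labels <- sig_field(16)
  rd(80 * ns)
  rd(8 * ns)
  phys_min <- as.numeric(sig_field(8))
  phys_max <- as.numeric(sig_field(8))
  dig_min <- as.numeric(sig_field(8))
  dig_max <- as.numeric(sig_field(8))
  rd(80 * ns)
  spr <- as.integer(sig_field(8))
  rd(32 * ns)

  is_ann <- labels == "EDF Annotations"
  data_ch <- which(!is_ann)
  fs <- spr[data_ch[1]] / rec_dur
  if (length(unique(spr[data_ch])) != 1)
    stop2("mixed sampling rates not supported")

  nvals <- sum(spr)
  data <- matrix(0, length(data_ch), n_rec * spr[data_ch[1]])
  ann_bytes <- raw(0)
  offsets <- c(0L, cumsum(spr))
  for (r in seq_len(n_rec)) {
    vals <- readBin(con, integer(), n = nvals, size = 2, endian = "little")
    if (length(vals) < nvals) stop2("truncated EDF data record %d", r)
    for (j in seq_along(data_ch)) {
      ch <- data_ch[j]
      seg <- vals[(offsets[ch] + 1L):offsets[ch + 1L]]
      sc <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[j, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        (seg - dig_min[ch]) * sc + phys_min[ch]
    }
    for (ch in which(is_ann)) {
      seg <- vals[(offsets[ch] + 1L):offsets[ch + 1L]]
      b <- writeBin(seg, raw(), size = 2, endian = "little")
      ann_bytes <- c(ann_bytes, b)
    }
  }
  events <- parse_edf_annotations(ann_bytes, fs)
  structure(list(labels = labels[data_ch], fs = fs, data = data,
                 events = events),
            class = "eeg_recording")
}

parse_edf_annotations <- function(bytes, fs) {
  out <- data.frame(sample = integer(0), code = integer(0),
                    condition = character(0), stringsAsFactors = FALSE)
  if (!length(bytes)) return(out)
  # TALs are NUL-terminated; split the raw stream on NUL bytes
  groups <- split(bytes, cumsum(bytes == as.raw(0)))
  tals <- vapply(groups, function(b) rawToChar(b[b != as.raw(0)]), "",
                 USE.NAMES = FALSE)
  tals <- tals[nzchar(tals)]
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[1])) next
    ann <- parts[-1]
    ann <- ann[nzchar(ann)]
    if (!length(ann)) next                         # keep-alive timestamp TAL
    onset <- as.numeric(sub("\x15.*", "", parts[1]))
    for (a in ann) {
      kv <- strsplit(a, ":", fixed = TRUE)[[1]]
      out <- rbind(out, data.frame(
        sample = as.integer(round(onset * fs)) + 1L,
        code = suppressWarnings(as.integer(kv[1])),
        condition = if (length(kv) > 1) kv[2] else NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  out[order(out$sample), , drop = FALSE]
}
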