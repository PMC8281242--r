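# BrainVision (.vhdr/.vmrk/.eeg) reader and writer. The header and marker
# files are INI-style text; the data file holds multiplexed binary samples
# (IEEE float32 or int16 with per-channel resolution). Trigger events map to
# "Stimulus" markers with descriptions "S  <code>".

#' Write an EEG recording as a BrainVision triplet
#'
#' @param rec an `eeg_recording`.
#' @param basepath path without extension; `.vhdr`, `.vmrk` and `.eeg` files
#'   are written next to each other.
#' @param binary_format "IEEE_FLOAT_32" or "INT_16".
#' @return Invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(rec, basepath,
                              binary_format = c("IEEE_FLOAT_32", "INT_16")) {
  stopifnot(inherits(rec, "eeg_recording"))
  binary_format <- match.arg(binary_format)
  base <- basename(basepath)
  nch <- nrow(rec$data)
  res <- rep(1, nch)
  if (binary_format == "INT_16") {
    res <- apply(abs(rec$data), 1, max) / 32000
    res[res == 0] <- 1
  }

  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "", "[Common Infos]",
           sprintf("DataFile=%s.eeg", base),
           sprintf("MarkerFile=%s.vmrk", base),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           sprintf("NumberOfChannels=%d", nch),
           sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
           "", "[Binary Infos]",
           sprintf("BinaryFormat=%s", binary_format),
           "", "[Channel Infos]",
           sprintf("Ch%d=%s,,%.10g,µV", seq_len(nch), rec$labels, res))
  writeLines(hdr, paste0(basepath, ".vhdr"))

  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]",
          sprintf("DataFile=%s.eeg", base),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (nrow(rec$events))
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L,
                        rec$events$code, rec$events$sample))
  writeLines(mk, paste0(basepath, ".vmrk"))

  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  } else {
    d <- round(sweep(rec$data, 1, res, "/"))
    writeBin(as.integer(d), con, size = 2, endian = "little")
  }
  invisible(paste0(basepath, ".vhdr"))
}

#' Read a BrainVision recording
#'
#' @param path path to the `.vhdr` header file; the data and marker files it
#'   names must sit in the same directory.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stop2("header file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  get_val <- function(key) {
    m <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(m)) return(NA_character_)
    sub(paste0("^", key, "="), "", m[1])
  }
  dir <- dirname(path)
  data_file <- file.path(dir, get_val("DataFile"))
  marker_file <- file.path(dir, get_val("MarkerFile"))
  if (!file.exists(data_file))
    stop2("BrainVision data file missing: %s", data_file)
  nch <- as.integer(get_val("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_val("SamplingInterval"))
  fmt <- get_val("BinaryFormat")
  if (!identical(get_val("DataOrientation"), "MULTIPLEXED"))
    stop2("only MULTIPLEXED BrainVision data is supported")

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_parts, `[`, "", 1)
  res <- vapply(ch_parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)

  sz <- file.info(data_file)$size
  con <- file(data_file, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    n <- sz / 4
    vals <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    n <- sz / 2
    vals <- readBin(con, integer(), n = n, size = 2, endian = "little")
  } else stop2("unsupported BinaryFormat: %s", fmt)
  if (n %% nch != 0) stop2("truncated BrainVision data file: %s", data_file)
  data <- matrix(vals, nrow = nch)
  data <- data * res  # column-recycled per-channel resolution

  events <- data.frame(sample = integer(0), code = integer(0),
                       condition = character(0), stringsAsFactors = FALSE)
  if (file.exists(marker_file)) {
    mk <- grep("^Mk[0-9]+=", readLines(marker_file, warn = FALSE), value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
    stim <- vapply(parts, function(p) identical(p[1], "Stimulus"), logical(1))
    if (any(stim)) {
      code <- as.integer(sub("^S\\s*", "", vapply(parts[stim], `[`, "", 2)))
      sample <- as.integer(vapply(parts[stim], `[`, "", 3))
      cond_map <- names(trigger_codes())[match(code, trigger_codes())]
      events <- data.frame(sample = sample, code = code,
                           condition = cond_map, stringsAsFactors = FALSE)
    }
  }
  structure(list(labels = labels, fs = fs, data = data, events = events),
            class = "eeg_recording")
}

#' Read an EEG recording, dispatching on file extension
#'
#' @param path `.edf` file or BrainVision `.vhdr` header.
#' @return An `eeg_recording`.
#' @export
read_eeg <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         edf = read_edf(path),
         vhdr = read_brainvision(path),
         stop2("unsupported EEG format: .%s", ext))
}
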