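# Minimal readers/writers for the two raw-EEG interchange formats the
# pipeline accepts (BrainVision triplets and EDF). Only the features the
# pipeline needs are covered: multiplexed binary data, one sampling rate for
# all channels, stimulus markers.

parse_ini_sections <- function(lines) {
  sections <- list(); current <- NULL
  for (l in lines) {
    l <- sub(";.*$", "", l)
    l <- trimws(l)
    if (l == "") next
    if (grepl("^\\[.*\\]$", l)) {
      current <- gsub("^\\[|\\]$", "", l)
      sections[[current]] <- character(0)
    } else if (!is.null(current) && grepl("=", l, fixed = TRUE)) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
      sections[[current]][trimws(kv[1L])] <- trimws(paste(kv[-1L], collapse = "="))
    }
  }
  sections
}

#' Read a BrainVision recording (.vhdr/.vmrk/.eeg triplet)
#'
#' Parses the text header and marker files and the multiplexed binary data
#' file (IEEE_FLOAT_32 or INT_16 with per-channel resolution). All three
#' files must be present.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return list with `data` (`channel x sample` matrix, microvolts), `fs`,
#'   `channels`, `markers` (tibble: `type`, `description`, `position` in
#'   samples, 1-based).
#' @export
read_brainvision <- function(vhdr) {
  if (!file.exists(vhdr)) stop(sprintf("no such file: %s", vhdr), call. = FALSE)
  hdr <- parse_ini_sections(readLines(vhdr, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  dir <- dirname(vhdr)
  datafile <- file.path(dir, ci[["DataFile"]])
  markerfile <- file.path(dir, ci[["MarkerFile"]])
  if (!file.exists(markerfile)) {
    stop(sprintf("BrainVision marker file missing: %s", markerfile), call. = FALSE)
  }
  if (!file.exists(datafile)) {
    stop(sprintf("BrainVision data file missing: %s", datafile), call. = FALSE)
  }
  n_chan <- as.integer(ci[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ci[["SamplingInterval"]])  # interval is in microseconds
  if (!identical(toupper(ci[["DataOrientation"]]), "MULTIPLEXED")) {
    stop("only MULTIPLEXED BrainVision data is supported", call. = FALSE)
  }
  fmt <- toupper(hdr[["Binary Infos"]][["BinaryFormat"]])
  chinfo <- hdr[["Channel Infos"]]
  labels <- character(n_chan); resol <- rep(1, n_chan)
  for (i in seq_len(n_chan)) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",", fixed = TRUE)[[1L]]
    labels[i] <- parts[1L]
    if (length(parts) >= 3L && nzchar(parts[3L])) resol[i] <- as.numeric(parts[3L])
  }
  sz <- file.size(datafile)
  con <- file(datafile, "rb"); on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, "numeric", n = sz / 4L, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(con, "integer", n = sz / 2L, size = 2L, signed = TRUE,
                   endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  n_samp <- length(raw) %/% n_chan
  data <- matrix(raw[seq_len(n_chan * n_samp)], nrow = n_chan)
  data <- data * resol
  mk <- parse_ini_sections(readLines(markerfile, warn = FALSE))[["Marker Infos"]]
  markers <- if (!is.null(mk) && length(mk)) {
    rows <- lapply(unname(mk), function(v) {
      parts <- strsplit(v, ",", fixed = TRUE)[[1L]]
      tibble::tibble(type = parts[1L], description = parts[2L],
                     position = as.integer(parts[3L]))
    })
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(type = character(0), description = character(0),
                   position = integer(0))
  }
  list(data = data, fs = fs, channels = labels, markers = markers)
}

#' Write a BrainVision triplet
#'
#' Writes `basepath.vhdr`, `basepath.vmrk` and `basepath.eeg`
#' (IEEE_FLOAT_32, multiplexed). Mainly used to exercise the reader on
#' synthetic recordings.
#'
#' @param data `channel x sample` matrix, microvolts.
#' @param fs sampling rate, Hz.
#' @param basepath output path without extension.
#' @param channels channel labels.
#' @param markers optional tibble with `type`, `description`, `position`.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(data, fs, basepath, channels = NULL, markers = NULL) {
  n_chan <- nrow(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(n_chan))
  base <- basename(basepath)
  vhdr <- paste0(basepath, ".vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_chan),
    paste0("SamplingInterval=", format(1e6 / fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_chan), channels)
  ), vhdr)
  mlines <- c("Brain Vision Data Exchange Marker File Version 1.0",
              "[Common Infos]",
              paste0("DataFile=", base, ".eeg"),
              "[Marker Infos]")
  if (!is.null(markers) && nrow(markers)) {
    mlines <- c(mlines, sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(markers)),
                                markers$type, markers$description,
                                markers$position))
  }
  writeLines(mlines, paste0(basepath, ".vmrk"))
  con <- file(paste0(basepath, ".eeg"), "wb")
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  close(con)
  invisible(vhdr)
}

#' Read an EDF/EDF+ recording
#'
#' Minimal reader: fixed-width ASCII header, 16-bit little-endian samples,
#' physical scaling from the per-signal calibration fields. All signals
#' must share one sampling rate. An EDF+ annotation channel, if present, is
#' dropped.
#'
#' @param path path to the `.edf` file.
#' @return list with `data` (`channel x sample` matrix), `fs`, `channels`,
#'   `markers` (empty tibble).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  rdstr <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  rdstr(8)                       # version
  rdstr(80); rdstr(80)           # patient / recording id
  rdstr(8); rdstr(8)             # start date / time
  as.integer(rdstr(8))           # header bytes
  rdstr(44)                      # reserved
  n_rec <- as.integer(rdstr(8))
  dur <- as.numeric(rdstr(8))
  ns <- as.integer(rdstr(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rdstr(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)                # transducer, physical dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                        # prefiltering
  nr <- as.integer(fld(8))       # samples per record per signal
  fld(32)                        # reserved
  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (length(unique(nr[keep])) != 1L) {
    stop("EDF signals with differing sampling rates are not supported", call. = FALSE)
  }
  fs <- nr[keep][1L] / dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, sum(keep), n_rec * nr[keep][1L])
  row_of <- cumsum(keep)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = nr[s], size = 2L, signed = TRUE,
                      endian = "little")
      if (keep[s]) {
        idx <- ((r - 1L) * nr[s] + 1L):(r * nr[s])
        data[row_of[s], idx] <- (vals - dig_min[s]) * gain[s] + phys_min[s]
      }
    }
  }
  list(data = data, fs = fs, channels = labels[keep],
       markers = tibble::tibble(type = character(0),
                                description = character(0),
                                position = integer(0)))
}

#' Write a minimal EDF file
#'
#' One-second data records, 16-bit samples, physical range taken from the
#' data. Mainly used to exercise the reader on synthetic recordings;
#' quantization to the 16-bit grid is lossy.
#'
#' @param data `channel x sample` matrix.
#' @param fs sampling rate, Hz (samples per channel must be a multiple of
#'   `fs`).
#' @param path output path.
#' @param channels channel labels.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, fs, path, channels = NULL) {
  ns <- nrow(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ns))
  if (ncol(data) %% fs != 0) {
    stop("sample count must be a whole number of 1-second records", call. = FALSE)
  }
  n_rec <- ncol(data) / fs
  pmin_ <- floor(apply(data, 1L, min)); pmax_ <- ceiling(apply(data, 1L, max))
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  con <- file(path, "wb"); on.exit(close(con))
  pad <- function(x, w) {
    s <- substr(format(x, width = w, justify = "left"), 1L, w)
    writeChar(sprintf(paste0("%-", w, "s"), s), con, nchars = w, eos = NULL)
  }
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(as.character(256L + ns * 256L), 8); pad("", 44)
  pad(as.character(n_rec), 8); pad("1", 8); pad(as.character(ns), 4)
  for (i in seq_len(ns)) pad(channels[i], 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(format(pmin_[i]), 8)
  for (i in seq_len(ns)) pad(format(pmax_[i]), 8)
  for (i in seq_len(ns)) pad("-32768", 8)
  for (i in seq_len(ns)) pad("32767", 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(as.character(fs), 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- (pmax_ - pmin_) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      idx <- ((r - 1L) * fs + 1L):(r * fs)
      dig <- round((data[s, idx] - pmin_[s]) / gain[s] + (-32768))
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Downsample a continuous recording
#'
#' Integer factors use `signal::decimate` (8th-order Chebyshev low-pass
#' then pick every q-th sample); non-integer rational factors use
#' `signal::resample`. The output sampling rate is exactly `new_fs` and the
#' length scales by `new_fs / fs`.
#'
#' @param rec a recording list (`data`, `fs`, `channels`, `markers`) as
#'   returned by [read_brainvision()] / [read_edf()].
#' @param new_fs target sampling rate, Hz.
#' @return the recording with `data`, `fs` and marker positions rescaled.
#' @export
downsample_recording <- function(rec, new_fs) {
  if (new_fs >= rec$fs) stop("`new_fs` must be below the recording rate", call. = FALSE)
  q <- rec$fs / new_fs
  n_out <- ceiling(ncol(rec$data) / q)
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) {
    out[ch, ] <- if (abs(q - round(q)) < 1e-9) {
      signal::decimate(rec$data[ch, ], round(q))[seq_len(n_out)]
    } else {
      signal::resample(rec$data[ch, ], p = new_fs, q = rec$fs)[seq_len(n_out)]
    }
  }
  markers <- rec$markers
  if (nrow(markers)) markers$position <- as.integer(round((markers$position - 1L) / q) + 1L)
  list(data = out, fs = new_fs, channels = rec$channels, markers = markers)
}

#' Cut a continuous recording into stimulus-locked trials
#'
#' @param rec recording list (`data`, `fs`, `channels`, `markers`).
#' @param window `c(start_ms, end_ms)` around each stimulus (half-open in
#'   samples: floor at the start, ceil at the end, 0-based offsets).
#' @param positions stimulus sample positions (1-based); defaults to all
#'   `Stimulus` markers in the recording.
#' @return a `tep_set` (time 0 at stimulus onset).
#' @export
epoch_around_events <- function(rec, window = c(-250, 500), positions = NULL) {
  if (is.null(positions)) {
    positions <- rec$markers$position[rec$markers$type == "Stimulus"]
  }
  if (length(positions) == 0L) stop("no stimulus positions available", call. = FALSE)
  i0 <- floor(window[1] / 1000 * rec$fs)
  i1 <- ceiling(window[2] / 1000 * rec$fs)
  offs <- i0:(i1 - 1L)
  ok <- positions + i0 >= 1L & positions + i1 - 1L <= ncol(rec$data)
  if (!all(ok)) warning(sprintf("%d trial(s) outside the recording dropped", sum(!ok)))
  positions <- positions[ok]
  if (length(positions) == 0L) stop("no complete trials inside the recording", call. = FALSE)
  data <- array(0, c(length(positions), nrow(rec$data), length(offs)))
  for (tr in seq_along(positions)) {
    data[tr, , ] <- rec$data[, positions[tr] + offs, drop = FALSE]
  }
  tep_set(data, fs = rec$fs, times = offs / rec$fs * 1000, channels = rec$channels)
}
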