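#' Multichannel spontaneous-EEG epochs
#'
#' An `epoch_set` holds fixed-length multichannel EEG epochs as a numeric
#' array with dimensions `epoch x channel x sample`, together with the
#' sampling rate and channel labels. Amplitudes are in microvolts.
#'
#' @param data numeric array `epoch x channel x sample` (a `channel x sample`
#'   matrix is promoted to a single epoch).
#' @param fs sampling rate in Hz.
#' @param channels optional character vector of channel labels.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, channels = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be an epoch x channel x sample array", call. = FALSE)
  }
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  fs <- as.numeric(fs)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2L]))
  if (length(channels) != dim(data)[2L]) {
    stop("`channels` length must match the channel dimension", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, channels = as.character(channels)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples @ %g Hz (%.1f s/epoch)\n",
    d[1], d[2], d[3], x$fs, d[3] / x$fs
  ))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' TMS-evoked trial set
#'
#' A `tep_set` holds single-trial TMS-evoked EEG segments as a
#' `trial x channel x sample` array, a sampling rate, and the time axis in
#' milliseconds relative to the stimulus (time 0 = pulse onset). Amplitudes
#' are in microvolts.
#'
#' @param data numeric array `trial x channel x sample`.
#' @param fs sampling rate in Hz.
#' @param times numeric vector of per-sample times in ms (length = sample
#'   dimension); must span negative (baseline) and non-negative (response)
#'   times.
#' @param channels optional channel labels.
#' @return an object of class `tep_set`.
#' @export
tep_set <- function(data, fs, times, channels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a trial x channel x sample array", call. = FALSE)
  }
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  fs <- as.numeric(fs)
  if (length(times) != dim(data)[3L]) {
    stop("`times` length must match the sample dimension", call. = FALSE)
  }
  if (!any(times < 0) || !any(times >= 0)) {
    stop("`times` must span pre-stimulus (negative) and post-stimulus times",
         call. = FALSE)
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2L]))
  structure(
    list(data = data, fs = fs, times = as.numeric(times),
         channels = as.character(channels)),
    class = "tep_set"
  )
}

#' @export
print.tep_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<tep_set> %d trials x %d channels x %d samples @ %g Hz, %g..%g ms\n",
    d[1], d[2], d[3], x$fs, min(x$times), max(x$times)
  ))
  invisible(x)
}

#' @export
dim.tep_set <- function(x) dim(x$data)

#' Write an epoch container to a plain-text file
#'
#' The container is a self-describing text format: the first line is a JSON
#' header (object type, dimensions, sampling rate, channel labels, and the
#' time axis for trial sets); each following line holds one `(epoch, channel)`
#' or `(trial, channel)` row of samples, comma-separated, printed with 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param x an `epoch_set` or `tep_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  if (inherits(x, "epoch_set")) {
    meta <- list(type = "epoch_set", dims = dim(x$data), fs = x$fs,
                 channels = x$channels)
  } else if (inherits(x, "tep_set")) {
    meta <- list(type = "tep_set", dims = dim(x$data), fs = x$fs,
                 channels = x$channels, times = x$times)
  } else {
    stop("`x` must be an epoch_set or tep_set", call. = FALSE)
  }
  d <- dim(x$data)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), con)
  for (e in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      writeLines(paste(sprintf("%.17g", x$data[e, ch, ]), collapse = ","), con)
    }
  }
  invisible(path)
}

#' Read an epoch container written by [write_epochs()]
#'
#' @param path path to a container file.
#' @return an `epoch_set` or `tep_set`, matching what was written.
#' @export
read_epoch_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1L])
  d <- as.integer(meta$dims)
  if (length(lines) - 1L != d[1L] * d[2L]) {
    stop("malformed container: row count does not match header dims",
         call. = FALSE)
  }
  vals <- lapply(lines[-1L], function(l) as.numeric(strsplit(l, ",", fixed = TRUE)[[1L]]))
  if (any(vapply(vals, length, 1L) != d[3L])) {
    stop("malformed container: sample count does not match header dims",
         call. = FALSE)
  }
  data <- array(0, d)
  i <- 1L
  for (e in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    data[e, ch, ] <- vals[[i]]
    i <- i + 1L
  }
  if (identical(meta$type, "epoch_set")) {
    epoch_set(data, fs = meta$fs, channels = meta$channels)
  } else if (identical(meta$type, "tep_set")) {
    tep_set(data, fs = meta$fs, times = as.numeric(meta$times),
            channels = meta$channels)
  } else {
    stop("unknown container type: ", meta$type, call. = FALSE)
  }
}

#' Cut a continuous recording into fixed-length epochs
#'
#' @param x `channel x sample` matrix of continuous data.
#' @param fs sampling rate in Hz.
#' @param epoch_length epoch length in seconds (default 5). Trailing samples
#'   that do not fill a complete epoch are dropped.
#' @param channels optional channel labels.
#' @return an `epoch_set`.
#' @export
epoch_continuous <- function(x, fs, epoch_length = 5, channels = NULL) {
  if (!is.matrix(x)) stop("`x` must be a channel x sample matrix", call. = FALSE)
  stopifnot_scalar_number(epoch_length, "epoch_length", positive = TRUE)
  len <- floor(epoch_length * fs)
  n_ep <- floor(ncol(x) / len)
  if (n_ep < 1L) stop("recording shorter than one epoch", call. = FALSE)
  data <- array(0, c(n_ep, nrow(x), len))
  for (e in seq_len(n_ep)) {
    data[e, , ] <- x[, ((e - 1L) * len + 1L):(e * len), drop = FALSE]
  }
  epoch_set(data, fs = fs, channels = channels)
}
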