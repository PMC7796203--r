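#' Gesture taxonomy
#'
#' The nine standardized hand gestures used as the default class labels:
#' five fingers extended (FFE), five fingers closed (FFC), extended thumb
#' (ET), flexion of thumb (FT), extended index finger (EIF), extended index
#' and middle finger (EIMF), extended thumb and index finger (ETIF),
#' extended thumb and pinkie (ETP), and flexion of thumb and index finger
#' (FTIF).
#'
#' @return Character vector of length 9, gesture abbreviations in class-id
#'   order (class 1 = FFE, ..., class 9 = FTIF).
#' @export
gesture_classes <- function() {
  c("FFE", "FFC", "ET", "FT", "EIF", "EIMF", "ETIF", "ETP", "FTIF")
}

#' Default channel names
#'
#' The four forearm muscles recorded by the default montage: extensor carpi
#' radialis (ECR), extensor digitorum (ED), flexor digitorum superficialis
#' (FDS) and extensor pollicis brevis (EPB).
#'
#' @return Character vector of length 4.
#' @export
default_channels <- function() c("ECR", "ED", "FDS", "EPB")

#' Multichannel sEMG recording
#'
#' Container for one trial of simultaneously sampled signals: a numeric
#' matrix with one column per channel, the sampling rate, and optional
#' gesture label and subject identifier.
#'
#' @param samples Numeric matrix, `n_samples x n_channels`; all values must
#'   be finite. A vector is treated as a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Optional character vector of channel labels; default
#'   [default_channels()] when there are four channels, else `ch1, ch2, ...`.
#' @param label Optional gesture class id (positive integer; 1-9 in the
#'   default taxonomy, see [gesture_classes()]).
#' @param subject_id Optional subject identifier (scalar).
#' @return An object of class `semg_recording` with fields `samples`, `fs`,
#'   `channel_names`, `label`, `subject_id`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(400), 100, 4), fs = 2000)
#' rec
recording <- function(samples, fs, channel_names = NULL, label = NULL,
                      subject_id = NULL) {
  if (is.vector(samples) && is.numeric(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stopf("samples must be a numeric matrix (samples x channels)")
  if (ncol(samples) < 1L || nrow(samples) < 1L)
    stopf("recording needs at least one sample and one channel")
  assert_finite(samples, "samples")
  assert_scalar_number(fs, "fs", positive = TRUE)
  nc <- ncol(samples)
  if (is.null(channel_names)) {
    channel_names <- if (nc == 4L) default_channels() else paste0("ch", seq_len(nc))
  }
  if (length(channel_names) != nc)
    stopf("channel_names has length %d but there are %d channels",
          length(channel_names), nc)
  if (!is.null(label)) {
    if (length(label) != 1L || !is.finite(label) || label != as.integer(label) || label < 1)
      stopf("label must be a single positive integer class id")
    label <- as.integer(label)
  }
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         label = label, subject_id = subject_id),
    class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %d samples x %d channels @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.null(x$label)) {
    nm <- if (x$label <= 9L) gesture_classes()[x$label] else as.character(x$label)
    cat(sprintf("  label: %d (%s)\n", x$label, nm))
  }
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' Write a recording as delimited text
#'
#' One row per sample, one comma-separated column per channel, with a
#' header line of channel names. Values are printed at full precision
#' (`%.17g`) so that [read_recording()] round-trips bit-exactly.
#'
#' @param recording A [recording()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  if (!inherits(recording, "semg_recording"))
    stopf("write_recording expects a semg_recording")
  s <- recording$samples
  fmt <- matrix(format_full(s), nrow(s), ncol(s))
  lines <- c(paste(recording$channel_names, collapse = ","),
             do.call(paste, c(lapply(seq_len(ncol(s)), function(j) fmt[, j]),
                              sep = ",")))
  con <- file(path, open = "wb") # fixed \n endings for byte reproducibility
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Parses the format written by [write_recording()]: optional header line
#' with channel names, then one comma-separated row per sample. Ragged or
#' non-numeric rows raise a parse error naming the offending line.
#'
#' @param path Input file path.
#' @param fs Sampling rate in Hz (the text format does not store it; supply
#'   it here or through a dataset manifest).
#' @param label,subject_id Optional metadata attached to the recording.
#' @param sep Field separator (default comma).
#' @return A [recording()] object.
#' @export
read_recording <- function(path, fs, label = NULL, subject_id = NULL, sep = ",") {
  if (!file.exists(path)) stopf("signal file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stopf("empty signal file: %s", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  has_header <- anyNA(first)
  channel_names <- NULL
  if (has_header) {
    channel_names <- trimws(fields[[1L]])
    fields <- fields[-1L]
    if (length(fields) == 0L) stopf("no data rows in %s", path)
  }
  ncol <- length(fields[[1L]])
  nf <- lengths(fields)
  bad <- which(nf != ncol)
  if (length(bad)) {
    line_no <- bad[1L] + if (has_header) 1L else 0L
    stopf("parse error in %s: line %d has %d fields, expected %d",
          path, line_no, nf[bad[1L]], ncol)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    row <- (which(is.na(vals))[1L] - 1L) %/% ncol + 1L
    line_no <- row + if (has_header) 1L else 0L
    stopf("parse error in %s: non-numeric value on line %d", path, line_no)
  }
  samples <- matrix(vals, ncol = ncol, byrow = TRUE)
  recording(samples, fs = fs, channel_names = channel_names,
            label = label, subject_id = subject_id)
}

#' Write a dataset manifest
#'
#' A manifest is a CSV table with columns `path`, `label`, `subject`, `fs`
#' listing the signal files of a dataset. Paths are stored as written;
#' [read_manifest()] resolves relative paths against the manifest location.
#'
#' @param manifest Data frame with columns `path`, `label`, `subject`, `fs`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("path", "label", "subject", "fs")
  if (!all(need %in% names(manifest)))
    stopf("manifest needs columns: %s", paste(need, collapse = ", "))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(need, collapse = ","), con, sep = "\n", useBytes = TRUE)
  if (nrow(manifest)) {
    rows <- paste(manifest$path, manifest$label, manifest$subject, manifest$fs,
                  sep = ",")
    writeLines(rows, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path Manifest CSV path (see [write_manifest()]).
#' @return Data frame with columns `path` (resolved relative to the
#'   manifest directory when not absolute), `label`, `subject`, `fs`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "subject", "fs")
  if (!all(need %in% names(m)))
    stopf("manifest %s needs columns: %s", path, paste(need, collapse = ", "))
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(base, m$path[rel])
  m
}
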