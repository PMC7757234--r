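#' Multi-channel EEG recording container
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channels channel names (row names of `data`).
#' @param fs sampling rate, samples/s.
#' @param events event table (`onset_sample`, `time_s`, `code`).
#' @param meta named list of provenance fields (subject, block, condition,
#'   seed, ...).
#' @return an object of class `assr_recording`.
#' @export
new_recording <- function(data, channels, fs, events, meta = list()) {
  stopifnot(is.matrix(data), nrow(data) == length(channels))
  if (!all(is.finite(data))) stop("recording data must be finite", call. = FALSE)
  if (nrow(events) && (any(events$onset_sample < 1) ||
                       any(events$onset_sample > ncol(data))))
    stop("event onsets outside the recording", call. = FALSE)
  rownames(data) <- channels
  structure(list(data = data, channels = channels, fs = fs,
                 events = events, meta = meta),
            class = "assr_recording")
}

#' @export
print.assr_recording <- function(x, ...) {
  cat(sprintf("<assr_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  events:", nrow(x$events), "| ",
      paste(sprintf("%s=%d", names(table(x$events$code)), table(x$events$code)),
            collapse = " "), "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `assr_recording`.
#' @export
recording_duration <- function(recording) ncol(recording$data) / recording$fs

#' Write / read the plain-text recording container
#'
#' Serialises a recording to a directory holding `data.tsv` (one column per
#' channel), `events.tsv`, and `meta.json`. All files are plain text so runs
#' are diffable and portable.
#'
#' @param recording an `assr_recording`.
#' @param dir target directory (created if missing).
#' @return `write_recording` returns `dir` invisibly; `read_recording`
#'   returns the reconstructed `assr_recording`.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(t(recording$data), file.path(dir, "data.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(recording$events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- c(recording$meta, list(fs = recording$fs,
                                 channels = recording$channels))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_recording
#' @param dir directory previously written by [write_recording()].
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  dat <- as.matrix(utils::read.table(file.path(dir, "data.tsv"),
                                     header = TRUE, sep = "\t",
                                     check.names = FALSE))
  ev <- utils::read.table(file.path(dir, "events.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  fs <- meta$fs; chans <- meta$channels
  meta$fs <- NULL; meta$channels <- NULL
  new_recording(t(dat), chans, fs, ev, meta)
}
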