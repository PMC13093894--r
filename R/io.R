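# Text-based ingestion and serialization: TSV signal/event files, JSON for
# structured results. All writers stamp a schema_version.

SCHEMA_VERSION <- 1L

#' Read an LFP recording from delimited text
#'
#' The signal file must be tab-delimited with header columns `time_s` and
#' `value`; the optional events file holds one onset time (s) per line.
#' Timestamps must be strictly increasing and regular to within 1 ppm of the
#' median sampling interval; rows with non-finite samples are rejected with
#' their row numbers.
#'
#' @param signal_path path to the signal TSV.
#' @param events_path optional path to the events file; missing means no
#'   events.
#' @param label recording label.
#' @param group optional group label.
#' @return an [lfp_recording()].
#' @export
read_recording <- function(signal_path, events_path = NULL, label = "",
                           group = NA_character_) {
  d <- utils::read.delim(signal_path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "value") %in% names(d)))
    stop(sprintf("'%s': header must name columns time_s and value", signal_path),
         call. = FALSE)
  bad <- which(!is.finite(d$value))
  if (length(bad))
    stop(sprintf("'%s': non-finite samples at row(s) %s", signal_path,
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  dt <- diff(d$time_s)
  if (any(dt <= 0))
    stop(sprintf("'%s': time column not strictly increasing at row(s) %s",
                 signal_path,
                 paste(utils::head(which(dt <= 0) + 1L, 10), collapse = ", ")),
         call. = FALSE)
  med <- stats::median(dt)
  if (any(abs(dt - med) > 1e-6 * med))
    stop(sprintf("'%s': irregular sampling (interval deviates from %g s by > 1 ppm)",
                 signal_path, med), call. = FALSE)
  fs <- 1 / med
  events <- numeric(0)
  if (!is.null(events_path)) {
    events <- scan(events_path, what = numeric(), quiet = TRUE)
    dur <- nrow(d) / fs
    out <- events[events < 0 | events >= dur]
    if (length(out))
      stop(sprintf("'%s': event time(s) outside the signal span [0, %g): %s",
                   events_path, dur, paste(out, collapse = ", ")), call. = FALSE)
  }
  lfp_recording(d$value, fs, events, label = label, group = group)
}

#' Write an LFP recording to delimited text
#'
#' Inverse of [read_recording()]: a `time_s`/`value` TSV (full double
#' precision, so round trips agree to ~1e-12) plus an events file with one
#' onset per line.
#'
#' @param recording an [lfp_recording()].
#' @param signal_path output signal TSV path.
#' @param events_path optional output events path.
#' @return invisibly, the paths written.
#' @export
write_recording <- function(recording, signal_path, events_path = NULL) {
  stopifnot(inherits(recording, "LfpRecording"))
  t <- (seq_along(recording$samples) - 1L) / recording$fs
  con <- file(signal_path, "w")
  writeLines("time_s\tvalue", con)
  writeLines(sprintf("%.12g\t%.17g", t, recording$samples), con)
  close(con)
  if (!is.null(events_path))
    writeLines(sprintf("%.12g", recording$events), events_path)
  invisible(c(signal_path, events_path))
}

#' Write structured results to an output directory
#'
#' Data frames become TSV; everything else becomes JSON. Every file carries
#' a `schema_version` (as a field for JSON, as a header comment for TSV).
#'
#' @param objects named list of results.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(objects, out_dir) {
  if (is.null(names(objects)) || any(names(objects) == ""))
    stop("`objects` must be a fully named list", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.data.frame(obj)) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      con <- file(p, "w")
      writeLines(sprintf("# schema_version: %d", SCHEMA_VERSION), con)
      utils::write.table(format(obj, digits = 15, trim = TRUE, scientific = NA),
                         con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    } else {
      p <- file.path(out_dir, paste0(nm, ".json"))
      payload <- c(list(schema_version = SCHEMA_VERSION), as.list(obj))
      jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
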