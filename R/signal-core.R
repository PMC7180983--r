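#' Distance signal from the chair-stand sensor
#'
#' A `distance_signal` holds one uniformly sampled distance-versus-time trace
#' (in cm) from a chair-mounted ultrasound range sensor, typically a 30-s
#' chair-stand test sampled at 10 Hz (about 300 samples). The time of sample
#' `i` is exactly `(i - 1) / rate_hz` seconds: indexing is 0-based in all
#' reported times and event indices, and the first sample sits at t = 0.
#'
#' Raw device recordings contain only finite non-negative distances; missing
#' values (`NA`) may appear after preprocessing (outlier nulling).
#'
#' @param samples numeric vector of distances in cm; non-negative or `NA`.
#' @param rate_hz sampling rate in Hz (default 10, the device cadence of one
#'   pulse every 100 ms).
#' @param subject_id opaque subject label.
#' @return An object of class `distance_signal` with fields `samples`,
#'   `rate_hz` and `subject_id`.
#' @examples
#' s <- distance_signal(c(15, 15, 50, 50, 15), rate_hz = 10, subject_id = "s1")
#' signal_times(s)
#' @export
distance_signal <- function(samples, rate_hz = 10, subject_id = NA_character_) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  finite <- samples[!is.na(samples)]
  if (any(finite < 0)) {
    stop("distance samples must be non-negative", call. = FALSE)
  }
  structure(
    list(samples = samples, rate_hz = rate_hz,
         subject_id = as.character(subject_id)),
    class = "distance_signal"
  )
}

#' @export
length.distance_signal <- function(x) length(x$samples)

#' Sample times of a distance signal
#'
#' @param signal a [distance_signal()].
#' @return numeric vector of times in seconds, `(0:(n-1)) / rate_hz`.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "distance_signal"))
  (seq_along(signal$samples) - 1) / signal$rate_hz
}

#' @export
print.distance_signal <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<distance_signal> subject '%s': %d samples at %g Hz (%.1f s)\n",
              x$subject_id, n, x$rate_hz, n / x$rate_hz))
  rng <- range(x$samples, na.rm = TRUE)
  cat(sprintf("  range %.1f-%.1f cm, %d missing\n",
              rng[1], rng[2], sum(is.na(x$samples))))
  invisible(x)
}

#' Read a distance signal from CSV
#'
#' Expects the two-column dialect `time_s,distance_cm` with a mandatory header
#' and '.' as decimal separator. The time column is advisory: sample order in
#' the file is authoritative, because the sensor emits at a fixed cadence.
#' Negative, non-numeric or missing distance values are rejected (raw device
#' files never contain them); malformed rows are reported by their data-row
#' number (1-based, header excluded).
#'
#' @param path path to a CSV file.
#' @param rate_hz sampling rate in Hz to attach to the signal (default 10).
#' @param subject_id subject label; defaults to the file name without
#'   extension.
#' @return A [distance_signal()].
#' @export
read_signal <- function(path, rate_hz = 10, subject_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("signal file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("empty signal file: '%s'", path), call. = FALSE)
  }
  header <- tolower(gsub("\\s", "", lines[[1]]))
  if (!identical(strsplit(header, ",")[[1]][1:2], c("time_s", "distance_cm"))) {
    stop(sprintf("'%s': expected header 'time_s,distance_cm'", path),
         call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) == 0L) {
    stop(sprintf("empty signal file (header only): '%s'", path), call. = FALSE)
  }
  samples <- numeric(length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], ",", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stop(sprintf("'%s': malformed row %d ('%s')", path, i, body[[i]]),
           call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(fields[[2]]))
    if (is.na(val) || val < 0) {
      stop(sprintf("'%s': malformed row %d ('%s'): distance must be a non-negative number",
                   path, i, body[[i]]), call. = FALSE)
    }
    samples[[i]] <- val
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  distance_signal(samples, rate_hz = rate_hz, subject_id = subject_id)
}

#' Write a distance signal to CSV
#'
#' Inverse of [read_signal()]: writes `time_s,distance_cm` rows, one per
#' sample, times computed from the sampling rate. Missing samples are
#' serialized as the literal token `NA`. Round-tripping reproduces the signal
#' to within 1e-6 cm per sample.
#'
#' @param signal a non-empty [distance_signal()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "distance_signal"))
  if (length(signal$samples) == 0L) {
    stop("cannot write an empty signal", call. = FALSE)
  }
  t <- signal_times(signal)
  d <- ifelse(is.na(signal$samples), "NA",
              sprintf("%.10g", signal$samples))
  lines <- c("time_s,distance_cm", paste(sprintf("%.10g", t), d, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read manual-count annotations
#'
#' Annotation files carry one row per subject with the rater's counts:
#' `subject_id,valid_count,total_count`. A stand-up is valid only if the
#' subject reached a complete upright posture; invalid attempts are counted
#' in the total but excluded from the valid score, so
#' `total_count >= valid_count >= 0` is enforced.
#'
#' @param path path to the annotation CSV.
#' @return data.frame with columns `subject_id` (character), `valid_count`
#'   and `total_count` (integer).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "valid_count", "total_count")
  if (!all(req %in% names(df))) {
    stop(sprintf("'%s': expected columns %s", path,
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$valid_count <- as.integer(df$valid_count)
  df$total_count <- as.integer(df$total_count)
  bad <- which(is.na(df$valid_count) | is.na(df$total_count) |
                 df$valid_count < 0 | df$total_count < df$valid_count)
  if (length(bad) > 0L) {
    stop(sprintf("'%s': invalid counts in row(s) %s (need total >= valid >= 0)",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  df[req]
}

#' Write manual-count annotations
#'
#' @param annotations data.frame with columns `subject_id`, `valid_count`,
#'   `total_count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  req <- c("subject_id", "valid_count", "total_count")
  stopifnot(all(req %in% names(annotations)))
  utils::write.csv(annotations[req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
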