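#' Detection result
#'
#' Ordered set of detected sit-to-stand transitions plus the final count.
#' Event indices are 0-based sample indices into the input signal; times are
#' `index / rate_hz` seconds; heights are filtered-signal values in cm.
#'
#' @param index integer vector of 0-based sample indices, strictly increasing.
#' @param time_s event times in seconds.
#' @param height_cm peak heights in cm.
#' @param algorithm label of the producing detector ("v1" or "v2").
#' @return object of class `detection_result` with fields `events`
#'   (data.frame `index`, `time_s`, `height_cm`) and `count`.
#' @export
detection_result <- function(index = integer(0), time_s = numeric(0),
                             height_cm = numeric(0), algorithm = NA_character_) {
  stopifnot(length(index) == length(time_s),
            length(index) == length(height_cm))
  if (length(index) > 1L && any(diff(index) <= 0)) {
    stop("event indices must be strictly increasing", call. = FALSE)
  }
  structure(
    list(events = data.frame(index = as.integer(index),
                             time_s = as.numeric(time_s),
                             height_cm = as.numeric(height_cm)),
         count = length(index),
         algorithm = as.character(algorithm)),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> algorithm %s: %d transition(s)\n",
              x$algorithm, x$count))
  if (x$count > 0) {
    cat(sprintf("  t = %s s\n",
                paste(formatC(x$events$time_s, format = "g"), collapse = ", ")))
  }
  invisible(x)
}
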