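#' Calibration set: annotated signals for parameter tuning
#'
#' Pairs each distance signal with its manual-count annotation, the way the
#' original detectors were tuned on ten annotated recordings per group. The
#' target chooses which manual count the detector should match: the valid
#' count (upright posture reached) or the total count.
#'
#' @param signals list of [distance_signal()] objects.
#' @param annotations data.frame as returned by [read_annotations()].
#' @param target `"valid"` or `"total"`.
#' @return object of class `calibration_set`.
#' @export
calibration_set <- function(signals, annotations,
                            target = c("valid", "total")) {
  target <- match.arg(target)
  stopifnot(length(signals) >= 1)
  ids <- vapply(signals, function(s) s$subject_id, character(1))
  missing <- setdiff(ids, annotations$subject_id)
  if (length(missing) > 0L) {
    stop(sprintf("no annotation for subject(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  col <- paste0(target, "_count")
  counts <- annotations[[col]][match(ids, annotations$subject_id)]
  structure(list(signals = signals, counts = as.integer(counts),
                 target = target),
            class = "calibration_set")
}

#' Grid-search calibration of detector parameters
#'
#' Exhaustively evaluates every row of a parameter grid, scoring each by the
#' mean absolute error between the detector's count and the manual count
#' over the calibration set, and returns the best gridpoint. "Mean error" is
#' taken as mean *absolute* error: a signed mean could be driven to zero by
#' cancelling over- and under-counts, which would defeat the tuning. Ties
#' are broken by the smaller magnitude of the mean signed bias, then by grid
#' order. A detector failure on a signal is scored with that signal's
#' annotated count (the worst case, equivalent to reporting zero), never a
#' crash.
#'
#' @param set a [calibration_set()].
#' @param detector `"v1"` or `"v2"`.
#' @param grid data.frame whose columns are a subset of the detector's
#'   parameter names ([params_v1()]: `df`, `pht`, ...; [params_v2()]:
#'   `atw`, `mpd_s`, `msbp`, `msd`, ...); unspecified parameters keep their
#'   defaults. One row per gridpoint, e.g. from [expand.grid()].
#' @return object of class `calibration_result`: `best_params` (a params
#'   object), `best_index` (row of `grid`), `best_mae`, and `table` (the
#'   full per-gridpoint error table with columns `mae` and `bias`).
#' @export
calibrate <- function(set, detector = c("v1", "v2"), grid) {
  detector <- match.arg(detector)
  stopifnot(inherits(set, "calibration_set"), is.data.frame(grid))
  if (nrow(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  maker <- if (detector == "v1") params_v1 else params_v2
  runner <- if (detector == "v1") detect_v1 else detect_v2
  allowed <- names(formals(maker))
  bad <- setdiff(names(grid), allowed)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s parameter(s) in grid: %s", detector,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  mae <- numeric(nrow(grid))
  bias <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    params <- do.call(maker, as.list(grid[r, , drop = FALSE]))
    err <- vapply(seq_along(set$signals), function(i) {
      cnt <- tryCatch(runner(set$signals[[i]], params)$count,
                      error = function(e) 0L)
      cnt - set$counts[[i]]
    }, numeric(1))
    mae[[r]] <- mean(abs(err))
    bias[[r]] <- mean(err)
  }
  ord <- order(mae, abs(bias), seq_len(nrow(grid)))
  best <- ord[[1]]
  structure(list(
    best_params = do.call(maker, as.list(grid[best, , drop = FALSE])),
    best_index = best, best_mae = mae[[best]],
    table = cbind(grid, mae = mae, bias = bias),
    detector = detector, target = set$target
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> detector %s, target '%s' count\n",
              x$detector, x$target))
  cat(sprintf("  best gridpoint #%d, mean absolute error %.3f\n",
              x$best_index, x$best_mae))
  print(x$table[x$best_index, , drop = FALSE])
  invisible(x)
}
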