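#' Run a detector over signal files or signal objects
#'
#' Thin batch wrapper tying the pipeline together for the command line:
#' reads each signal (directories are expanded to their `*.csv` members in
#' lexicographic order), runs the chosen detector, and returns a one-row-
#' per-signal report.
#'
#' @param inputs character vector of CSV paths and/or directories, or a list
#'   of [distance_signal()] objects.
#' @param algorithm `"v1"` or `"v2"`.
#' @param params a [params_v1()] / [params_v2()] matching `algorithm`;
#'   defaults used when `NULL`.
#' @param rate_hz sampling rate for file inputs (default 10).
#' @return data.frame with columns `subject_id`, `count`, `event_times_s`
#'   (events as a semicolon-joined string), plus attribute `"results"`
#'   holding the full [detection_result()] list.
#' @export
run_detect <- function(inputs, algorithm = c("v2", "v1"), params = NULL,
                       rate_hz = 10) {
  algorithm <- match.arg(algorithm)
  if (is.null(params)) {
    params <- if (algorithm == "v1") params_v1() else params_v2()
  }
  runner <- if (algorithm == "v1") detect_v1 else detect_v2
  signals <- if (is.character(inputs)) {
    paths <- unlist(lapply(inputs, function(p) {
      if (dir.exists(p)) {
        f <- sort(list.files(p, pattern = "\\.csv$", full.names = TRUE))
        f[basename(f) != "annotations.csv"]   # cohort layout side file
      } else {
        p
      }
    }))
    lapply(paths, read_signal, rate_hz = rate_hz)
  } else {
    inputs
  }
  results <- lapply(signals, runner, params = params)
  df <- data.frame(
    subject_id = vapply(signals, function(s) s$subject_id, character(1)),
    count = vapply(results, function(r) r$count, integer(1)),
    event_times_s = vapply(results, function(r) {
      paste(formatC(r$events$time_s, format = "g"), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  attr(df, "results") <- results
  df
}

#' Validate a detector against manual annotations
#'
#' Runs the detector over annotated signals and assesses inter-rater
#' reliability between the algorithm and the human rater, once against the
#' valid-transition counts and once against the total counts (the two
#' paired comparisons of the original validation design). When a normative
#' table plus subject demographics are supplied, also evaluates the derived
#' three-class functional classifier against the no-information rate:
#' subjects with missing gender or age cannot be classified and are excluded
#' with a warning.
#'
#' @param signals list of [distance_signal()] objects.
#' @param annotations data.frame as from [read_annotations()].
#' @param algorithm `"v1"` or `"v2"`.
#' @param params detector parameters (defaults when `NULL`).
#' @param demographics optional data.frame `subject_id, gender, age`.
#' @param normative optional [normative_table()] (defaults to the shipped
#'   fixture when demographics are given).
#' @param nir no-information rate for the classifier test (default 0.75).
#' @return list with `ratings_valid`, `ratings_total` (n x 2 matrices),
#'   `icc_valid`, `icc_total` ([icc_a1()] results) and, when demographics
#'   are supplied, `classifier` ([classifier_report()]).
#' @export
run_validate <- function(signals, annotations, algorithm = c("v2", "v1"),
                         params = NULL, demographics = NULL,
                         normative = NULL, nir = 0.75) {
  algorithm <- match.arg(algorithm)
  det <- run_detect(signals, algorithm = algorithm, params = params)
  ids <- det$subject_id
  unmatched <- setdiff(ids, annotations$subject_id)
  if (length(unmatched) > 0L) {
    stop(sprintf("subject id(s) without annotation: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  }
  ann <- annotations[match(ids, annotations$subject_id), ]
  ratings_valid <- cbind(manual = ann$valid_count, algorithm = det$count)
  ratings_total <- cbind(manual = ann$total_count, algorithm = det$count)
  out <- list(ratings_valid = ratings_valid, ratings_total = ratings_total,
              icc_valid = icc_a1(ratings_valid),
              icc_total = icc_a1(ratings_total))
  if (!is.null(demographics)) {
    if (is.null(normative)) normative <- default_normative_table()
    demo <- demographics[match(ids, demographics$subject_id), ]
    ok <- !is.na(demo$gender) & !is.na(demo$age)
    if (any(!ok)) {
      warning(sprintf("excluding %d subject(s) with missing gender/age: %s",
                      sum(!ok), paste(ids[!ok], collapse = ", ")),
              call. = FALSE)
    }
    truth <- classify_score(ann$valid_count[ok], demo$gender[ok],
                            demo$age[ok], normative)
    pred <- classify_score(det$count[ok], demo$gender[ok], demo$age[ok],
                           normative)
    out$classifier <- classifier_report(truth, pred, nir = nir)
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Generates a cohort with [generate_cohort()] and writes one signal CSV per
#' subject plus a ground-truth annotation CSV (`annotations.csv`), the
#' on-disk layout the `chairstand` command-line tool consumes.
#'
#' @param outdir output directory (created if needed).
#' @param n_subjects cohort size.
#' @param regime `"young"` or `"older"`.
#' @param seed integer RNG seed.
#' @return invisibly, the annotation data.frame.
#' @export
run_simulate <- function(outdir, n_subjects, regime = c("young", "older"),
                         seed = 1L) {
  regime <- match.arg(regime)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n_subjects, regime, seed)
  ann <- data.frame(
    subject_id = vapply(cohort, function(s) s$signal$subject_id, character(1)),
    valid_count = vapply(cohort, function(s) s$truth$valid_count, integer(1)),
    total_count = vapply(cohort, function(s) s$truth$total_count, integer(1))
  )
  for (s in cohort) {
    write_signal(s$signal, file.path(outdir, paste0(s$signal$subject_id, ".csv")))
  }
  write_annotations(ann, file.path(outdir, "annotations.csv"))
  invisible(ann)
}
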