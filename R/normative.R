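#' Normative score table for the 30-s chair-stand test
#'
#' Gender- and age-banded 25th/75th-percentile score ranges, used to place a
#' test score in one of three functional classes: below average (below the
#' 25th percentile), average (between the 25th and 75th percentiles,
#' inclusive), above average (above the 75th). Expected physical decline
#' with normal aging differs by gender and age, so the same score can be
#' average for an 82-year-old woman and below average for a 63-year-old one.
#'
#' The package ships a *synthetic, user-replaceable* fixture table at
#' `system.file("extdata", "normative_synthetic.csv", package = "chairstand")`
#' consistent with published gender/age patterns; substitute the published
#' normative standards for clinical use.
#'
#' @param entries data.frame with columns `gender` (`"female"`/`"male"`),
#'   `age_low`, `age_high` (years, inclusive), `p25`, `p75` (scores).
#' @return object of class `normative_table`.
#' @export
normative_table <- function(entries) {
  req <- c("gender", "age_low", "age_high", "p25", "p75")
  stopifnot(is.data.frame(entries), all(req %in% names(entries)))
  entries <- entries[req]
  entries$gender <- tolower(as.character(entries$gender))
  if (!all(entries$gender %in% c("female", "male"))) {
    stop("gender must be 'female' or 'male'", call. = FALSE)
  }
  if (any(entries$p25 > entries$p75)) {
    stop("p25 must not exceed p75", call. = FALSE)
  }
  if (any(entries$age_low > entries$age_high)) {
    stop("age_low must not exceed age_high", call. = FALSE)
  }
  for (g in unique(entries$gender)) {
    e <- entries[entries$gender == g, ]
    e <- e[order(e$age_low), ]
    if (nrow(e) > 1L && any(e$age_low[-1] <= e$age_high[-nrow(e)])) {
      stop(sprintf("overlapping age bands for gender '%s'", g), call. = FALSE)
    }
  }
  structure(entries, class = c("normative_table", "data.frame"))
}

#' Read a normative table from CSV
#'
#' @param path CSV with columns `gender,age_low,age_high,p25,p75`.
#' @return a [normative_table()].
#' @export
read_normative_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("normative table not found: '%s'", path), call. = FALSE)
  }
  normative_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

# The shipped synthetic fixture table.
default_normative_table <- function() {
  read_normative_table(system.file("extdata", "normative_synthetic.csv",
                                   package = "chairstand"))
}

#' Classify a chair-stand score against normative percentile ranges
#'
#' `score < p25` is below average, `p25 <= score <= p75` average (boundary
#' scores read "between the percentiles" inclusively), `score > p75` above
#' average. A gender/age combination not covered by the table raises an
#' explicit no-norm-available error rather than guessing.
#'
#' @param score integer test score(s).
#' @param gender `"female"` or `"male"` (recycled to the length of `score`).
#' @param age age(s) in years.
#' @param table a [normative_table()]; defaults to the shipped synthetic
#'   fixture.
#' @return character vector of `"below_average"`, `"average"`,
#'   `"above_average"`.
#' @examples
#' tab <- normative_table(data.frame(
#'   gender = "female", age_low = 80, age_high = 84, p25 = 10, p75 = 15))
#' classify_score(11, "female", 82, tab)
#' @export
classify_score <- function(score, gender, age, table = default_normative_table()) {
  stopifnot(inherits(table, "normative_table"))
  m <- max(length(score), length(gender), length(age))
  score <- rep_len(score, m)
  gender <- rep_len(tolower(as.character(gender)), m)
  age <- rep_len(age, m)
  out <- character(m)
  for (i in seq_len(m)) {
    hit <- which(table$gender == gender[[i]] &
                   table$age_low <= age[[i]] & table$age_high >= age[[i]])
    if (length(hit) == 0L) {
      stop(sprintf("no normative range available for gender '%s', age %s",
                   gender[[i]], format(age[[i]])), call. = FALSE)
    }
    p25 <- table$p25[[hit[[1]]]]; p75 <- table$p75[[hit[[1]]]]
    out[[i]] <- if (score[[i]] < p25) "below_average"
    else if (score[[i]] <= p75) "average"
    else "above_average"
  }
  out
}
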