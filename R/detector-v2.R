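#' Parameters for the moving-minimum detector (algorithm v2)
#'
#' The second-generation detector nulls gross outliers to missing, filters
#' with a moving minimum (erasing any noise spike narrower than the window),
#' thresholds the filtered trace with an adaptive sitting-standing threshold
#' (SST), and counts rising edges of the resulting binary sitting/standing
#' signal after a merge/discard cascade:
#'
#' * standing events closer than `mpd_s` seconds are merged into one peak;
#' * peaks closer than `msbp` samples are merged;
#' * peaks whose height does not exceed `msd` cm are discarded.
#'
#' The SST interpolates between the 4-s moving minimum and the 4-s moving
#' median of the preprocessed signal, weighted by `atw` in \[0, 1\]
#' (0 = minimum, 1 = median). The tuned values used on the original
#' recordings were never published; the defaults (ATW = 0.5, MPD = 1 s,
#' MSBP = 5, MSD = 25 cm) come from re-calibration on synthetic fixtures and
#' are fully configurable.
#'
#' @param atw adaptive threshold weight in \[0, 1\] (default 0.5).
#' @param mpd_s minimum peak distance in seconds (default 1.0).
#' @param msbp minimum samples between peaks, a sample count (default 5).
#' @param msd minimum subject distance in cm (default 25).
#' @param outlier_ceiling samples strictly above this (cm) are set to missing
#'   (default 99).
#' @param minimum_window_s moving-minimum window in seconds (default 0.7).
#' @param sst_window_s window for both SST moving filters in seconds
#'   (default 4).
#' @return object of class `params_v2`.
#' @export
params_v2 <- function(atw = 0.5, mpd_s = 1.0, msbp = 5L, msd = 25,
                      outlier_ceiling = 99, minimum_window_s = 0.7,
                      sst_window_s = 4.0) {
  stopifnot(atw >= 0, atw <= 1, mpd_s > 0, msbp >= 0, msbp == round(msbp),
            msd > 0, outlier_ceiling > 0, minimum_window_s > 0,
            sst_window_s > 0)
  structure(list(atw = atw, mpd_s = mpd_s, msbp = as.integer(msbp), msd = msd,
                 outlier_ceiling = outlier_ceiling,
                 minimum_window_s = minimum_window_s,
                 sst_window_s = sst_window_s),
            class = "params_v2")
}

#' Outlier nulling preprocessing (algorithm v2)
#'
#' Every sample strictly greater than `outlier_ceiling` (default 99 cm) is
#' set to the missing marker `NA`; all other samples pass through. A
#' recording in which every sample is nulled is unusable and raises an error.
#'
#' @param signal a raw finite [distance_signal()].
#' @param params a [params_v2()].
#' @return preprocessed [distance_signal()] (may contain `NA`).
#' @export
preprocess_v2 <- function(signal, params = params_v2()) {
  stopifnot(inherits(signal, "distance_signal"), inherits(params, "params_v2"))
  x <- signal$samples
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  x[!is.na(x) & x > params$outlier_ceiling] <- NA_real_
  if (all(is.na(x))) {
    stop("unusable recording: all samples above the outlier ceiling",
         call. = FALSE)
  }
  distance_signal(x, rate_hz = signal$rate_hz, subject_id = signal$subject_id)
}

#' Adaptive sitting-standing threshold (SST)
#'
#' `SST[i] = movmin[i] + atw * (movmed[i] - movmin[i])`, where both moving
#' filters use the `sst_window_s` window (default 4 s) on the preprocessed
#' signal. For `atw` in \[0, 1\] the SST always lies between the moving
#' minimum and the moving median; `atw = 0` reproduces the minimum and
#' `atw = 1` the median. All-missing windows propagate `NA`.
#'
#' @param x numeric vector, the preprocessed samples.
#' @param params a [params_v2()].
#' @param rate_hz sampling rate in Hz.
#' @return numeric vector of threshold values, same length as `x`.
#' @export
compute_sst <- function(x, params = params_v2(), rate_hz = 10) {
  stopifnot(inherits(params, "params_v2"))
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  mmin <- moving_minimum(x, params$sst_window_s, rate_hz)
  mmed <- moving_median(x, params$sst_window_s, rate_hz)
  mmin + params$atw * (mmed - mmin)
}

#' Rising edges of a binary sitting/standing signal
#'
#' Stand-up moments are the 0-to-1 transitions of the binary signal; a
#' leading 1 at the first sample is not an edge (the subject starts the test
#' seated, and an initial standing state carries no stand-up event). Missing
#' values are treated as 0 (sitting).
#'
#' @param binary vector of 0/1 values (`NA` allowed, read as 0).
#' @return integer vector of 0-based sample indices `i` with
#'   `binary[i-1] == 0` and `binary[i] == 1`.
#' @examples
#' rising_edges(c(0, 0, 1, 1, 0, 1))  # 2, 5
#' @export
rising_edges <- function(binary) {
  b <- as.integer(!is.na(binary) & binary == 1)
  n <- length(b)
  if (n < 2L) return(integer(0))
  which(b[-1L] == 1L & b[-n] == 0L)   # 1-based i-1 == 0-based i
}

#' Detect sit-to-stand transitions with the moving-minimum algorithm (v2)
#'
#' Pipeline: [preprocess_v2()] (outliers to `NA`), [moving_minimum()] with a
#' 0.7-s window, [compute_sst()] on the preprocessed samples, binary signal
#' `filtered > SST` (missing compares as sitting), [rising_edges()], then the
#' merge/discard cascade in the order MPD merge, MSBP merge, MSD discard. A
#' merged peak's extent is the union of the contiguous above-threshold runs
#' containing its member edges; its height is the maximum filtered value over
#' that extent and its index the position of that maximum.
#'
#' @param signal a [distance_signal()] at least one SST window long.
#' @param params a [params_v2()].
#' @return a [detection_result()].
#' @examples
#' spec <- synthetic_spec(n_cycles = 8, period_s = 3.5, noise_sd_cm = 0, seed = 1)
#' sim <- generate_signal(spec)
#' detect_v2(sim$signal)$count
#' @export
detect_v2 <- function(signal, params = params_v2()) {
  stopifnot(inherits(signal, "distance_signal"), inherits(params, "params_v2"))
  rate <- signal$rate_hz
  w <- window_samples(params$sst_window_s, rate)
  if (length(signal$samples) < w) {
    stop(sprintf("signal shorter (%d samples) than the SST window (%d)",
                 length(signal$samples), w), call. = FALSE)
  }
  pre <- preprocess_v2(signal, params)
  filt <- moving_minimum(pre$samples, params$minimum_window_s, rate)
  sst <- compute_sst(pre$samples, params, rate)
  binary <- as.integer(!is.na(filt) & !is.na(sst) & filt > sst)
  edges0 <- rising_edges(binary)               # 0-based
  if (length(edges0) == 0L) {
    return(detection_result(algorithm = "v2"))
  }
  edges <- edges0 + 1L                         # 1-based internal

  # MPD merge: standing events closer than mpd_s seconds become one peak.
  mpd_samples <- params$mpd_s * rate
  grp <- cumsum(c(1L, as.integer(diff(edges) >= mpd_samples)))
  groups <- split(edges, grp)

  # MSBP merge: peaks closer than msbp samples (gap between the last member
  # of one group and the first of the next) are merged again.
  if (length(groups) > 1L) {
    firsts <- vapply(groups, `[[`, integer(1), 1L)
    lasts <- vapply(groups, function(g) g[[length(g)]], integer(1))
    gap <- firsts[-1L] - lasts[-length(lasts)]
    grp2 <- cumsum(c(1L, as.integer(gap >= params$msbp)))
    groups <- lapply(split(seq_along(groups), grp2),
                     function(js) unlist(groups[js], use.names = FALSE))
  }

  # Peak extent, height, index; then MSD discard (keep height > msd).
  runs <- binary_runs(binary)
  idx <- integer(0); height <- numeric(0)
  for (g in groups) {
    ext <- sort(unique(unlist(lapply(g, function(e) run_members(runs, e)))))
    if (length(ext) == 0L) ext <- g
    h <- filt[ext]
    j <- ext[[which.max(h)]]
    if (filt[[j]] > params$msd) {
      idx <- c(idx, j)
      height <- c(height, filt[[j]])
    }
  }
  o <- order(idx)
  detection_result(index = idx[o] - 1L, time_s = (idx[o] - 1L) / rate,
                   height_cm = height[o], algorithm = "v2")
}

# Contiguous runs of 1s in a binary vector: data.frame(start, end), 1-based.
binary_runs <- function(binary) {
  r <- rle(binary)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep])
}

# Samples of the run containing 1-based index e (empty if none).
run_members <- function(runs, e) {
  hit <- which(runs$start <= e & runs$end >= e)
  if (length(hit) == 0L) return(integer(0))
  seq.int(runs$start[[hit[[1]]]], runs$end[[hit[[1]]]])
}
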