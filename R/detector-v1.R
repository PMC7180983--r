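#' Parameters for the moving-median detector (algorithm v1)
#'
#' The first-generation detector resets gross outliers, smooths with a
#' moving median, and counts local maxima after two data-driven checks:
#' maxima separated by less than the peak distance threshold
#' `PDT = DF * median inter-maximum gap` are merged into one peak, and only
#' peaks strictly higher than the peak height threshold `PHT` count as
#' transitions.
#'
#' The tuned DF/PHT used on the original recordings were never published;
#' the defaults here (DF = 0.5, PHT = 30 cm) come from re-calibration on
#' synthetic fixtures (see [calibrate()]) and are fully configurable.
#'
#' @param df distance factor, dimensionless multiplier on the median
#'   inter-maximum gap (default 0.5).
#' @param pht peak height threshold in cm (default 30).
#' @param outlier_ceiling samples strictly above this (cm) are treated as
#'   outliers (default 70, well above any upright-position distance).
#' @param outlier_reset replacement value for outliers (cm, default 15, a
#'   typical sitting distance).
#' @param median_window_s moving-median window in seconds (default 0.7).
#' @return object of class `params_v1`.
#' @export
params_v1 <- function(df = 0.5, pht = 30, outlier_ceiling = 70,
                      outlier_reset = 15, median_window_s = 0.7) {
  stopifnot(df > 0, pht > 0, outlier_ceiling > outlier_reset,
            outlier_reset > 0, median_window_s > 0)
  structure(list(df = df, pht = pht, outlier_ceiling = outlier_ceiling,
                 outlier_reset = outlier_reset,
                 median_window_s = median_window_s),
            class = "params_v1")
}

#' Outlier reset preprocessing (algorithm v1)
#'
#' Every sample strictly greater than `outlier_ceiling` (default 70 cm) is
#' replaced by `outlier_reset` (default 15 cm, an estimate of the usual
#' sitting distance); all other samples pass through unchanged.
#'
#' @param signal a raw finite [distance_signal()].
#' @param params a [params_v1()].
#' @return preprocessed [distance_signal()].
#' @export
preprocess_v1 <- function(signal, params = params_v1()) {
  stopifnot(inherits(signal, "distance_signal"), inherits(params, "params_v1"))
  x <- signal$samples
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  x[!is.na(x) & x > params$outlier_ceiling] <- params$outlier_reset
  distance_signal(x, rate_hz = signal$rate_hz, subject_id = signal$subject_id)
}

#' Detect sit-to-stand transitions with the moving-median algorithm (v1)
#'
#' Pipeline: [preprocess_v1()], [moving_median()] (0.7-s window), strict
#' local maxima of the filtered trace, merging of maxima whose gap is below
#' `PDT = DF * median(inter-maximum gaps)` into single peaks (peak = highest
#' member, earliest index on ties), and finally validation `height > PHT`.
#' With fewer than two local maxima the gap median is undefined and no
#' merging is applied.
#'
#' @param signal a [distance_signal()] at least one filter window long.
#' @param params a [params_v1()].
#' @return a [detection_result()].
#' @examples
#' spec <- synthetic_spec(n_cycles = 5, period_s = 5, noise_sd_cm = 0, seed = 1)
#' sim <- generate_signal(spec)
#' detect_v1(sim$signal)$count
#' @export
detect_v1 <- function(signal, params = params_v1()) {
  stopifnot(inherits(signal, "distance_signal"), inherits(params, "params_v1"))
  w <- window_samples(params$median_window_s, signal$rate_hz)
  if (length(signal$samples) < w) {
    stop(sprintf("signal shorter (%d samples) than the filter window (%d)",
                 length(signal$samples), w), call. = FALSE)
  }
  pre <- preprocess_v1(signal, params)
  filt <- moving_median(pre$samples, params$median_window_s, signal$rate_hz)
  maxima <- local_maxima(filt)
  if (length(maxima) == 0L) {
    return(detection_result(algorithm = "v1"))
  }
  if (length(maxima) >= 2L) {
    gaps <- diff(maxima)
    pdt <- stats::median(gaps) * params$df
    grp <- cumsum(c(1L, as.integer(gaps >= pdt)))
  } else {
    grp <- 1L
  }
  idx <- integer(0); height <- numeric(0)
  for (g in split(maxima, grp)) {
    h <- filt[g]
    j <- g[[which.max(h)]]            # earliest member on ties
    idx <- c(idx, j)
    height <- c(height, filt[[j]])
  }
  keep <- height > params$pht
  idx <- idx[keep]; height <- height[keep]
  o <- order(idx)
  detection_result(index = idx[o] - 1L,
                   time_s = (idx[o] - 1L) / signal$rate_hz,
                   height_cm = height[o], algorithm = "v1")
}
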