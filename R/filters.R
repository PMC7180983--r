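#' @title NA-aware centered moving-window filters
#' @description Both detection algorithms rest on sliding-window order
#'   statistics of the distance trace: a moving median (robust smoother that
#'   rejects isolated spikes) and a moving minimum (tracks the envelope of
#'   local minima, erasing any spike narrower than the window). Windows are
#'   centered and shrink at the signal edges, which avoids the phase lag a
#'   trailing window would introduce into transition times. Missing values
#'   (`NA`/`NaN`) are ignored within each window; a window with no finite
#'   member yields `NA`.
#' @name moving_filters
NULL

# Window length in samples: round(window_s * rate_hz), promoted to the next
# odd integer so the window has a symmetric center (0.7 s at 10 Hz -> 7).
window_samples <- function(window_s, rate_hz) {
  if (window_s <= 0 || rate_hz <= 0) {
    stop("window_s and rate_hz must be positive", call. = FALSE)
  }
  w <- round(window_s * rate_hz)
  if (w < 1) {
    stop("window shorter than one sample (window_s * rate_hz < 1)",
         call. = FALSE)
  }
  if (w %% 2 == 0) w <- w + 1
  as.integer(w)
}

moving_stat <- function(x, window_s, rate_hz, stat) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) stop("empty input signal", call. = FALSE)
  w <- window_samples(window_s, rate_hz)
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  ok <- !is.na(x) & !is.nan(x)
  for (i in seq_len(n)) {
    a <- max(1L, i - half)
    b <- min(n, i + half)
    v <- x[a:b][ok[a:b]]
    out[[i]] <- if (length(v) == 0L) NA_real_ else stat(v)
  }
  out
}

#' Moving median filter
#'
#' Centered moving median with window length `round(window_s * rate_hz)`
#' samples, promoted by one sample if even; at the edges the window shrinks
#' to the available samples. The median of an even number of finite window
#' members is the mean of the two central values.
#'
#' @param x numeric vector (may contain `NA` missing markers).
#' @param window_s window length in seconds (default 0.7).
#' @param rate_hz sampling rate in Hz (default 10).
#' @return numeric vector, same length as `x`.
#' @seealso [moving_minimum()]
#' @export
moving_median <- function(x, window_s = 0.7, rate_hz = 10) {
  moving_stat(x, window_s, rate_hz, stats::median)
}

#' Moving minimum filter
#'
#' Centered moving minimum; window sizing and edge behaviour as in
#' [moving_median()]. Wherever `x[i]` is finite, `output[i] <= x[i]`, and any
#' spike narrower than the window is erased entirely -- the property the
#' second detection algorithm exploits to cope with clustered noise spikes.
#'
#' @inheritParams moving_median
#' @return numeric vector, same length as `x`; `NA` where a window holds no
#'   finite value.
#' @export
moving_minimum <- function(x, window_s = 0.7, rate_hz = 10) {
  moving_stat(x, window_s, rate_hz, min)
}

# Strict local maxima with plateau handling: a run of equal values is a
# single maximum (reported at its first index) when the adjacent distinct
# values on BOTH sides are lower; signal endpoints never qualify.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  x <- ifelse(is.na(x), -Inf, x)
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  idx <- integer(0)
  for (j in 2:(k - 1L)) {
    if (r$values[[j]] > r$values[[j - 1L]] &&
        r$values[[j]] > r$values[[j + 1L]]) {
      idx <- c(idx, starts[[j]])
    }
  }
  idx
}
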