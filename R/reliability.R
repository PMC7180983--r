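#' Intraclass correlation ICC(A,1): single-rater, absolute-agreement, two-way
#'
#' Treats device scoring as an inter-rater reliability problem: each subject
#' is scored by two raters (manual count and algorithm), and agreement is
#' quantified with the two-way, absolute-agreement, single-rater intraclass
#' correlation (McGraw-Wong ICC(A,1)). From the two-way ANOVA mean squares
#' (rows = subjects, columns = raters):
#'
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#'
#' The significance test of ICC > 0 uses `F = MS_R / MS_E` on
#' `(n-1, (n-1)(k-1))` degrees of freedom; the 95% confidence interval uses
#' the McGraw-Wong F bounds with Satterthwaite degrees of freedom. Absolute
#' agreement (unlike consistency) penalizes a constant shift between raters,
#' which is the property that makes it the right yardstick for a scoring
#' device.
#'
#' Reliability bands follow the Koo-Li cutpoints: ICC < 0.5 poor,
#' \[0.5, 0.75) moderate, \[0.75, 0.9) good, >= 0.9 excellent. Besides the
#' point-estimate band, a conservative "supported" band is derived from the
#' lower confidence bound (the reliability level the data can actually
#' ensure).
#'
#' @param ratings n x 2 numeric matrix or data.frame: one row per subject,
#'   columns rater 1 (manual) and rater 2 (algorithm).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `f_stat`, `df1`, `df2`, `p_value`, `band`, `supported_band`, `n`, `k`.
#' @examples
#' m <- cbind(manual = c(10, 12, 14, 9, 11, 13),
#'            algo   = c(10, 13, 14, 9, 12, 13))
#' icc_a1(m)
#' @export
icc_a1 <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (any(is.na(x))) stop("ratings must have no missing cells", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (k != 2L) stop("expected exactly 2 raters (columns)", call. = FALSE)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)

  gm <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (sst == 0) {
    stop("undefined ICC: zero total variance (all scores identical)",
         call. = FALSE)
  }

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  f_stat <- msr / mse
  p_value <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  if (mse == 0 && msr > 0) {
    # Perfect within-subject agreement: the interval degenerates at 1.
    ci_low <- ci_high <- 1
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
    fu <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
    ci_low <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }

  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 f_stat = f_stat, df1 = df1, df2 = df2, p_value = p_value,
                 band = icc_band(icc), supported_band = icc_band(ci_low),
                 n = n, k = k, conf_level = conf_level),
            class = "icc_result")
}

#' Koo-Li reliability band for an ICC value
#'
#' Cutpoints: below 0.5 poor, 0.5 to below 0.75 moderate, 0.75 to below 0.9
#' good, 0.9 and above excellent (left-closed intervals, so 0.5 is moderate
#' and 0.86 is good).
#'
#' @param icc numeric vector of ICC values.
#' @return character vector of band labels.
#' @examples
#' icc_band(c(0.96, 0.86, 0.50, 0.3))
#' @export
icc_band <- function(icc) {
  stopifnot(is.numeric(icc))
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      right = FALSE) |> as.character()
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f, %d%% CI [%.3f, %.3f] (n = %d subjects)\n",
              x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n))
  cat(sprintf("  F(%d, %.1f) = %.2f, p = %.4g\n", x$df1, x$df2, x$f_stat,
              x$p_value))
  cat(sprintf("  reliability: %s (point), %s (supported by lower CI bound)\n",
              x$band, x$supported_band))
  invisible(x)
}

#' Classifier performance against a no-information rate
#'
#' Evaluates a 3-class functional-status classifier against the accuracy of
#' always predicting the most common class (the no-information rate, NIR).
#' Reports overall accuracy with an exact Clopper-Pearson 95% interval, a
#' one-sided exact binomial test of accuracy > NIR, Cohen's arcsine effect
#' size `h = 2 asin(sqrt(acc)) - 2 asin(sqrt(nir))`, and the power of the
#' one-sample proportion test for this `h` and `n` at `alpha` (normal
#' approximation on the arcsine scale).
#'
#' @param true_classes vector of reference class labels.
#' @param predicted_classes vector of predicted labels, same length.
#' @param nir no-information rate, a proportion strictly inside (0, 1).
#' @param alpha significance level for the power computation (default 0.05).
#' @return object of class `classifier_report`: `accuracy`, `ci_low`,
#'   `ci_high`, `nir`, `p_vs_nir`, `effect_size_h`, `power`, `n_correct`, `n`.
#' @export
classifier_report <- function(true_classes, predicted_classes, nir,
                              alpha = 0.05) {
  if (length(true_classes) != length(predicted_classes)) {
    stop("true and predicted class vectors differ in length", call. = FALSE)
  }
  n <- length(true_classes)
  if (n == 0L) stop("empty class vectors", call. = FALSE)
  if (!is.numeric(nir) || length(nir) != 1L || nir <= 0 || nir >= 1) {
    stop("`nir` must be a single proportion in (0, 1)", call. = FALSE)
  }
  x <- sum(as.character(true_classes) == as.character(predicted_classes))
  acc <- x / n
  ci <- stats::binom.test(x, n)$conf.int
  p <- stats::binom.test(x, n, p = nir, alternative = "greater")$p.value
  h <- 2 * asin(sqrt(acc)) - 2 * asin(sqrt(nir))
  power <- stats::pnorm(sqrt(n) * h - stats::qnorm(1 - alpha))
  structure(list(accuracy = acc, ci_low = ci[[1]], ci_high = ci[[2]],
                 nir = nir, p_vs_nir = p, effect_size_h = h, power = power,
                 n_correct = x, n = n, alpha = alpha),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("accuracy %d/%d = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$n_correct, x$n, x$accuracy, x$ci_low, x$ci_high))
  cat(sprintf("  one-sided exact binomial vs NIR = %.2f: p = %.4g\n",
              x$nir, x$p_vs_nir))
  cat(sprintf("  effect size h = %.3f, power = %.3f at alpha = %.2f\n",
              x$effect_size_h, x$power, x$alpha))
  invisible(x)
}
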