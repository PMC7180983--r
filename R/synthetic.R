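#' Specification for a synthetic chair-stand test signal
#'
#' The original study's recordings were never deposited, so the package
#' ships a generator that emulates their observed statistical structure:
#' quasi-periodic trapezoidal sit-stand-sit cycles (the distance dwells at
#' the sitting baseline and the standing plateau, as a torso-to-backrest
#' distance does), Gaussian sensor noise, a burst-Poisson spike process whose
#' heights straddle the 99-cm outlier ceiling so both preprocessing branches
#' are exercised, occasional invalid (non-upright) attempts, and an optional
#' elevated sitting baseline for subjects who do not lean back after sitting.
#'
#' Each cycle occupies `period_s` seconds starting at a 1-s lead-in: a ramp
#' of `rise_s` up to the standing plateau, a plateau until `period_s / 2`, a
#' ramp down, then sitting dwell. Cycles must fit in the recording and may
#' not overlap (`period_s >= 2 * rise_s`).
#'
#' @param n_cycles number of sit-stand-sit cycles.
#' @param period_s cycle period in seconds.
#' @param rise_s duration of each stand-up/sit-down ramp in seconds.
#' @param sit_cm sitting-baseline distance in cm (default 15).
#' @param stand_cm standing-plateau distance in cm (default 50).
#' @param baseline_cm extra cm added to the sitting baseline for
#'   no-lean-back segments (default 0; values > 15 push filtered minima
#'   above 30 cm, the regime where the moving-minimum detector degrades).
#' @param noise_sd_cm Gaussian noise standard deviation in cm (default 0).
#' @param spike_rate_per_s rate of spike-burst onsets per second (default 0).
#' @param spike_cluster_size mean burst size in samples (default 1 =
#'   isolated spikes; larger values give the clustered bursts typical of
#'   older-subject recordings).
#' @param spike_height_cm length-2 range (cm) spike heights are drawn from.
#' @param invalid_rate per-cycle probability of an invalid (non-upright)
#'   attempt (default 0).
#' @param invalid_height_cm peak distance reached by invalid attempts
#'   (default 35 cm, below a full upright posture).
#' @param duration_s recording length in seconds (default 30).
#' @param rate_hz sampling rate in Hz (default 10).
#' @param seed integer RNG seed; identical specs give bit-identical signals.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cycles = 8, period_s = 3.5, rise_s = 1.0,
                           sit_cm = 15, stand_cm = 50, baseline_cm = 0,
                           noise_sd_cm = 0, spike_rate_per_s = 0,
                           spike_cluster_size = 1,
                           spike_height_cm = c(60, 150),
                           invalid_rate = 0, invalid_height_cm = 35,
                           duration_s = 30, rate_hz = 10, seed = 1L) {
  if (period_s < 2 * rise_s) {
    stop("overlapping cycles: period_s must be >= 2 * rise_s", call. = FALSE)
  }
  stopifnot(n_cycles >= 1, sit_cm >= 0, sit_cm < stand_cm, baseline_cm >= 0,
            noise_sd_cm >= 0, spike_rate_per_s >= 0, spike_cluster_size >= 1,
            length(spike_height_cm) == 2, invalid_rate >= 0, invalid_rate <= 1,
            invalid_height_cm > sit_cm, duration_s > 0, rate_hz > 0)
  lead_in <- 1.0
  if (lead_in + n_cycles * period_s > duration_s) {
    stop(sprintf("%d cycles of %.2f s do not fit in %.0f s", n_cycles,
                 period_s, duration_s), call. = FALSE)
  }
  structure(list(n_cycles = as.integer(n_cycles), period_s = period_s,
                 rise_s = rise_s, sit_cm = sit_cm, stand_cm = stand_cm,
                 baseline_cm = baseline_cm, noise_sd_cm = noise_sd_cm,
                 spike_rate_per_s = spike_rate_per_s,
                 spike_cluster_size = spike_cluster_size,
                 spike_height_cm = sort(as.numeric(spike_height_cm)),
                 invalid_rate = invalid_rate,
                 invalid_height_cm = invalid_height_cm,
                 duration_s = duration_s, rate_hz = rate_hz,
                 lead_in_s = lead_in, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Run fn() under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic distance signal with exact ground truth
#'
#' Builds the deterministic trapezoidal cycle train described in
#' [synthetic_spec()], then adds Gaussian noise, overwrites spike-burst
#' samples (burst onsets from a Poisson process, geometric burst sizes,
#' heights uniform over `spike_height_cm`), and truncates a random
#' `invalid_rate` fraction of cycles at `invalid_height_cm`. Ground truth
#' records every cycle onset and its validity, so detector tests compare
#' against construction, never against eyeballed values.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `signal` (a [distance_signal()]) and `truth` (list with
#'   `valid_times_s`, `invalid_times_s`, `valid_count`, `total_count`).
#' @export
generate_signal <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, function() generate_signal_impl(spec))
}

generate_signal_impl <- function(spec) {
  n <- round(spec$duration_s * spec$rate_hz)
  t <- (seq_len(n) - 1) / spec$rate_hz
  sit <- spec$sit_cm + spec$baseline_cm
  x <- rep(sit, n)

  onsets <- spec$lead_in_s + (seq_len(spec$n_cycles) - 1) * spec$period_s
  invalid <- stats::runif(spec$n_cycles) < spec$invalid_rate
  # An invalid attempt stops short of upright: at the configured height, or
  # halfway between the subject's own sitting level and upright when an
  # elevated baseline would otherwise sit above it.
  invalid_peak <- max(spec$invalid_height_cm, (sit + spec$stand_cm) / 2)
  for (c in seq_len(spec$n_cycles)) {
    peak <- if (invalid[[c]]) invalid_peak else spec$stand_cm
    tc <- t - onsets[[c]]
    up <- tc >= 0 & tc < spec$rise_s
    plateau <- tc >= spec$rise_s & tc < spec$period_s / 2
    down <- tc >= spec$period_s / 2 & tc < spec$period_s / 2 + spec$rise_s
    x[up] <- pmin(peak, sit + (peak - sit) * tc[up] / spec$rise_s)
    x[plateau] <- peak
    x[down] <- pmax(sit, peak - (peak - sit) *
                      (tc[down] - spec$period_s / 2) / spec$rise_s)
  }

  if (spec$noise_sd_cm > 0) {
    x <- pmax(0, x + stats::rnorm(n, 0, spec$noise_sd_cm))
  }

  if (spec$spike_rate_per_s > 0) {
    # Burst-Poisson spike process: burst onsets at spike_rate_per_s, burst
    # sizes geometric with the configured mean, capped at 6 samples (0.6 s at
    # 10 Hz) -- artifacts are narrow "spikes", always narrower than the 0.7-s
    # filter window. One reflection event has one apparent distance, so all
    # samples of a burst share a single height.
    n_bursts <- stats::rpois(1, spec$spike_rate_per_s * spec$duration_s)
    if (n_bursts > 0) {
      starts <- sort(sample.int(n, n_bursts, replace = TRUE))
      # Dead time: physical artifacts (momentary chair motion, passing limbs)
      # do not overlap; enforce a 1-s refractory gap between burst onsets so
      # two bursts never fuse into one artifact wider than the filter window.
      keep <- !logical(length(starts))
      last <- -Inf
      for (b in seq_along(starts)) {
        if (starts[[b]] - last < round(spec$rate_hz)) keep[[b]] <- FALSE
        else last <- starts[[b]]
      }
      starts <- starts[keep]
      n_bursts <- length(starts)
      sizes <- 1L + pmin(stats::rgeom(n_bursts, 1 / spec$spike_cluster_size), 5L)
      heights <- stats::runif(n_bursts, spec$spike_height_cm[[1]],
                              spec$spike_height_cm[[2]])
      for (b in seq_len(n_bursts)) {
        members <- starts[[b]] + 0:(sizes[[b]] - 1L)
        members <- members[members <= n]
        x[members] <- heights[[b]]
      }
    }
  }

  truth <- list(valid_times_s = onsets[!invalid],
                invalid_times_s = onsets[invalid],
                valid_count = sum(!invalid),
                total_count = spec$n_cycles)
  list(signal = distance_signal(x, rate_hz = spec$rate_hz,
                                subject_id = sprintf("synthetic-seed%d", spec$seed)),
       truth = truth)
}

#' Generate a synthetic cohort in the young or older noise regime
#'
#' Per-subject specs are drawn from regime-specific distributions mirroring
#' the two study groups:
#'
#' * `young` (laboratory, healthy subjects): fast cadence, low noise,
#'   sparse isolated narrow spikes, clean 15-cm sitting baseline.
#' * `older` (pre-clinical, older adults): slower cadence and fewer cycles,
#'   higher noise, abundant clustered spike bursts, ~3% invalid attempts,
#'   and an elevated no-lean-back sitting baseline (filtered minima above
#'   30 cm) for about a quarter of subjects.
#'
#' Per-subject seeds are derived from `seed` by counter, so a cohort is
#' reproducible as a whole and subject-by-subject.
#'
#' @param n_subjects number of subjects (study groups were 25 young and
#'   30 older).
#' @param regime `"young"` or `"older"`.
#' @param seed integer RNG seed.
#' @return list of `n_subjects` elements, each a list with `signal`,
#'   `truth` and `spec`.
#' @export
generate_cohort <- function(n_subjects, regime = c("young", "older"),
                            seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_subjects >= 1)
  draws <- with_seed(seed, function() {
    lapply(seq_len(n_subjects), function(i) draw_subject_spec(regime, i))
  })
  lapply(seq_len(n_subjects), function(i) {
    sp <- draws[[i]]
    sp$seed <- (abs(seed) %% 1000000L) * 1000L + i
    spec <- do.call(synthetic_spec, sp)
    out <- generate_signal(spec)
    out$signal$subject_id <- sprintf("%s-%02d", regime, i)
    out$spec <- spec
    out
  })
}

draw_subject_spec <- function(regime, i) {
  if (regime == "young") {
    period <- stats::runif(1, 1.8, 2.6)
    rise <- stats::runif(1, 0.6, 0.85)
    sp <- list(period_s = period, rise_s = rise,
               noise_sd_cm = 0.5, spike_rate_per_s = 0.05,
               spike_cluster_size = 1, spike_height_cm = c(60, 150),
               invalid_rate = 0.01, baseline_cm = 0)
  } else {
    period <- stats::runif(1, 2.2, 3.4)
    rise <- stats::runif(1, 0.7, 1.0)
    elevated <- stats::runif(1) < 0.25
    sp <- list(period_s = period, rise_s = rise,
               noise_sd_cm = 1.0, spike_rate_per_s = 0.5,
               spike_cluster_size = 4, spike_height_cm = c(40, 110),
               invalid_rate = 0.033,
               baseline_cm = if (elevated) stats::runif(1, 17, 30) else 0)
  }
  sp$n_cycles <- max(3L, floor((30 - 1.0) / period))
  sp
}
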