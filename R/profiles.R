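#' Default class-conditional cardiac parameters
#'
#' Per-activity generative parameters for the RR-interval simulator: the
#' population mean RR interval (s), the between-subject SD of that mean (s),
#' the within-window white jitter SD (s), and the amplitudes (s) of the
#' low-frequency (default 0.095 Hz) and high-frequency (default 0.25 Hz)
#' sinusoidal modulations.  The SI/ST/WK/AS means and dispersions follow the
#' class-conditional window statistics of the laboratory protocol the
#' generator emulates (mean RR 0.86/0.77/0.61/0.47 s, SD 0.12/0.10/0.08/0.07 s).
#' RU and REST have no reported statistics: RU is extrapolated to 0.40 s
#' (continuing the WK > AS ordering) and REST is placed midway between SI and
#' WK (0.735 s), reflecting seated posture with an elevated post-exercise rate.
#'
#' @return A data.frame keyed by `activity`.
#' @export
default_cardiac_params <- function() {
  data.frame(
    activity   = c("SI", "ST", "WK", "AS", "RU", "REST"),
    mean_rr    = c(0.86, 0.77, 0.61, 0.47, 0.40, 0.735),
    sd_between = c(0.12, 0.10, 0.08, 0.07, 0.06, 0.10),
    jitter_sd  = c(0.035, 0.030, 0.020, 0.012, 0.010, 0.030),
    lf_amp     = c(0.030, 0.025, 0.015, 0.008, 0.006, 0.020),
    hf_amp     = c(0.020, 0.015, 0.008, 0.005, 0.004, 0.012),
    stringsAsFactors = FALSE
  )
}

#' Default class-conditional accelerometer parameters
#'
#' Wrist-accelerometer generative parameters per activity: dominant gait
#' frequency (Hz), oscillation amplitude (g) and white-noise SD (g).  Static
#' activities are gravity plus low-amplitude noise (amplitude 0); dynamic
#' amplitudes increase WK < AS < RU so windowed RMS separates the categories
#' while WK/AS remain close (the overlap the recognition experiments probe).
#'
#' @return A data.frame keyed by `activity`.
#' @export
default_accel_params <- function() {
  data.frame(
    activity  = c("SI", "ST", "WK", "AS", "RU", "REST"),
    gait_freq = c(0, 0, 1.8, 2.0, 2.5, 0),
    amp_g     = c(0, 0, 0.60, 0.72, 1.40, 0),
    noise_sd  = c(0.020, 0.028, 0.08, 0.09, 0.12, 0.020),
    stringsAsFactors = FALSE
  )
}

#' Draw a cohort of subject profiles
#'
#' Each subject gets anthropometrics drawn uniformly from plausible adult
#' ranges (height 150-190 cm, weight 45-95 kg) and per-activity cardiac and
#' accelerometer parameters: the subject's mean RR per activity is drawn from
#' the class-conditional normal (truncated to (0.3, 2.0) s), gait frequency
#' and amplitude get small subject-level perturbations.
#'
#' @param n_subjects number of subjects (default 13).
#' @param cardiac,accel parameter tables as returned by
#'   [default_cardiac_params()] / [default_accel_params()].
#' @param seed integer RNG seed.
#' @return List of `subject_profile` lists.
#' @export
subject_profiles <- function(n_subjects = 13L,
                             cardiac = default_cardiac_params(),
                             accel = default_accel_params(),
                             seed = 1L) {
  stopifnot(n_subjects >= 1)
  rng <- local_rng(seed)
  lapply(seq_len(n_subjects), function(i) {
    card <- cardiac
    card$mean_rr <- pmin(2.0 - 1e-3, pmax(0.3 + 1e-3,
      stats::rnorm(nrow(card), card$mean_rr, card$sd_between)))
    # preserve the configured activity ordering of mean RR within a subject:
    # a subject whose AS heart rate is slower than WK would be atypical
    ord <- order(cardiac$mean_rr)
    card$mean_rr[ord] <- sort(card$mean_rr[ord])
    acc <- accel
    dyn <- acc$amp_g > 0
    acc$gait_freq[dyn] <- acc$gait_freq[dyn] * stats::runif(sum(dyn), 0.9, 1.1)
    acc$amp_g[dyn] <- acc$amp_g[dyn] * stats::runif(sum(dyn), 0.9, 1.1)
    structure(list(
      subject_id = sprintf("S%02d", i),
      height = stats::runif(1, 150, 190),
      weight = stats::runif(1, 45, 95),
      cardiac = card,
      accel = acc
    ), class = "subject_profile")
  })
}

cardiac_row <- function(profile, activity) {
  check_activity(activity)
  row <- profile$cardiac[profile$cardiac$activity == activity, ]
  if (nrow(row) != 1L)
    stop("no cardiac parameters configured for activity ", activity, call. = FALSE)
  row
}

accel_row <- function(profile, activity) {
  check_activity(activity)
  row <- profile$accel[profile$accel$activity == activity, ]
  if (nrow(row) != 1L)
    stop("no accelerometer parameters configured for activity ", activity, call. = FALSE)
  row
}
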