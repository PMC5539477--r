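#' Generative energy-expenditure model
#'
#' The ground-truth kcal/min of every simulated minute is an affine
#' function of that minute's true generative features plus homoscedastic
#' Gaussian noise, with separate coefficient sets for static (SI/ST/REST)
#' and dynamic (WK/AS/RU) minutes — mirroring the activity-specific model
#' family the analysis fits.  Defaults give plausible adult values
#' (~1 kcal/min seated, 4-8 kcal/min running) and make EE depend on mean
#' heart rate in both categories, so HRV-aware regressions genuinely have
#' signal to find.
#'
#' Feature names available to the coefficients: `height` (cm), `weight`
#' (kg), `rms`, `sd`, `f_dominant`, `energy` (IMU), and any of the 31 HRV
#' names (`mHR` in 1/min, `mRR` in ms, ...).
#'
#' @param static,dynamic named coefficient vectors; `(Intercept)` required.
#' @param noise_sd Gaussian noise SD (kcal/min).
#' @return List of class `ee_model`.
#' @export
default_ee_model <- function(
    static = c(`(Intercept)` = 0.5, height = -0.004, weight = 0.012, mHR = 0.020),
    dynamic = c(`(Intercept)` = -2.0, weight = 0.015, rms = 2.2,
                f_dominant = 0.30, mHR = 0.025),
    noise_sd = 0.25) {
  stopifnot("(Intercept)" %in% names(static), "(Intercept)" %in% names(dynamic),
            noise_sd >= 0)
  structure(list(static = static, dynamic = dynamic, noise_sd = noise_sd),
            class = "ee_model")
}

ee_linear_predictor <- function(model, category, features) {
  beta <- model[[category]]
  vars <- setdiff(names(beta), "(Intercept)")
  missing <- setdiff(vars, names(features))
  if (length(missing))
    stop("ee model references unknown features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  unname(beta[["(Intercept)"]] + sum(beta[vars] * unlist(features)[vars]))
}

# true per-minute generative features for one (subject, activity) pair:
# what the sensors would measure with no noise, used as EE ground truth
true_minute_features <- function(profile, activity) {
  card <- cardiac_row(profile, activity)
  acc <- accel_row(profile, activity)
  # RMS of the mean-removed magnitude of the configured oscillation:
  # fundamental (az) + second harmonic (az) + horizontal component (ax)
  rms_true <- if (acc$amp_g > 0)
    sqrt((acc$amp_g^2 + (0.2 * acc$amp_g)^2 + (0.3 * acc$amp_g)^2) / 2) else 0
  c(height = profile$height, weight = profile$weight,
    rms = rms_true, sd = rms_true, f_dominant = acc$gait_freq,
    energy = rms_true^2 * 256,
    mRR = card$mean_rr * 1000, mHR = 60 / card$mean_rr)
}

#' Simulate a full multi-subject cohort at signal level
#'
#' For each subject, walks the session schedule generating one RR series
#' and one accelerometer bout per activity block, and computes per-minute
#' reference energy expenditure by applying `ee_model` to the generator's
#' true per-minute features plus Gaussian noise.  Everything is
#' reproducible from `seed`.
#'
#' @param n_subjects cohort size (>= 3; leave-one-subject-out needs
#'   train/validation/test subjects), default 13.
#' @param schedule session schedule (see [default_schedule()]).
#' @param ee_model generative EE model (see [default_ee_model()]).
#' @param seed integer seed.
#' @param profiles optional pre-built list of subject profiles.
#' @param ecg also synthesize the raw ECG waveform for every bout (slower;
#'   the RR ground truth is always present).
#' @param ecg_noise_sd,accel_fs,ecg_fs signal-generation settings.
#' @return A `cohort`: list with `subjects` (per-subject list of profile,
#'   per-block `rr`, `accel`, optional `ecg`), `schedule`, `labels`
#'   (per-minute data.frame with `subject_id`, `minute_index`, `activity`,
#'   `ee_kcal_per_min`), `seed`.
#' @export
generate_cohort <- function(n_subjects = 13L, schedule = default_schedule(),
                            ee_model = default_ee_model(), seed = 1L,
                            profiles = NULL, ecg = FALSE,
                            ecg_noise_sd = 0.05, accel_fs = 128, ecg_fs = 256) {
  if (n_subjects < 3L)
    stop("need at least 3 subjects for leave-one-subject-out folds", call. = FALSE)
  schedule <- validate_schedule(schedule)
  if (is.null(profiles))
    profiles <- subject_profiles(n_subjects, seed = child_seed(seed, "profiles"))
  stopifnot(length(profiles) == n_subjects)

  subjects <- vector("list", n_subjects)
  labels <- list()
  for (s in seq_len(n_subjects)) {
    prof <- profiles[[s]]
    blocks <- vector("list", nrow(schedule))
    minute0 <- 0L
    for (b in seq_len(nrow(schedule))) {
      act <- schedule$activity[b]; mins <- schedule$minutes[b]
      dur <- mins * 60
      prev_dyn <- if (act == "REST" && b > 1L) schedule$activity[b - 1L] else "RU"
      rr <- generate_rr_series(act, dur, prof,
                               seed = child_seed(seed, "rr", s, b),
                               rest_from = prev_dyn)
      acc <- generate_accel(act, dur, prof, fs = accel_fs,
                            seed = child_seed(seed, "acc", s, b))
      block <- list(activity = act, minutes = mins, rr = rr, accel = acc)
      if (ecg)
        block$ecg <- generate_ecg_waveform(rr, fs = ecg_fs, noise_sd = ecg_noise_sd,
                                           wander_amp = 0.1,
                                           seed = child_seed(seed, "ecg", s, b))
      blocks[[b]] <- block

      truth <- true_minute_features(prof, act)
      cat_b <- activity_category(act)
      mu <- ee_linear_predictor(ee_model, cat_b, truth)
      local_rng(child_seed(seed, "ee", s, b))
      ee <- mu + stats::rnorm(mins, 0, ee_model$noise_sd)
      labels[[length(labels) + 1L]] <- data.frame(
        subject_id = prof$subject_id,
        minute_index = minute0 + seq_len(mins) - 1L,
        activity = act,
        ee_kcal_per_min = ee,
        stringsAsFactors = FALSE)
      minute0 <- minute0 + mins
    }
    subjects[[s]] <- list(profile = prof, blocks = blocks)
  }
  structure(list(subjects = subjects, schedule = schedule,
                 labels = do.call(rbind, labels), seed = seed,
                 ee_model = ee_model),
            class = "cohort")
}

#' Extract the per-minute analysis table from a simulated cohort
#'
#' Runs the feature-extraction stages on every block of every subject: the
#' four IMU features per minute (2-s windows averaged 30-per-minute) and
#' the 31 HRV parameters per one-minute RR window, joined with activity
#' labels, anthropometrics and reference EE.  When a block carries a raw
#' ECG waveform and `use_detector` is TRUE, R peaks are re-detected from
#' it; otherwise the generator's ground-truth RR series is used.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param use_detector run [detect_r_peaks()] on stored ECG waveforms.
#' @return Data.frame, one row per minute: `subject_id`, `minute_index`,
#'   `activity`, `height`, `weight`, the 4 IMU features, the 31 HRV
#'   parameters, `ee_kcal_per_min`.
#' @export
cohort_minutes <- function(cohort, use_detector = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- list()
  for (sub in cohort$subjects) {
    minute0 <- 0L
    for (block in sub$blocks) {
      imu <- imu_features_by_minute(block$accel)
      rr <- block$rr
      if (use_detector && !is.null(block$ecg))
        rr <- build_rr(detect_r_peaks(block$ecg))
      hrv <- suppressWarnings(hrv_features_by_minute(rr))
      n_min <- min(nrow(imu), nrow(hrv), block$minutes)
      if (n_min == 0L) { minute0 <- minute0 + block$minutes; next }
      d <- cbind(
        data.frame(subject_id = sub$profile$subject_id,
                   minute_index = minute0 + seq_len(n_min) - 1L,
                   activity = block$activity,
                   height = sub$profile$height,
                   weight = sub$profile$weight,
                   stringsAsFactors = FALSE),
        imu[seq_len(n_min), c("rms", "sd", "f_dominant", "energy")],
        hrv[seq_len(n_min), hrv_parameter_names()])
      rows[[length(rows) + 1L]] <- d
      minute0 <- minute0 + block$minutes
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  merge(out, cohort$labels,
        by = c("subject_id", "minute_index", "activity"), sort = FALSE)
}
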