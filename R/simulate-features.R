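#' Simulate a per-minute feature cohort directly
#'
#' Draws the per-minute analysis table (4 IMU features + 31 HRV parameters
#' + anthropometrics + reference EE) from class-conditional distributions,
#' bypassing signal synthesis and feature extraction.  This is the fast
#' substrate for Monte-Carlo studies of the recognition and regression
#' stages: the informative features carry the class-conditional window
#' statistics the full pipeline converges to, and every other HRV
#' parameter is class-independent standard-normal noise.
#'
#' Per minute of activity `a` for subject `s`:
#' * `mRR` (ms) ~ N(mu_a, sigma_a) split into a subject-level shift and
#'   window noise (equal variance shares), with the class means/SDs of
#'   [default_cardiac_params()] (0.86/0.77/0.61/0.47 s for SI/ST/WK/AS);
#' * `mHR` (1/min) = 60000/mRR plus small measurement noise, matching the
#'   class-conditional heart-rate statistics (71.2/79.9/100.8/130.6 for
#'   SI/ST/WK/AS);
#' * the remaining 29 HRV parameters ~ N(0, 1), class-independent;
#' * IMU features from the configured per-activity amplitudes with
#'   within-subject noise (SI/ST and WK/AS pairs overlap, the separations
#'   the recognition scenarios probe);
#' * `ee_kcal_per_min` from `ee_model` applied to the minute's true
#'   features plus Gaussian noise.
#'
#' @param n_subjects cohort size, default 13.
#' @param schedule session schedule (see [default_schedule()]).
#' @param ee_model generative EE model (see [default_ee_model()]).
#' @param seed integer seed.
#' @param hr_noise_sd measurement noise added to `mHR` (1/min).
#' @return Data.frame, one row per minute, same columns as
#'   [cohort_minutes()].
#' @export
simulate_feature_cohort <- function(n_subjects = 13L,
                                    schedule = default_schedule(),
                                    ee_model = default_ee_model(),
                                    seed = 1L, hr_noise_sd = 2) {
  if (n_subjects < 3L)
    stop("need at least 3 subjects for leave-one-subject-out folds", call. = FALSE)
  schedule <- validate_schedule(schedule)
  card <- default_cardiac_params()
  acc <- default_accel_params()
  local_rng(seed)
  other <- setdiff(hrv_parameter_names(), c("mRR", "mHR"))

  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    height <- stats::runif(1, 150, 190)
    weight <- stats::runif(1, 45, 95)
    # subject-level shifts: half the class variance between subjects,
    # half within (window to window)
    rr_shift <- stats::setNames(
      stats::rnorm(nrow(card), 0, card$sd_between / sqrt(2)), card$activity)
    amp_fac <- stats::runif(1, 0.9, 1.1)
    other_shift <- stats::rnorm(length(other), 0, 0.3)
    minute0 <- 0L
    for (b in seq_len(nrow(schedule))) {
      a <- schedule$activity[b]; mins <- schedule$minutes[b]
      crow <- card[card$activity == a, ]
      arow <- acc[acc$activity == a, ]
      mrr_s <- (crow$mean_rr + rr_shift[[a]]) * 1000
      mrr <- stats::rnorm(mins, mrr_s, crow$sd_between / sqrt(2) * 1000)
      mrr <- pmin(1999, pmax(301, mrr))
      mhr <- 60000 / mrr + stats::rnorm(mins, 0, hr_noise_sd)

      amp <- arow$amp_g * amp_fac
      rms_true <- if (amp > 0) sqrt((amp^2 + (0.2 * amp)^2 + (0.3 * amp)^2) / 2) else 0
      rms <- pmax(0, rms_true + arow$noise_sd + stats::rnorm(mins, 0, 0.03 + 0.05 * amp))
      sdv <- pmax(0, rms + stats::rnorm(mins, 0, 0.01))
      fdom <- pmax(0, arow$gait_freq +
                     stats::rnorm(mins, 0, if (arow$gait_freq > 0) 0.15 else 0.5))
      energy <- 256 * rms^2 + stats::rnorm(mins, 0, 0.5)

      hrvother <- matrix(stats::rnorm(mins * length(other)), nrow = mins)
      hrvother <- sweep(hrvother, 2L, other_shift, `+`)
      colnames(hrvother) <- other

      truth <- c(height = height, weight = weight,
                 rms = rms_true, sd = rms_true, f_dominant = arow$gait_freq,
                 energy = 256 * rms_true^2,
                 mRR = (crow$mean_rr + rr_shift[[a]]) * 1000,
                 mHR = 60 / (crow$mean_rr + rr_shift[[a]]))
      mu <- ee_linear_predictor(ee_model, activity_category(a), truth)
      # per-minute EE also tracks the minute's own heart rate so that the
      # HRV column carries usable regression signal within subjects
      beta_hr <- ee_model[[activity_category(a)]]["mHR"]
      if (is.na(beta_hr)) beta_hr <- 0
      ee <- mu + beta_hr * (mhr - truth[["mHR"]]) +
        stats::rnorm(mins, 0, ee_model$noise_sd)

      d <- data.frame(subject_id = sid,
                      minute_index = minute0 + seq_len(mins) - 1L,
                      activity = a, height = height, weight = weight,
                      rms = rms, sd = sdv, f_dominant = fdom, energy = energy,
                      stringsAsFactors = FALSE)
      d$mRR <- mrr; d$mHR <- mhr
      d <- cbind(d, as.data.frame(hrvother))
      d$ee_kcal_per_min <- ee
      rows[[length(rows) + 1L]] <- d
      minute0 <- minute0 + mins
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("subject_id", "minute_index", "activity", "height", "weight",
          "rms", "sd", "f_dominant", "energy", hrv_parameter_names(),
          "ee_kcal_per_min")]
}

#' Names of the feature columns of a per-minute table
#'
#' @param data_type `"imu"` (4 features), `"imu_ecg"` (35), `"ecg"` (31).
#' @param anthropometrics prepend `height`, `weight` (the EE candidate
#'   pools).
#' @return Character vector of column names.
#' @export
feature_columns <- function(data_type = c("imu_ecg", "imu", "ecg"),
                            anthropometrics = FALSE) {
  data_type <- match.arg(data_type)
  imu <- c("rms", "sd", "f_dominant", "energy")
  cols <- switch(data_type,
                 imu = imu,
                 imu_ecg = c(imu, hrv_parameter_names()),
                 ecg = hrv_parameter_names())
  if (anthropometrics) cols <- c("height", "weight", cols)
  cols
}
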