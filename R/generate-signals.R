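#' Simulate an RR-interval series for one activity bout
#'
#' Beat-to-beat intervals are generated as a baseline mean RR plus two
#' sinusoidal modulations — one in the low-frequency band (default 0.095 Hz)
#' and one in the high-frequency band (default 0.25 Hz) — plus white jitter.
#' This gives the simulated tachogram a known spectral truth so the
#' frequency-domain HRV stage can be checked against configured tones.
#'
#' For `REST` the baseline decays exponentially from the mean RR of the
#' preceding dynamic activity (`rest_from`) towards the sitting mean with
#' time constant `rest_tau`, emulating seated post-exercise recovery.
#'
#' @param activity one activity code.
#' @param duration bout length in seconds (>= 60).
#' @param profile a `subject_profile` (see [subject_profiles()]); any list
#'   with a `cardiac` table in the [default_cardiac_params()] layout works.
#' @param seed integer seed (NULL = use current RNG stream).
#' @param lf_freq,hf_freq modulation frequencies (Hz).
#' @param rest_from activity whose mean RR seeds the REST recovery decay.
#' @param rest_tau REST recovery time constant (s).
#' @return An [rr_series] whose R-peak times cover `duration`.
#' @export
generate_rr_series <- function(activity, duration, profile, seed = NULL,
                               lf_freq = 0.095, hf_freq = 0.25,
                               rest_from = "RU", rest_tau = 90) {
  if (!is.numeric(duration) || duration < 60)
    stop("duration must be at least 60 s", call. = FALSE)
  row <- cardiac_row(profile, activity)
  local_rng(seed)
  phase_lf <- stats::runif(1, 0, 2 * pi)
  phase_hf <- stats::runif(1, 0, 2 * pi)

  baseline <- function(t) rep_len(row$mean_rr, length(t))
  if (identical(activity, "REST")) {
    m_end <- cardiac_row(profile, "SI")$mean_rr
    m_start <- cardiac_row(profile, rest_from)$mean_rr
    baseline <- function(t) m_end - (m_end - m_start) * exp(-t / rest_tau)
  }

  # beats are laid down sequentially because each interval depends on the
  # wall-clock time at which it starts
  n_guess <- ceiling(duration / max(row$mean_rr - 3 * row$jitter_sd, 0.3)) + 16L
  rr <- numeric(0); t <- 0
  repeat {
    jit <- stats::rnorm(n_guess, 0, row$jitter_sd)
    for (i in seq_len(n_guess)) {
      r <- baseline(t) +
        row$lf_amp * sin(2 * pi * lf_freq * t + phase_lf) +
        row$hf_amp * sin(2 * pi * hf_freq * t + phase_hf) +
        jit[i]
      r <- min(2.0, max(0.3, r))   # physiological clamp
      t <- t + r
      rr <- c(rr, r)
      if (t >= duration) break
    }
    if (t >= duration) break
  }
  rr_from_intervals(rr * 1000)
}

#' Synthesize an ECG waveform from an RR series
#'
#' Places a fixed-width biphasic QRS-like template (a narrow positive
#' Gaussian spike with a smaller trailing negative lobe, ~80 ms overall) at
#' each R-peak time of `rr`, and adds optional sinusoidal baseline wander
#' (0.25 Hz) and white noise.  The true R-peak times travel with the signal
#' as ground truth for detector validation.
#'
#' @param rr an [rr_series]; its `t` field gives the R-peak times.
#' @param fs sampling rate (Hz, >= 128; the emulated chest sensor records at 256).
#' @param noise_sd white-noise SD in units of the QRS amplitude.
#' @param wander_amp baseline-wander amplitude (same units).
#' @param qrs_amp QRS peak amplitude (arbitrary units).
#' @param seed integer seed for the noise.
#' @return An `ecg_signal`: list with `time`, `ecg`, `fs`, `true_peaks`.
#' @export
generate_ecg_waveform <- function(rr, fs = 256, noise_sd = 0, wander_amp = 0,
                                  qrs_amp = 1, seed = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  if (!length(rr)) stop("rr series is empty", call. = FALSE)
  if (fs < 128) stop("fs must be at least 128 Hz", call. = FALSE)
  local_rng(seed)
  peaks <- rr$t
  n <- ceiling((max(peaks) + 0.4) * fs) + 1L
  x <- numeric(n)
  sig_r <- 0.012                     # main spike width (s)
  sig_s <- 0.012                     # trailing S-lobe width (s)
  lobe_lag <- 0.035                  # S-lobe offset (s); total footprint ~80 ms
  half <- ceiling(0.06 * fs)
  for (p in peaks) {
    c_idx <- round(p * fs)           # 0-based sample of the R peak
    idx <- max(0L, c_idx - half):min(n - 1L, c_idx + half)
    tau <- idx / fs - p
    x[idx + 1L] <- x[idx + 1L] + qrs_amp *
      (exp(-tau^2 / (2 * sig_r^2)) -
         0.35 * exp(-(tau - lobe_lag)^2 / (2 * sig_s^2)))
  }
  tgrid <- (seq_len(n) - 1L) / fs
  if (wander_amp > 0)
    x <- x + wander_amp * qrs_amp * sin(2 * pi * 0.25 * tgrid + stats::runif(1, 0, 2 * pi))
  if (noise_sd > 0)
    x <- x + stats::rnorm(n, 0, noise_sd * qrs_amp)
  structure(list(time = tgrid, ecg = x, fs = fs, true_peaks = peaks),
            class = "ecg_signal")
}

#' Simulate a wrist tri-axial accelerometer bout
#'
#' Static activities produce a gravity offset plus low-amplitude white
#' noise.  Dynamic activities superimpose a gait-frequency sinusoid, a
#' second harmonic and an elevated mean on the vertical axis, plus a smaller
#' out-of-phase component on the horizontal axis, so the vector-magnitude
#' signal carries its dominant spectral line at the gait frequency and its
#' RMS scales with the configured amplitude (WK < AS < RU).
#'
#' @param activity activity code.
#' @param duration bout length (s, >= 60).
#' @param profile a `subject_profile` (or any list with an `accel` table).
#' @param fs sampling rate (Hz; the emulated wrist unit records at 128).
#' @param seed integer seed.
#' @return An `accel_signal`: list with `time`, `ax`, `ay`, `az` (g), `fs`.
#' @export
generate_accel <- function(activity, duration, profile, fs = 128, seed = NULL) {
  if (!is.numeric(duration) || duration < 60)
    stop("duration must be at least 60 s", call. = FALSE)
  row <- accel_row(profile, activity)
  local_rng(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  amp <- row$amp_g; f <- row$gait_freq
  ax <- numeric(n); ay <- numeric(n); az <- rep(1, n)
  if (amp > 0 && f > 0) {
    az <- 1 + 0.8 * amp + amp * sin(2 * pi * f * t) +
      0.2 * amp * sin(4 * pi * f * t + 0.8)
    ax <- 0.3 * amp * sin(2 * pi * f * t + 1.0)
  }
  if (row$noise_sd > 0) {
    ax <- ax + stats::rnorm(n, 0, row$noise_sd)
    ay <- ay + stats::rnorm(n, 0, row$noise_sd)
    az <- az + stats::rnorm(n, 0, row$noise_sd)
  }
  structure(list(time = t, ax = ax, ay = ay, az = az, fs = fs,
                 activity = activity),
            class = "accel_signal")
}
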