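#' Detect R peaks in a single-lead ECG
#'
#' A Pan-Tompkins-style pipeline: zero-phase 5-30 Hz Butterworth band-pass,
#' five-point derivative, squaring, 150-ms moving-window integration, then
#' an adaptive signal/noise threshold with a 250 ms refractory period.  The
#' reported peak time is the local maximum of the band-passed signal within
#' +/-120 ms of each accepted integrator peak.
#'
#' @param ecg an `ecg_signal` (list with `ecg`, `fs`) or a numeric vector.
#' @param fs sampling rate, required when `ecg` is a bare vector.
#' @return Strictly increasing R-peak times (s).
#' @export
detect_r_peaks <- function(ecg, fs = NULL) {
  if (inherits(ecg, "ecg_signal")) { x <- ecg$ecg; fs <- ecg$fs }
  else { x <- as.numeric(ecg); if (is.null(fs)) stop("fs required", call. = FALSE) }
  if (length(x) < 2 * fs)
    stop("ECG shorter than 2 s cannot be analysed", call. = FALSE)
  if (stats::sd(x) == 0) return(numeric(0))

  bp <- signal::butter(3, c(5, 30) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  dx <- c(0, diff(xf)) * fs
  sq <- dx^2
  w <- max(1L, round(0.150 * fs))
  integ <- stats::filter(sq, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  refr <- round(0.250 * fs)
  cand <- local_maxima(integ, min_sep = refr)
  if (!length(cand)) return(numeric(0))

  spki <- max(integ[cand]); npki <- stats::median(integ[cand])
  thr <- npki + 0.25 * (spki - npki)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    v <- integ[cand[i]]
    if (v > thr) {
      keep[i] <- TRUE
      spki <- 0.125 * v + 0.875 * spki
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  cand <- cand[keep]
  if (!length(cand)) return(numeric(0))

  # refine to the band-passed local maximum near each accepted peak
  half <- round(0.120 * fs)
  times <- vapply(cand, function(ci) {
    lo <- max(1L, ci - half); hi <- min(length(xf), ci + half)
    (lo + which.max(xf[lo:hi]) - 2L) / fs
  }, numeric(1))
  times <- sort(unique(times))
  # enforce the refractory period on the refined times
  if (length(times) > 1L) {
    keep <- rep(TRUE, length(times)); last <- times[1]
    for (i in 2:length(times)) {
      if (times[i] - last < 0.250) keep[i] <- FALSE else last <- times[i]
    }
    times <- times[keep]
  }
  times
}

local_maxima <- function(y, min_sep) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  # greedy thinning: keep the larger of any two maxima closer than min_sep
  ord <- idx[order(-y[idx])]
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(taken - i) >= min_sep)) taken <- c(taken, i)
  }
  sort(taken)
}

#' Build an RR series from R-peak times
#'
#' Successive differences of the peak times become RR intervals (ms);
#' intervals outside the physiological band are discarded (no
#' interpolation) and counted in `n_dropped`.
#'
#' @param peak_times strictly increasing R-peak times (s).
#' @param band physiological interval band (ms), default 300-2000.
#' @return An [rr_series].
#' @export
build_rr <- function(peak_times, band = c(300, 2000)) {
  if (length(peak_times) < 2L)
    stop("at least two R peaks are needed to form an interval", call. = FALSE)
  if (any(diff(peak_times) <= 0))
    stop("peak times must be strictly increasing", call. = FALSE)
  rr <- diff(peak_times) * 1000
  t_end <- peak_times[-1L]
  ok <- rr >= band[1] & rr <= band[2]
  rr_series(t_end[ok], rr[ok], n_dropped = sum(!ok))
}

#' Split an RR series into non-overlapping one-minute windows
#'
#' Windows are anchored at `t0` (session start) and tile `[t0, t0+w)`,
#' `[t0+w, t0+2w)`, ...  An interval belongs to the window containing its
#' terminating R peak; the trailing partial window is discarded.  The
#' number of windows is `floor((t_last - t0) / window)`.
#'
#' @param rr an [rr_series].
#' @param window window length (s), default 60.
#' @param t0 window-grid origin (s), default 0.
#' @return List of [rr_series] windows (possibly empty, with a warning).
#' @export
window_rr <- function(rr, window = 60, t0 = 0) {
  stopifnot(inherits(rr, "rr_series"))
  if (!length(rr) || (max(rr$t) - t0) < window) {
    warning("RR series spans less than one window")
    return(list())
  }
  n_win <- floor((max(rr$t) - t0) / window)
  idx <- floor((rr$t - t0) / window)
  lapply(seq_len(n_win) - 1L, function(k) {
    sel <- idx == k
    rr_series(rr$t[sel], rr$rr_ms[sel])
  })
}
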