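#' Segment an accelerometer signal into 2-s windows
#'
#' Non-overlapping windows of `window * fs` samples over the vector of
#' sample indices; the trailing partial window is discarded.
#'
#' @param signal an `accel_signal` (see [generate_accel()]) or a 3-column
#'   matrix `(ax, ay, az)` in g.
#' @param fs sampling rate (required for a bare matrix).
#' @param window window length (s), default 2.
#' @return List of 3-column matrices, each `window * fs` rows.
#' @export
segment_accel <- function(signal, fs = NULL, window = 2) {
  if (inherits(signal, "accel_signal")) {
    m <- cbind(signal$ax, signal$ay, signal$az); fs <- signal$fs
  } else {
    m <- as.matrix(signal)
    if (is.null(fs)) stop("fs required", call. = FALSE)
  }
  len <- round(window * fs)
  n_win <- nrow(m) %/% len
  if (n_win == 0L) {
    warning("signal shorter than one window")
    return(list())
  }
  lapply(seq_len(n_win), function(k) m[((k - 1L) * len + 1L):(k * len), , drop = FALSE])
}

#' Four accelerometer features of one 2-s window
#'
#' Computed on the mean-removed vector magnitude `m(t) =
#' sqrt(ax^2+ay^2+az^2)`: `rms` (g, root mean square), `sd` (g, sample SD),
#' `f_dominant` (Hz, frequency of the largest non-DC FFT bin; 0 for an
#' all-zero spectrum) and `energy` (g^2, `sum(|X_k|^2)/N` over non-DC
#' bins, which by Parseval equals the summed square of the mean-removed
#' magnitude).
#'
#' @param window a 3-column matrix (one segment from [segment_accel()]).
#' @param fs sampling rate (Hz).
#' @return Named numeric vector `c(rms, sd, f_dominant, energy)`.
#' @export
imu_window_features <- function(window, fs = 128) {
  m <- as.matrix(window)
  if (ncol(m) != 3L) stop("window must have three axis columns", call. = FALSE)
  n <- nrow(m)
  mag <- sqrt(rowSums(m^2))
  mag <- mag - mean(mag)
  X <- stats::fft(mag)
  half <- n %/% 2L
  amp2 <- Mod(X[2:(half + 1L)])^2        # non-DC bins up to Nyquist
  fdom <- if (all(amp2 <= .Machine$double.eps)) 0 else (which.max(amp2)) * fs / n
  c(rms = sqrt(mean(mag^2)),
    sd = stats::sd(mag),
    f_dominant = fdom,
    energy = sum(Mod(X[-1L])^2) / n)
}

#' Per-minute IMU feature vector
#'
#' Element-wise mean of the four features over the (nominally 30) 2-s
#' windows of one minute.  Minutes with fewer than `min_windows` usable
#' windows are returned as `NA` with a flag.
#'
#' @param feature_rows matrix or data.frame of per-window feature rows.
#' @param min_windows minimum window count for a valid minute, default 25.
#' @return Named numeric vector of the four averaged features, with a
#'   `flags` attribute.
#' @export
imu_minute_average <- function(feature_rows, min_windows = 25L) {
  m <- as.matrix(feature_rows)
  if (nrow(m) < min_windows) {
    out <- stats::setNames(rep(NA_real_, 4L), c("rms", "sd", "f_dominant", "energy"))
    attr(out, "flags") <- "too-few-windows"
    return(out)
  }
  out <- colMeans(m)
  names(out) <- c("rms", "sd", "f_dominant", "energy")
  attr(out, "flags") <- character(0)
  out
}

#' Per-minute IMU features for a whole session
#'
#' Segments the signal into 2-s windows, extracts the four features per
#' window, and averages them over each one-minute block (30 windows).
#'
#' @param signal an `accel_signal` or 3-column matrix.
#' @param fs sampling rate (required for a bare matrix).
#' @param window sub-window length (s).
#' @param minute minute length (s).
#' @return Data.frame with `minute_index` and columns `rms`, `sd`,
#'   `f_dominant`, `energy`.
#' @export
imu_features_by_minute <- function(signal, fs = NULL, window = 2, minute = 60) {
  if (inherits(signal, "accel_signal")) fs <- signal$fs
  segs <- segment_accel(signal, fs = fs, window = window)
  if (!length(segs)) return(data.frame())
  feats <- t(vapply(segs, imu_window_features, numeric(4), fs = fs))
  per_min <- as.integer(minute / window)
  n_min <- length(segs) %/% per_min
  rows <- lapply(seq_len(n_min), function(k) {
    block <- feats[((k - 1L) * per_min + 1L):(k * per_min), , drop = FALSE]
    avg <- imu_minute_average(block)
    data.frame(minute_index = k - 1L, rms = avg[["rms"]], sd = avg[["sd"]],
               f_dominant = avg[["f_dominant"]], energy = avg[["energy"]])
  })
  do.call(rbind, rows)
}
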