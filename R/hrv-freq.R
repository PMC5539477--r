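#' Welch power spectral density
#'
#' Averaged modified periodogram: the mean-removed series is cut into
#' Hann-windowed segments of `nseg` samples with 50% overlap and the
#' one-sided periodograms are averaged.  Scaling follows the PSD
#' convention `sum(psd) * df ~ variance` (checked against a Parseval
#' oracle in the test suite).
#'
#' @param x numeric series sampled at `fs`.
#' @param fs sampling rate (Hz).
#' @param nseg segment length in samples (clipped to `length(x)`).
#' @return List with `freq` (Hz) and `psd` (input units^2 per Hz).
#' @keywords internal
welch_psd <- function(x, fs, nseg = 128L) {
  n <- length(x)
  nseg <- min(as.integer(nseg), n)
  if (nseg < 8L) stop("series too short for spectral estimation", call. = FALSE)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1L)) / nseg))  # Hann (periodic)
  u <- sum(w^2)
  acc <- numeric(nseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[1:(nseg %/% 2L + 1L)]
    p <- Mod(X)^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist when nseg is even)
    sc <- rep(2, length(p)); sc[1] <- 1
    if (nseg %% 2L == 0L) sc[length(p)] <- 1
    acc <- acc + p * sc
  }
  list(freq = (0:(nseg %/% 2L)) * fs / nseg, psd = acc / length(starts))
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Frequency-domain HRV parameters
#'
#' The RR tachogram (interval length vs R-peak time) is resampled to an
#' even 4 Hz grid by cubic interpolation, mean-removed, and its PSD
#' estimated by Welch's method (32-s Hann segments, 50% overlap).  Band
#' powers (ms^2) are trapezoidal integrals over VLF (0-0.04 Hz), LF
#' (0.04-0.15 Hz) and HF (0.15-0.4 Hz); `VLF`/`LF`/`HF` are the band peak
#' frequencies (Hz).  Relative powers use the band-limited total
#' (pVLF+pLF+pHF) as denominator; normalized units use LF+HF.
#'
#' @param rr an [rr_series] (peak times required) or numeric RR vector (ms),
#'   in which case times are reconstructed by cumulative summation.
#' @param resample_fs tachogram resampling rate (Hz).
#' @param nseg Welch segment length (s).
#' @return Named numeric vector of the 12 frequency-domain parameters with a
#'   `flags` attribute (`"zero-power"` when the spectrum is empty).
#' @export
hrv_freq <- function(rr, resample_fs = 4, nseg = 32) {
  x <- rr_values(rr); tt <- rr_times(rr)
  if (length(x) < 30L)
    stop("frequency-domain parameters need at least 30 RR intervals", call. = FALSE)
  grid <- seq(tt[1], tt[length(tt)], by = 1 / resample_fs)
  tach <- stats::spline(tt, x, xout = grid, method = "fmm")$y
  tach <- tach - mean(tach)
  sp <- welch_psd(tach, fs = resample_fs, nseg = round(nseg * resample_fs))

  bands <- list(VLF = c(0, 0.04), LF = c(0.04, 0.15), HF = c(0.15, 0.40))
  pow <- peak <- numeric(3); names(pow) <- names(peak) <- names(bands)
  for (b in names(bands)) {
    sel <- sp$freq >= bands[[b]][1] & sp$freq <= bands[[b]][2]
    pow[b] <- trapz(sp$freq[sel], sp$psd[sel])
    peak[b] <- if (any(sel) && any(sp$psd[sel] > 0))
      sp$freq[sel][which.max(sp$psd[sel])] else 0
  }
  total <- sum(pow)
  flags <- character(0)
  if (total <= .Machine$double.eps) {
    flags <- "zero-power"
    prc <- c(0, 0, 0); nlf <- 0; nhf <- 0; lfhf <- 0
  } else {
    prc <- 100 * pow / total
    lh <- pow["LF"] + pow["HF"]
    if (lh > 0) { nlf <- unname(pow["LF"] / lh); nhf <- unname(pow["HF"] / lh) }
    else { nlf <- 0; nhf <- 0; flags <- "zero-lf-hf" }
    lfhf <- if (pow["HF"] > 0) unname(pow["LF"] / pow["HF"]) else 0
  }
  out <- c(VLF = unname(peak["VLF"]), LF = unname(peak["LF"]), HF = unname(peak["HF"]),
           pVLF = unname(pow["VLF"]), pLF = unname(pow["LF"]), pHF = unname(pow["HF"]),
           prcVLF = unname(prc[1]), prcLF = unname(prc[2]), prcHF = unname(prc[3]),
           nLF = nlf, nHF = nhf, LF_HF = lfhf)
  attr(out, "flags") <- flags
  out
}
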