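#' Time-domain HRV parameters
#'
#' Computes the seven time-domain parameters of a one-minute RR window:
#' mean RR interval `mRR` (ms), its sample SD `SDRR` (ms), mean and SD of
#' the instantaneous heart rate `mHR`/`SDHR` (1/min, HR_i = 60000/RR_i),
#' `RMSSD` (ms, root mean square of successive differences), `NN50` (count
#' of successive-interval pairs differing by more than 50 ms) and `pNN50`
#' (%, NN50 over the number of RR intervals).
#'
#' @param rr an [rr_series] or numeric vector of RR intervals (ms).
#' @return Named numeric vector of the seven parameters.
#' @export
hrv_time <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 2L)
    stop("time-domain parameters need at least 2 RR intervals (SDRR)", call. = FALSE)
  if (length(x) < 3L)
    stop("RMSSD/NN50 need at least 3 RR intervals", call. = FALSE)
  hr <- 60000 / x
  d <- diff(x)
  nn50 <- sum(abs(d) > 50)
  c(mRR = mean(x),
    SDRR = stats::sd(x),
    mHR = mean(hr),
    SDHR = stats::sd(hr),
    RMSSD = sqrt(mean(d^2)),
    NN50 = nn50,
    pNN50 = 100 * nn50 / length(x))
}

rr_values <- function(rr) {
  if (inherits(rr, "rr_series")) rr$rr_ms else as.numeric(rr)
}

rr_times <- function(rr) {
  if (inherits(rr, "rr_series")) rr$t else cumsum(as.numeric(rr)) / 1000
}
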