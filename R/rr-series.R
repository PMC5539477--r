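#' RR-interval series
#'
#' Container for a sequence of RR intervals.  Each interval `rr_ms[i]`
#' terminates at the absolute R-peak time `t[i]` (seconds from session
#' start); `t` is strictly increasing.  `n_dropped` records how many
#' intervals were removed by the physiological band filter.
#'
#' @param t terminating R-peak time of each interval (s), strictly increasing.
#' @param rr_ms interval lengths (ms), same length as `t`.
#' @param n_dropped count of intervals removed by artifact filtering.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(t, rr_ms, n_dropped = 0L) {
  stopifnot(length(t) == length(rr_ms))
  if (length(t) && any(diff(t) <= 0))
    stop("R-peak times must be strictly increasing", call. = FALSE)
  if (any(rr_ms <= 0))
    stop("RR intervals must be positive", call. = FALSE)
  structure(list(t = as.numeric(t), rr_ms = as.numeric(rr_ms),
                 n_dropped = as.integer(n_dropped)),
            class = "rr_series")
}

#' @rdname rr_series
#' @param t0 time of the (implicit) beat preceding the first interval.
#' @export
rr_from_intervals <- function(rr_ms, t0 = 0) {
  rr_series(t0 + cumsum(rr_ms) / 1000, rr_ms)
}

#' @export
length.rr_series <- function(x) length(x$rr_ms)

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series: %d intervals over %.1f s, mean RR %.1f ms, %d dropped>\n",
              length(x), if (length(x)) max(x$t) - (x$t[1] - x$rr_ms[1] / 1000) else 0,
              mean(x$rr_ms), x$n_dropped))
  invisible(x)
}
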