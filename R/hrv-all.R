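#' Canonical order of the 31 HRV parameter names
#'
#' Time domain (7), frequency domain (12), nonlinear (12).  `LF_HF` is the
#' LF/HF band-power ratio; `D2` the correlation dimension.
#'
#' @return Character vector of length 31.
#' @export
hrv_parameter_names <- function() c(
  "mRR", "SDRR", "mHR", "SDHR", "RMSSD", "NN50", "pNN50",
  "VLF", "LF", "HF", "pVLF", "pLF", "pHF", "prcVLF", "prcLF", "prcHF",
  "nLF", "nHF", "LF_HF",
  "SD1", "SD2", "ApEn", "SampEn", "D2", "Alpha1", "Alpha2",
  "Lmean", "Lmax", "REC", "DET", "ShanEn"
)

#' All 31 HRV parameters for one window
#'
#' Runs the time-domain, frequency-domain, Poincare, entropy, DFA,
#' correlation-dimension and recurrence stages on one RR window and
#' assembles the canonical 31-value vector.  Stages whose preconditions
#' fail on a degenerate window return `NA` for their fields and are named
#' in the `flags` attribute — missingness is never silently encoded as 0
#' beyond each stage's documented conventions (constant-window entropies
#' and empty recurrence plots).
#'
#' @param rr an [rr_series] or numeric RR vector (ms) for one window.
#' @param config optional list overriding nonlinear defaults
#'   (`entropy_m`, `entropy_r_frac`, `rqa_m`, `rqa_lmin`, `d2_m`).
#' @return Named numeric vector of length 31 with a `flags` attribute.
#' @export
hrv_features <- function(rr, config = list()) {
  x <- rr_values(rr)
  if (!length(x)) stop("empty RR window", call. = FALSE)
  cfg <- utils::modifyList(list(entropy_m = 2L, entropy_r_frac = 0.2,
                                rqa_m = 10L, rqa_lmin = 2L, d2_m = 10L), config)
  out <- stats::setNames(rep(NA_real_, 31L), hrv_parameter_names())
  flags <- character(0)

  grab <- function(fun, fields, label) {
    res <- tryCatch(fun(), error = function(e) NULL)
    if (is.null(res)) {
      flags <<- c(flags, paste0(label, ":unavailable"))
    } else {
      out[fields] <<- as.numeric(res)[seq_along(fields)]
      f <- attr(res, "flags")
      if (length(f)) flags <<- c(flags, paste0(label, ":", f))
    }
  }
  grab(function() hrv_time(x),
       c("mRR", "SDRR", "mHR", "SDHR", "RMSSD", "NN50", "pNN50"), "time")
  grab(function() hrv_freq(if (inherits(rr, "rr_series")) rr else x),
       c("VLF", "LF", "HF", "pVLF", "pLF", "pHF", "prcVLF", "prcLF", "prcHF",
         "nLF", "nHF", "LF_HF"), "freq")
  grab(function() hrv_poincare(x), c("SD1", "SD2"), "poincare")
  grab(function() hrv_entropy(x, m = cfg$entropy_m,
                              r = cfg$entropy_r_frac * stats::sd(x)),
       c("ApEn", "SampEn"), "entropy")
  grab(function() hrv_d2(x, m = cfg$d2_m), "D2", "d2")
  grab(function() hrv_dfa(x), c("Alpha1", "Alpha2"), "dfa")
  grab(function() hrv_rqa(x, m = cfg$rqa_m, lmin = cfg$rqa_lmin),
       c("Lmean", "Lmax", "REC", "DET", "ShanEn"), "rqa")
  attr(out, "flags") <- flags
  out
}

#' HRV features for every one-minute window of a session
#'
#' @param rr an [rr_series] covering a whole session.
#' @param window window length (s).
#' @param ... passed to [hrv_features()].
#' @return A data.frame: `window_index` plus the 31 parameter columns and a
#'   `flags` character column (`;`-joined).
#' @export
hrv_features_by_minute <- function(rr, window = 60, ...) {
  wins <- window_rr(rr, window = window)
  rows <- lapply(seq_along(wins), function(k) {
    f <- hrv_features(wins[[k]], ...)
    d <- as.data.frame(as.list(f))
    d$window_index <- k - 1L
    d$flags <- paste(attr(f, "flags"), collapse = ";")
    d
  })
  out <- do.call(rbind, rows)
  out[, c("window_index", hrv_parameter_names(), "flags")]
}
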