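#' Poincare-plot dispersion parameters
#'
#' `SD1` is the sample SD of `(RR[n+1] - RR[n]) / sqrt(2)` and `SD2` the
#' sample SD of `(RR[n+1] + RR[n]) / sqrt(2)`, both computed about their
#' means: the dispersion of the lag-1 return map perpendicular to and along
#' the identity line.
#'
#' @param rr an [rr_series] or numeric RR vector (ms).
#' @return Named numeric vector `c(SD1, SD2)` (ms).
#' @export
hrv_poincare <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 3L)
    stop("Poincare parameters need at least 3 RR intervals", call. = FALSE)
  a <- utils::head(x, -1); b <- utils::tail(x, -1)
  c(SD1 = stats::sd((b - a) / sqrt(2)), SD2 = stats::sd((b + a) / sqrt(2)))
}

embed_series <- function(x, m, delay = 1L) {
  n <- length(x) - (m - 1L) * delay
  if (n < 1L) stop("series too short for embedding dimension ", m, call. = FALSE)
  E <- sapply(seq_len(m), function(j) x[(1:n) + (j - 1L) * delay])
  if (is.null(dim(E))) E <- matrix(E, ncol = m)
  E
}

cheb_dist <- function(E) stats::dist(E, method = "maximum")

#' Approximate and sample entropy
#'
#' Template-matching irregularity measures with Chebyshev distance.
#' `ApEn = Phi_m - Phi_(m+1)` with self-matches included; `SampEn =
#' -ln(A/B)` with self-matches excluded, where `B` and `A` count template
#' matches of length `m` and `m+1`.  A constant window (zero tolerance) is
#' returned as 0 for both with a `"constant"` flag; `A = 0` yields the
#' conventional upper bound `-ln(2 / ((N-m-1)(N-m)))` with a flag.
#'
#' @param rr an [rr_series] or numeric RR vector (ms).
#' @param m embedding (template) length, default 2.
#' @param r tolerance; default `0.2 * sd(rr)`.
#' @return Named numeric vector `c(ApEn, SampEn)` with a `flags` attribute.
#' @export
hrv_entropy <- function(rr, m = 2L, r = NULL) {
  x <- rr_values(rr)
  n <- length(x)
  if (n < m + 2L)
    stop("entropy needs at least m + 2 RR intervals", call. = FALSE)
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  flags <- character(0)
  if (r <= 0) {
    out <- c(ApEn = 0, SampEn = 0)
    attr(out, "flags") <- "constant"
    return(out)
  }
  phi <- function(mm) {
    D <- as.matrix(cheb_dist(embed_series(x, mm)))
    cnt <- rowSums(D <= r)               # diagonal is 0, so self-matches count
    mean(log(cnt / length(cnt)))
  }
  apen <- phi(m) - phi(m + 1L)
  # SampEn restricts the m-templates to the first N - m so every template
  # has an (m+1)-length extension; self-matches are excluded
  Em <- embed_series(x, m)[seq_len(n - m), , drop = FALSE]
  B <- sum(cheb_dist(Em) <= r)
  A <- sum(cheb_dist(embed_series(x, m + 1L)) <= r)
  if (A == 0 || B == 0) {
    sampen <- -log(2 / ((n - m - 1) * (n - m)))
    flags <- c(flags, "sampen-max")
  } else sampen <- -log(A / B)
  out <- c(ApEn = apen, SampEn = sampen)
  attr(out, "flags") <- flags
  out
}

#' Detrended fluctuation analysis exponents
#'
#' The mean-centered RR series is integrated; for each box size `n` the RMS
#' residual about per-box least-squares lines gives `F(n)`; the scaling
#' exponents are the slopes of `log F(n)` vs `log n` over boxes 4-16
#' (`Alpha1`, short-term) and 17-64 (`Alpha2`, long-term).  `Alpha2` is
#' `NA` (flagged) when the series is shorter than twice the smallest
#' long-term box, as in ordinary one-minute windows.
#'
#' @param rr an [rr_series] or numeric RR vector (ms).
#' @return Named numeric vector `c(Alpha1, Alpha2)` with a `flags` attribute.
#' @export
hrv_dfa <- function(rr) {
  x <- rr_values(rr)
  N <- length(x)
  if (N < 20L) stop("DFA needs at least 20 RR intervals", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("DFA is undefined for a zero-fluctuation series", call. = FALSE)
  y <- cumsum(x - mean(x))
  fluct <- function(nbox) {
    k <- N %/% nbox
    if (k < 2L) return(NA_real_)
    res2 <- 0
    tt <- seq_len(nbox)
    sxx <- sum((tt - mean(tt))^2)
    for (b in seq_len(k)) {
      seg <- y[((b - 1L) * nbox + 1L):(b * nbox)]
      beta <- sum((tt - mean(tt)) * (seg - mean(seg))) / sxx
      fit <- mean(seg) + beta * (tt - mean(tt))
      res2 <- res2 + sum((seg - fit)^2)
    }
    sqrt(res2 / (k * nbox))
  }
  slope_of <- function(sizes) {
    Fn <- vapply(sizes, fluct, numeric(1))
    ok <- is.finite(Fn) & Fn > 0
    if (sum(ok) < 3L) return(NA_real_)
    stats::coef(stats::lm(log(Fn[ok]) ~ log(sizes[ok])))[[2]]
  }
  a1 <- slope_of(4:16)
  a2 <- if (N >= 34L) slope_of(17:64) else NA_real_
  out <- c(Alpha1 = a1, Alpha2 = a2)
  attr(out, "flags") <- if (is.na(a2)) "alpha2-short-series" else character(0)
  out
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Correlation sums `C(r)` are computed over a log-spaced radius grid in a
#' delay embedding (dimension `m`, delay 1, Euclidean distance); `D2` is
#' the least-squares slope of `log C(r)` vs `log r` over the central
#' portion of the usable radius range (radii where `0 < C(r) < 1`).
#'
#' @param rr an [rr_series] or numeric RR vector (ms).
#' @param m embedding dimension, default 10.
#' @param n_radii size of the radius grid.
#' @return Scalar `D2` with a `flags` attribute (`"degenerate"` gives 0).
#' @export
hrv_d2 <- function(rr, m = 10L, n_radii = 24L) {
  x <- rr_values(rr)
  if (length(x) < m + 10L)
    stop("correlation dimension needs at least m + 10 RR intervals", call. = FALSE)
  if (stats::sd(x) == 0) {
    out <- 0; attr(out, "flags") <- "degenerate"; return(out)
  }
  E <- embed_series(x, m)
  d <- stats::dist(E)
  dpos <- d[d > 0]
  if (!length(dpos)) { out <- 0; attr(out, "flags") <- "degenerate"; return(out) }
  r_lo <- stats::quantile(dpos, 0.05); r_hi <- max(dpos)
  radii <- exp(seq(log(r_lo), log(r_hi), length.out = n_radii))
  Cr <- vapply(radii, function(r) mean(d <= r), numeric(1))
  ok <- Cr > 0 & Cr < 1
  if (sum(ok) < 3L) { out <- 0; attr(out, "flags") <- "no-scaling-region"; return(out) }
  # central portion of the usable log-radius range
  lr <- log(radii[ok]); lc <- log(Cr[ok])
  mid <- lr >= stats::quantile(lr, 0.15) & lr <= stats::quantile(lr, 0.70)
  if (sum(mid) < 3L) mid <- rep(TRUE, length(lr))
  out <- stats::coef(stats::lm(lc[mid] ~ lr[mid]))[[2]]
  attr(out, "flags") <- character(0)
  out
}

#' Correlation sum oracle surface
#'
#' Exact correlation sums (fraction of embedded point pairs within radius
#' `r`) used by [hrv_d2()]; exported so tests can compare the vectorized
#' path against an independent pairwise count.
#'
#' @inheritParams hrv_d2
#' @param radii radius grid.
#' @return Numeric vector of `C(r)` values.
#' @export
correlation_sums <- function(rr, radii, m = 10L) {
  x <- rr_values(rr)
  d <- stats::dist(embed_series(x, m))
  vapply(radii, function(r) mean(d <= r), numeric(1))
}

#' Recurrence quantification analysis
#'
#' The series is delay-embedded (dimension `m`, delay 1); points closer
#' than `threshold` (Euclidean) are recurrent.  The line of identity is
#' excluded everywhere.  `REC` is the percentage of recurrent points;
#' diagonal lines of length >= `lmin` give `DET` (percentage of recurrent
#' points on such lines), `Lmean`, `Lmax` and `ShanEn` (Shannon entropy,
#' nats, of the line-length distribution).
#'
#' @param rr an [rr_series] or numeric RR vector (ms).
#' @param m embedding dimension, default 10.
#' @param delay embedding delay (beats).
#' @param threshold recurrence radius; default `sqrt(m) * sd(rr)`, the
#'   conventional SD-scaled radius for embedded physiological series.
#' @param lmin minimum diagonal line length, default 2.
#' @return Named numeric vector `c(Lmean, Lmax, REC, DET, ShanEn)` with a
#'   `flags` attribute (`"no-recurrence"` when the plot is empty).
#' @export
hrv_rqa <- function(rr, m = 10L, delay = 1L, threshold = NULL, lmin = 2L) {
  x <- rr_values(rr)
  if (length(x) < m + lmin)
    stop("RQA needs at least m + lmin RR intervals", call. = FALSE)
  if (is.null(threshold)) threshold <- sqrt(m) * stats::sd(x)
  E <- embed_series(x, m, delay)
  if (is.null(dim(E))) E <- matrix(E, ncol = m)
  M <- nrow(E)
  R <- as.matrix(stats::dist(E)) <= threshold
  diag(R) <- FALSE                       # exclude the line of identity
  n_rec <- sum(R)
  total <- M * (M - 1)
  if (n_rec == 0) {
    out <- c(Lmean = 0, Lmax = 0, REC = 0, DET = 0, ShanEn = 0)
    attr(out, "flags") <- "no-recurrence"
    return(out)
  }
  lens <- integer(0)
  for (k in seq_len(M - 1L)) {          # off-diagonals above the LOI
    v <- R[cbind(seq_len(M - k), seq_len(M - k) + k)]
    runs <- rle(v)
    lens <- c(lens, runs$lengths[runs$values])
  }
  lens <- c(lens, lens)                  # the plot is symmetric
  keep <- lens >= lmin
  det_pts <- sum(lens[keep])
  if (any(keep)) {
    p <- table(lens[keep]) / sum(keep)
    shan <- -sum(p * log(p))
    lmean <- mean(lens[keep]); lmax <- max(lens[keep])
  } else { shan <- 0; lmean <- 0; lmax <- 0 }
  out <- c(Lmean = lmean, Lmax = lmax,
           REC = 100 * n_rec / total,
           DET = 100 * det_pts / n_rec,
           ShanEn = shan)
  attr(out, "flags") <- character(0)
  out
}
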