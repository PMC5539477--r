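#' Train-fold z-score scaler
#'
#' Per-feature mean and sample SD are fit on training rows only and applied
#' unchanged to validation/test rows, so no information leaks across the
#' subject partition.  Zero-variance training features are centered with
#' scale 1 and flagged.
#'
#' @param train numeric matrix/data.frame of training rows.
#' @return A `zscaler` (list with `center`, `scale`, `flags`).
#' @export
zscore_fit <- function(train) {
  m <- as.matrix(train)
  if (nrow(m) == 0L) stop("empty training set", call. = FALSE)
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  flags <- colnames(m)[!is.na(scale) & scale == 0]
  scale[is.na(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale, flags = flags),
            class = "zscaler")
}

#' @rdname zscore_fit
#' @param scaler a fitted `zscaler`.
#' @param x rows to transform.
#' @export
zscore_apply <- function(scaler, x) {
  m <- as.matrix(x)
  sweep(sweep(m, 2L, scaler$center[colnames(m) %||% seq_len(ncol(m))], `-`),
        2L, scaler$scale[colnames(m) %||% seq_len(ncol(m))], `/`)
}

#' @rdname zscore_fit
#' @export
zscore_invert <- function(scaler, x) {
  m <- as.matrix(x)
  sweep(sweep(m, 2L, scaler$scale[colnames(m) %||% seq_len(ncol(m))], `*`),
        2L, scaler$center[colnames(m) %||% seq_len(ncol(m))], `+`)
}
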