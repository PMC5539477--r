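#' Pooled confusion matrix
#'
#' @param truth,predicted label vectors (same length); `levels` fixes the
#'   class order (default: recognition labels present in `truth`).
#' @return Integer matrix, rows = ground truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) levels <- intersect(recognition_labels(), unique(truth))
  tab <- table(factor(truth, levels = levels), factor(predicted, levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(truth = levels, predicted = levels))
  m
}

#' Recall, precision and overall accuracy of a confusion table
#'
#' `recall_c = 100 * diag_c / rowsum_c`, `precision_c = 100 * diag_c /
#' colsum_c` and `accuracy = 100 * trace / total`, all in percent.  A
#' class never predicted has undefined precision, returned as `NA` with a
#' flag.
#'
#' @param counts square matrix of non-negative integer counts
#'   (rows = ground truth, columns = predicted).
#' @return List with `recall`, `precision` (named vectors, %), `accuracy`
#'   (%), and `flags`.
#' @export
confusion_metrics <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(m) == 0) stop("all-zero confusion matrix", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m)
  recall <- ifelse(rs > 0, 100 * diag(m) / rs, NA_real_)
  precision <- ifelse(cs > 0, 100 * diag(m) / cs, NA_real_)
  names(recall) <- rownames(m); names(precision) <- colnames(m)
  flags <- character(0)
  if (anyNA(precision)) flags <- c(flags, "undefined-precision")
  if (anyNA(recall)) flags <- c(flags, "undefined-recall")
  list(recall = recall, precision = precision,
       accuracy = 100 * sum(diag(m)) / sum(m), flags = flags)
}
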