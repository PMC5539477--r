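#' Mann-Whitney U test
#'
#' Rank-sum location test between two independent samples.  `U` is the
#' count of (x, y) pairs with x preceding y (ties counted half); the
#' two-sided p-value comes from exact enumeration when both samples have
#' at most 8 observations and no ties, and otherwise from the
#' tie-corrected normal approximation with continuity correction
#' (delegated to [stats::wilcox.test()]).
#'
#' @param x,y numeric samples.
#' @return List with `U` and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  exact <- n <= 8 && m <= 8 && !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  if (is.na(p)) p <- 1
  list(U = U, p = p)
}

#' Rank HRV features by class-pair separability
#'
#' For each of the 31 HRV parameters two Mann-Whitney p-values are
#' computed on the training minutes: SI vs ST and WK vs AS — the two
#' activity pairs an accelerometer confuses.  Features are ranked by the
#' *larger* of the two p-values ascending (a useful feature must separate
#' both confused pairs); ties break by canonical parameter order.  The
#' top `k` names are returned.
#'
#' @param train per-minute training data.frame (needs `activity` and the
#'   31 HRV columns).
#' @param k number of features to return (0 gives an empty selection; 31
#'   returns the full ranked list).
#' @return Character vector of `k` feature names, best first, with the
#'   full ranking in attribute `ranking` and scores in `score`.
#' @export
select_hrv_features <- function(train, k) {
  stopifnot(k >= 0, k <= 31)
  need <- c("SI", "ST", "WK", "AS")
  if (!all(need %in% train$activity))
    stop("training data must contain all of SI, ST, WK, AS", call. = FALSE)
  feats <- hrv_parameter_names()
  score <- vapply(feats, function(f) {
    v <- train[[f]]
    p1 <- mann_whitney_u(v[train$activity == "SI"], v[train$activity == "ST"])$p
    p2 <- mann_whitney_u(v[train$activity == "WK"], v[train$activity == "AS"])$p
    max(p1, p2)
  }, numeric(1))
  ord <- order(score, seq_along(feats))
  ranking <- feats[ord]
  out <- utils::head(ranking, k)
  attr(out, "ranking") <- ranking
  attr(out, "score") <- score[ord]
  out
}
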