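#' Leave-one-subject-out fold plans
#'
#' Recognition folds hold out one test subject and one validation subject
#' (the next subject in id order, wrapping around), training on the
#' remainder; every subject is the test subject exactly once.  EE folds
#' have no validation subject: all other subjects train.
#'
#' @param subject_ids unique subject identifiers (>= 3 for recognition).
#' @return List of folds, each with `test`, `validation` (recognition
#'   only) and `train` subject-id vectors.
#' @export
loso_folds <- function(subject_ids) {
  ids <- unique(subject_ids)
  n <- length(ids)
  if (n < 3L) stop("recognition folds need at least 3 subjects", call. = FALSE)
  lapply(seq_len(n), function(i) {
    v <- ids[(i %% n) + 1L]
    list(test = ids[i], validation = v, train = setdiff(ids, c(ids[i], v)))
  })
}

#' @rdname loso_folds
#' @export
ee_folds <- function(subject_ids) {
  ids <- unique(subject_ids)
  if (length(ids) < 2L) stop("EE folds need at least 2 subjects", call. = FALSE)
  lapply(ids, function(s) list(test = s, train = setdiff(ids, s)))
}

scenario_columns <- function(scenario) {
  switch(as.character(scenario),
         "1" = list(base = feature_columns("imu"), selected = 0L),
         "2" = list(base = feature_columns("imu_ecg"), selected = 0L),
         "3" = list(base = feature_columns("imu"), selected = NA_integer_),
         "4" = list(base = feature_columns("ecg"), selected = 0L),
         "5" = list(base = character(0), selected = NA_integer_),
         stop("scenario must be 1..5", call. = FALSE))
}

#' Run one recognition scenario under leave-one-subject-out CV
#'
#' For every fold: the z-scaler and (scenarios III/V) the Mann-Whitney
#' feature ranking are fit on the training subjects only; the classifier
#' hyperparameters — and the number of selected HRV features — are chosen
#' by accuracy on the validation subject (ties resolve to the smallest
#' hyperparameters and fewest features); the winner is refit on the
#' training subjects and applied to the test subject.  REST minutes are
#' excluded: recognition runs on the five ambulatory labels.
#'
#' @param minutes per-minute data.frame ([cohort_minutes()] /
#'   [simulate_feature_cohort()] layout).
#' @param scenario 1 = IMU only, 2 = IMU + ECG, 3 = IMU + selected ECG,
#'   4 = ECG only, 5 = selected ECG only.
#' @param classifier `"lsvm"`, `"rbfsvm"`, `"knn"` or `"lda"`.
#' @param grid hyperparameter grid (default [default_grid()]).
#' @param k_grid candidate selected-feature counts for scenarios III/V.
#' @return An `evaluation_report`: list with `scenario`, `classifier`,
#'   `fold_accuracy`, `accuracy_mean`, `accuracy_sd`, pooled `confusion`,
#'   `metrics`, per-fold `chosen` (hyperparameters, selected features),
#'   `n_pooled`.
#' @export
run_loso <- function(minutes, scenario = 1, classifier = "lda",
                     grid = default_grid(classifier), k_grid = 1:8) {
  data <- minutes[minutes$activity %in% recognition_labels(), , drop = FALSE]
  labs <- recognition_labels()
  sc <- scenario_columns(scenario)
  select_k <- is.na(sc$selected)
  folds <- loso_folds(unique(data$subject_id))

  fold_acc <- numeric(0)
  chosen <- list()
  pooled_truth <- character(0); pooled_pred <- character(0)
  for (f in folds) {
    tr <- data[data$subject_id %in% f$train, ]
    va <- data[data$subject_id == f$validation, ]
    te <- data[data$subject_id == f$test, ]
    if (!all(labs %in% tr$activity)) {
      warning("fold skipped: training subjects miss a class")
      next
    }
    ranking <- if (select_k) select_hrv_features(tr, 31L) else NULL
    ks <- if (select_k) k_grid else 0L

    best <- NULL
    for (k in ks) {
      cols <- c(sc$base, if (select_k) utils::head(ranking, k))
      if (!length(cols)) next
      scaler <- zscore_fit(tr[, cols, drop = FALSE])
      xtr <- zscore_apply(scaler, tr[, cols, drop = FALSE])
      xva <- zscore_apply(scaler, va[, cols, drop = FALSE])
      for (params in grid) {
        fit <- fit_classifier(classifier, xtr, tr$activity, params)
        acc <- mean(as.character(predict_labels(fit, xva)) == va$activity)
        if (is.null(best) || acc > best$acc + 1e-12)
          best <- list(acc = acc, k = k, params = params, cols = cols)
      }
    }
    scaler <- zscore_fit(tr[, best$cols, drop = FALSE])
    fit <- fit_classifier(classifier,
                          zscore_apply(scaler, tr[, best$cols, drop = FALSE]),
                          tr$activity, best$params)
    pred <- predict_labels(fit, zscore_apply(scaler, te[, best$cols, drop = FALSE]))
    fold_acc <- c(fold_acc, 100 * mean(as.character(pred) == te$activity))
    pooled_truth <- c(pooled_truth, te$activity)
    pooled_pred <- c(pooled_pred, as.character(pred))
    chosen[[length(chosen) + 1L]] <-
      list(test = f$test, validation = f$validation,
           k = best$k, params = best$params,
           features = best$cols, validation_accuracy = 100 * best$acc)
  }
  conf <- confusion_matrix(pooled_truth, pooled_pred, levels = labs)
  structure(list(scenario = scenario, classifier = classifier,
                 fold_accuracy = fold_acc,
                 accuracy_mean = mean(fold_acc), accuracy_sd = stats::sd(fold_acc),
                 confusion = conf, metrics = confusion_metrics(conf),
                 chosen = chosen, n_pooled = length(pooled_truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<scenario %s, %s: accuracy %.2f%% (SD %.2f) over %d folds, %d pooled minutes>\n",
              x$scenario, x$classifier, x$accuracy_mean, x$accuracy_sd,
              length(x$fold_accuracy), x$n_pooled))
  invisible(x)
}
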