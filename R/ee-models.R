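#' Ordinary least squares with coefficient inference
#'
#' Fits `y = X b + e` via the QR decomposition (numerically identical to
#' the normal-equations closed form `(X'X)^-1 X'y`, which the test suite
#' asserts).  Returns the coefficient vector, residual variance, t-based
#' per-coefficient p-values and R^2.  Rank deficiency is an error naming
#' the collinear columns.
#'
#' @param X design matrix including an intercept column.
#' @param y response (kcal/min).
#' @return A `regression_model`: list with `coefficients`, `se`, `p`,
#'   `sigma2`, `r_squared`, `df_residual`, `variables`.
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X))
    stop("need more rows than columns to fit", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  Rinv <- backsolve(qr.R(qrx), diag(ncol(X)))
  XtXinv <- matrix(0, ncol(X), ncol(X))
  XtXinv[qrx$pivot, qrx$pivot] <- Rinv %*% t(Rinv)
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 p = stats::setNames(as.numeric(p), colnames(X)),
                 sigma2 = sigma2, df_residual = df,
                 r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
                 variables = setdiff(colnames(X), "(Intercept)")),
            class = "regression_model")
}

#' @rdname ols_fit
#' @param object a `regression_model`.
#' @param newdata data.frame/matrix with the model's variable columns.
#' @param ... unused.
#' @export
predict.regression_model <- function(object, newdata, ...) {
  m <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  as.numeric(cbind(1, m) %*% object$coefficients[c("(Intercept)", object$variables)])
}

#' Backward elimination at the 5% level
#'
#' Starting from the full candidate model, repeatedly drops the variable
#' with the largest coefficient p-value while any p >= `alpha`, refitting
#' each time; the intercept is always kept.  If every variable is
#' eliminated the intercept-only model is returned with a warning.
#'
#' @param data data.frame holding `response` and candidate columns.
#' @param response response column name.
#' @param candidates candidate variable names.
#' @param alpha retention threshold on the coefficient p-value (a variable
#'   with p < alpha stays).
#' @return Character vector of surviving variable names (attribute `model`
#'   holds the final `regression_model`).
#' @export
select_variables <- function(data, response, candidates, alpha = 0.05) {
  stopifnot(length(candidates) >= 1)
  y <- data[[response]]
  vars <- candidates
  # guard against exactly collinear candidates before the first full fit
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, vars, drop = FALSE]))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    vars <- setdiff(vars, drop_cols)
  }
  repeat {
    X <- cbind(`(Intercept)` = 1, as.matrix(data[, vars, drop = FALSE]))
    fit <- ols_fit(X, y)
    pv <- fit$p[vars]
    if (!length(pv) || max(pv) < alpha) break
    vars <- setdiff(vars, names(which.max(pv)))
    if (!length(vars)) {
      warning("backward elimination removed every candidate; intercept-only model")
      fit <- ols_fit(matrix(1, nrow(data), 1,
                            dimnames = list(NULL, "(Intercept)")), y)
      break
    }
  }
  structure(vars, model = fit)
}

#' Fit an energy-expenditure model family on one training fold
#'
#' The candidate pool is always height, weight and the four IMU features
#' (6 variables); `data_type = "imu_ecg"` adds the 31 HRV parameters (37
#' variables).  `model_type = "single"` fits one regression over all six
#' activities; `"specific"` fits one model on static minutes (SI, ST,
#' REST) and one on dynamic minutes (WK, AS, RU).  Each model is built by
#' [select_variables()] (p < 0.05 backward elimination) followed by the
#' final OLS fit, on training minutes only.
#'
#' @param train training minutes (all activities, `ee_kcal_per_min` column).
#' @param data_type `"imu"` or `"imu_ecg"`.
#' @param model_type `"single"` or `"specific"`.
#' @param alpha selection threshold.
#' @return An `ee_fit`: list of `regression_model`s keyed by category
#'   (`all`, or `static` + `dynamic`).
#' @export
fit_ee <- function(train, data_type = c("imu", "imu_ecg"),
                   model_type = c("single", "specific"), alpha = 0.05) {
  data_type <- match.arg(data_type); model_type <- match.arg(model_type)
  pool <- feature_columns(data_type, anthropometrics = TRUE)
  fit_one <- function(d) {
    if (!nrow(d)) stop("a model category has no training minutes", call. = FALSE)
    vars <- select_variables(d, "ee_kcal_per_min", pool, alpha = alpha)
    attr(vars, "model")
  }
  models <- if (model_type == "single") {
    list(all = fit_one(train))
  } else {
    list(static = fit_one(train[train$activity %in% static_labels(), ]),
         dynamic = fit_one(train[train$activity %in% dynamic_labels(), ]))
  }
  structure(list(models = models, data_type = data_type,
                 model_type = model_type),
            class = "ee_fit")
}

#' Per-activity RMSE of an EE fit on test minutes
#'
#' Activity-specific fits route each test minute by the category of its
#' ground-truth label (EE is evaluated given known activity).
#'
#' @param fit an `ee_fit`.
#' @param test test minutes.
#' @return Named numeric vector: RMSE (kcal/min) per activity present in
#'   `test`, `NA` for an empty activity cell.
#' @export
evaluate_ee <- function(fit, test) {
  pred <- numeric(nrow(test))
  if (fit$model_type == "single") {
    pred <- stats::predict(fit$models$all, test)
  } else {
    for (cat in c("static", "dynamic")) {
      sel <- activity_category(test$activity) == cat
      if (any(sel))
        pred[sel] <- stats::predict(fit$models[[cat]], test[sel, , drop = FALSE])
    }
  }
  acts <- intersect(activity_labels(), unique(test$activity))
  vapply(stats::setNames(acts, acts), function(a) {
    sel <- test$activity == a
    if (!any(sel)) return(NA_real_)
    sqrt(mean((pred[sel] - test$ee_kcal_per_min[sel])^2))
  }, numeric(1))
}

#' Cross-validated comparison of the four EE model families
#'
#' Runs leave-one-subject-out folds (12 training subjects, 1 test; no
#' validation subject) for each requested (data type, model type)
#' combination, collecting the per-fold, per-activity RMSE table.
#'
#' @param minutes per-minute table including REST.
#' @param specs data.frame of the model specs to run; defaults to the four
#'   canonical combinations Model I-IV.
#' @param alpha selection threshold.
#' @return An `ee_report`: list with `rmse` (long data.frame: `model`,
#'   `data_type`, `model_type`, `fold`, `activity`, `rmse`), `fits`
#'   (models of the first fold per spec), `n_models` (fitted regressions
#'   per spec).
#' @export
run_ee_cv <- function(minutes, specs = ee_model_specs(), alpha = 0.05) {
  folds <- ee_folds(unique(minutes$subject_id))
  rows <- list(); fits1 <- list(); n_models <- integer(0)
  for (i in seq_len(nrow(specs))) {
    dt <- specs$data_type[i]; mt <- specs$model_type[i]
    nm <- 0L
    for (k in seq_along(folds)) {
      f <- folds[[k]]
      fit <- fit_ee(minutes[minutes$subject_id %in% f$train, ],
                    data_type = dt, model_type = mt, alpha = alpha)
      nm <- nm + length(fit$models)
      if (k == 1L) fits1[[specs$model[i]]] <- fit
      rmse <- evaluate_ee(fit, minutes[minutes$subject_id == f$test, ])
      rows[[length(rows) + 1L]] <- data.frame(
        model = specs$model[i], data_type = dt, model_type = mt,
        fold = k, activity = names(rmse), rmse = as.numeric(rmse),
        stringsAsFactors = FALSE)
    }
    n_models <- c(n_models, stats::setNames(nm, specs$model[i]))
  }
  structure(list(rmse = do.call(rbind, rows), fits = fits1,
                 n_models = n_models),
            class = "ee_report")
}

#' @rdname run_ee_cv
#' @export
ee_model_specs <- function() {
  data.frame(model = c("I", "II", "III", "IV"),
             data_type = c("imu", "imu_ecg", "imu", "imu_ecg"),
             model_type = c("single", "single", "specific", "specific"),
             stringsAsFactors = FALSE)
}

#' Two-way fixed-effects ANOVA on a balanced 2x2 layout
#'
#' Classical sums-of-squares decomposition (factors A, B, interaction,
#' error) for a balanced two-factor design — here data type (IMU vs
#' IMU+ECG) by model type (single vs activity-specific) with the
#' fold-by-activity RMSE cells as replicates.
#'
#' @param values numeric response (e.g. RMSE per fold x activity cell).
#' @param a,b factor levels of the two effects (each must have exactly two
#'   levels with equal cell sizes).
#' @return Data.frame with rows A, B, A:B, Residuals and columns `df`,
#'   `ss`, `ms`, `F`, `p`.
#' @export
anova_2x2 <- function(values, a, b) {
  a <- factor(a); b <- factor(b)
  if (nlevels(a) != 2L || nlevels(b) != 2L)
    stop("both factors must have exactly two levels", call. = FALSE)
  tab <- table(a, b)
  if (length(unique(as.integer(tab))) != 1L)
    stop("unbalanced layout: cell sizes differ", call. = FALSE)
  n <- unique(as.integer(tab)); N <- length(values)
  grand <- mean(values)
  ma <- tapply(values, a, mean); mb <- tapply(values, b, mean)
  mab <- tapply(values, interaction(a, b), mean)
  ss_a <- sum(table(a) * (ma - grand)^2)
  ss_b <- sum(table(b) * (mb - grand)^2)
  cell_counts <- as.integer(table(interaction(a, b)))
  ss_cells <- sum(cell_counts * (mab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cells
  df <- c(1L, 1L, 1L, N - 4L)
  ss <- c(ss_a, ss_b, ss_ab, ss_err)
  ms <- ss / df
  # zero effect sum-of-squares is F = 0 by convention, even in a flat table
  Fv <- c(ifelse(ms[1:3] == 0, 0, ms[1:3] / ms[4]), NA)
  p <- c(stats::pf(Fv[1:3], 1, df[4], lower.tail = FALSE), NA)
  data.frame(term = c("A", "B", "A:B", "Residuals"),
             df = df, ss = ss, ms = ms, F = Fv, p = p,
             stringsAsFactors = FALSE)
}
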