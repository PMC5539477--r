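#' Linear discriminant analysis (pooled-covariance closed form)
#'
#' Multi-class LDA fitted directly from the class means and the pooled
#' within-class covariance: the discriminant score of class c is
#' `x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c` with `pi_c` the training
#' class proportions.  A small ridge (`reg * mean diagonal`) stabilises
#' the pooled covariance when features are nearly collinear.
#'
#' @param x training feature matrix.
#' @param y training labels (factor or character).
#' @param reg ridge fraction added to the pooled covariance diagonal.
#' @return An `lda_model`.
#' @export
lda_fit <- function(x, y, reg = 1e-8) {
  x <- as.matrix(x); y <- factor(y)
  classes <- levels(y)
  p <- ncol(x)
  mu <- matrix(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                      numeric(p)),
               nrow = length(classes), ncol = p, byrow = TRUE)
  Sp <- matrix(0, p, p)
  for (cl in classes) {
    xc <- x[y == cl, , drop = FALSE]
    if (nrow(xc) > 1L)
      Sp <- Sp + crossprod(sweep(xc, 2L, colMeans(xc)))
  }
  Sp <- Sp / (nrow(x) - length(classes))
  Sp <- Sp + diag(reg * mean(diag(Sp)) + 1e-12, p)
  Sinv <- solve(Sp)
  structure(list(classes = classes, mu = mu, Sinv = Sinv,
                 log_prior = log(as.numeric(table(y)[classes]) / length(y))),
            class = "lda_model")
}

#' @rdname lda_fit
#' @param object fitted `lda_model`.
#' @param newdata feature matrix to classify.
#' @param ... unused.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  W <- object$Sinv %*% t(object$mu)                    # p x C
  scores <- x %*% W -
    matrix(0.5 * colSums(t(object$mu) * W), nrow(x), length(object$classes),
           byrow = TRUE) +
    matrix(object$log_prior, nrow(x), length(object$classes), byrow = TRUE)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Fit one of the four recognition classifiers
#'
#' `lsvm`/`rbfsvm` wrap the libsvm C-classification interface (features
#' are already scaled by the fold scaler, so internal scaling is off),
#' `knn` stores the training set for [class::knn()], `lda` uses the
#' closed-form [lda_fit()].
#'
#' @param method one of `"lsvm"`, `"rbfsvm"`, `"knn"`, `"lda"`.
#' @param x training matrix, `y` labels.
#' @param params list of hyperparameters: `cost` (both SVMs), `gamma`
#'   (RBF), `k` (kNN).
#' @return Classifier object with a `predict_labels()`-compatible fit.
#' @export
fit_classifier <- function(method = c("lsvm", "rbfsvm", "knn", "lda"),
                           x, y, params = list()) {
  method <- match.arg(method)
  x <- as.matrix(x); y <- factor(y)
  fit <- switch(method,
    lsvm = e1071::svm(x, y, kernel = "linear",
                      cost = params$cost %||% 1, scale = FALSE),
    rbfsvm = e1071::svm(x, y, kernel = "radial", cost = params$cost %||% 1,
                        gamma = params$gamma %||% (1 / ncol(x)), scale = FALSE),
    knn = list(x = x, y = y, k = params$k %||% 3L),
    lda = lda_fit(x, y))
  structure(list(method = method, fit = fit, levels = levels(y)),
            class = "hrvee_classifier")
}

#' @rdname fit_classifier
#' @param model fitted classifier from [fit_classifier()].
#' @param newdata matrix of rows to classify.
#' @export
predict_labels <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  out <- switch(model$method,
    lsvm = ,
    rbfsvm = stats::predict(model$fit, newdata),
    knn = class::knn(model$fit$x, newdata, model$fit$y, k = model$fit$k),
    lda = stats::predict(model$fit, newdata))
  factor(as.character(out), levels = model$levels)
}

#' Default hyperparameter grids
#'
#' SVM cost spans powers of four from 2^-5 to 2^15, the RBF gamma powers
#' of four from 2^-15 to 2^3, and kNN odd neighbourhood sizes 1-9.  LDA
#' has no tuned hyperparameter.
#'
#' @param method classifier name.
#' @return List of named parameter combinations (possibly a single empty
#'   set), ordered so that validation ties resolve to the smallest values.
#' @export
default_grid <- function(method = c("lsvm", "rbfsvm", "knn", "lda")) {
  method <- match.arg(method)
  switch(method,
    lsvm = lapply(2^seq(-5, 15, by = 2), function(C) list(cost = C)),
    rbfsvm = {
      combos <- expand.grid(cost = 2^seq(-5, 15, by = 2),
                            gamma = 2^seq(-15, 3, by = 2))
      combos <- combos[order(combos$cost, combos$gamma), ]
      lapply(seq_len(nrow(combos)),
             function(i) list(cost = combos$cost[i], gamma = combos$gamma[i]))
    },
    knn = lapply(c(1L, 3L, 5L, 7L, 9L), function(k) list(k = k)),
    lda = list(list()))
}
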