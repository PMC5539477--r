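test_that("OLS equals the normal-equations closed form and recovers exact fits", {
  # exact line through 5 points
  x <- 1:5
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- ols_fit(X, 1 + 2 * x)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-12)

  set.seed(12)
  X <- cbind(`(Intercept)` = 1, matrix(rnorm(50 * 5), ncol = 5,
                                       dimnames = list(NULL, paste0("x", 1:5))))
  beta <- c(0.5, -1, 2, 0, 3, -0.25)
  y <- as.numeric(X %*% beta)
  fit <- ols_fit(X, y)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-9)

  # closed form (X'X)^-1 X'y
  y2 <- y + rnorm(50)
  fit2 <- ols_fit(X, y2)
  closed <- solve(t(X) %*% X) %*% t(X) %*% y2
  expect_equal(unname(fit2$coefficients), as.numeric(closed), tolerance = 1e-9)
  # residual orthogonality X'(y - Xb) = 0
  expect_lt(max(abs(t(X) %*% (y2 - X %*% fit2$coefficients))), 1e-8)
  # p-values agree with the standard linear-model machinery
  lmfit <- lm(y2 ~ X - 1)
  expect_equal(unname(fit2$p), unname(coef(summary(lmfit))[, 4]), tolerance = 1e-9)

  Xdup <- cbind(X, x1_copy = X[, "x1"])
  expect_error(ols_fit(Xdup, y2), "rank deficient.*x1_copy")
})

test_that("backward elimination keeps a planted support and respects the alpha boundary", {
  hits <- 0L
  set.seed(41)
  for (i in 1:100) {
    n <- 500
    d <- as.data.frame(matrix(rnorm(n * 10), ncol = 10))
    names(d) <- paste0("v", 1:10)
    d$y <- 1 + 0.8 * d$v2 - 0.6 * d$v5 + 0.7 * d$v9 + rnorm(n, 0, 1)
    sel <- select_variables(d, "y", paste0("v", 1:10))
    if (all(c("v2", "v5", "v9") %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits, 90L)

  # pure noise: survivors appear at roughly the nominal type-I rate
  set.seed(42)
  survivors <- 0L
  for (i in 1:100) {
    d <- as.data.frame(matrix(rnorm(200 * 10), ncol = 10))
    names(d) <- paste0("v", 1:10)
    d$y <- rnorm(200)
    # most runs end intercept-only, which warns by design
    survivors <- survivors +
      length(suppressWarnings(select_variables(d, "y", paste0("v", 1:10))))
  }
  rate <- survivors / (100 * 10)
  expect_gt(rate, 0.005); expect_lt(rate, 0.15)

  # threshold boundary: a variable is kept iff its p-value is below alpha
  set.seed(7)
  d <- data.frame(v1 = rnorm(40))
  d$y <- 0.3 * d$v1 + rnorm(40)
  p1 <- ols_fit(cbind(`(Intercept)` = 1, v1 = d$v1), d$y)$p[["v1"]]
  expect_identical(as.character(select_variables(d, "y", "v1", alpha = p1 + 1e-6)), "v1")
  expect_warning(dropped <- select_variables(d, "y", "v1", alpha = p1 - 1e-6),
                 "intercept-only")
  expect_length(dropped, 0L)
})

test_that("EE candidate pools and model counts match the four-family design", {
  expect_length(feature_columns("imu_ecg", anthropometrics = TRUE), 37L)
  expect_length(feature_columns("imu", anthropometrics = TRUE), 6L)

  m <- simulate_feature_cohort(n_subjects = 5, seed = 6,
                               schedule = default_schedule(include_rest = TRUE))
  fit <- fit_ee(m[m$subject_id != "S01", ], "imu_ecg", "specific")
  expect_setequal(names(fit$models), c("static", "dynamic"))
  # the static and dynamic fits never share training minutes (routing partition)
  expect_length(intersect(static_labels(), dynamic_labels()), 0L)

  rmse <- evaluate_ee(fit, m[m$subject_id == "S01", ])
  expect_setequal(names(rmse), activity_labels())
  expect_true(all(rmse >= 0, na.rm = TRUE))
})

test_that("a known static generative model is recovered within 3 SE", {
  set.seed(55)
  n <- 500
  d <- data.frame(height = runif(n, 150, 190), weight = runif(n, 45, 95),
                  rms = runif(n, 0, 0.1), sd = runif(n, 0, 0.1),
                  f_dominant = runif(n, 0, 1), energy = runif(n, 0, 3))
  for (p in hrv_parameter_names()) d[[p]] <- rnorm(n)
  d$mHR <- rnorm(n, 75, 9)
  truth <- c(`(Intercept)` = 0.5, height = -0.004, weight = 0.012, mHR = 0.020)
  d$ee_kcal_per_min <- truth[["(Intercept)"]] + truth[["height"]] * d$height +
    truth[["weight"]] * d$weight + truth[["mHR"]] * d$mHR + rnorm(n, 0, 0.05)
  d$activity <- "SI"; d$subject_id <- "S01"
  fit <- fit_ee(d, "imu_ecg", "single")$models$all
  expect_true(all(c("height", "weight", "mHR") %in% fit$variables))
  for (v in c("height", "weight", "mHR"))
    expect_lt(abs(fit$coefficients[[v]] - truth[[v]]), 3 * fit$se[[v]])
})

test_that("RMSE conventions: perfect predictor and mean predictor", {
  set.seed(66)
  d <- data.frame(activity = "WK", subject_id = "S01",
                  rms = rnorm(50, 1, 0.2))
  d$ee_kcal_per_min <- 3 + 2 * d$rms
  fit <- structure(list(models = list(all = structure(
    list(coefficients = c(`(Intercept)` = 3, rms = 2), variables = "rms"),
    class = "regression_model")), model_type = "single"), class = "ee_fit")
  expect_equal(unname(evaluate_ee(fit, d)[["WK"]]), 0, tolerance = 1e-12)

  const_fit <- structure(list(models = list(all = structure(
    list(coefficients = c(`(Intercept)` = mean(d$ee_kcal_per_min)),
         variables = character(0)), class = "regression_model")),
    model_type = "single"), class = "ee_fit")
  pop_sd <- sqrt(mean((d$ee_kcal_per_min - mean(d$ee_kcal_per_min))^2))
  expect_equal(unname(evaluate_ee(const_fit, d)[["WK"]]), pop_sd, tolerance = 1e-12)
})

test_that("two-way ANOVA matches textbook sums of squares and the stats oracle", {
  v <- c(3, 5, 2, 4, 6, 8, 7, 9)
  a <- rep(c("A1", "A2"), each = 4)
  b <- rep(c("B1", "B1", "B2", "B2"), 2)
  out <- anova_2x2(v, a, b)
  o <- brute_anova_2x2(v, a, b)
  expect_equal(out$F[1], o$F_a, tolerance = 1e-9)
  expect_equal(out$F[2], o$F_b, tolerance = 1e-9)
  expect_equal(out$F[3], o$F_ab, tolerance = 1e-9)
  expect_equal(out$df[4], o$df_err)
  # SS decomposition is exact
  expect_equal(sum(out$ss[1:3]) + out$ss[4], sum((v - mean(v))^2), tolerance = 1e-9)

  set.seed(91)
  v2 <- rnorm(80)
  a2 <- rep(c("x", "y"), each = 40)
  b2 <- rep(rep(c("p", "q"), each = 20), 2)
  out2 <- anova_2x2(v2, a2, b2)
  ref <- anova(aov(v2 ~ factor(a2) * factor(b2)))
  expect_equal(out2$F[1:3], ref$`F value`[1:3], tolerance = 1e-9)
  expect_equal(out2$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-9)

  flat <- anova_2x2(rep(2, 8), a, b)
  expect_equal(flat$F[1:3], c(0, 0, 0))
  expect_error(anova_2x2(v[-1], a[-1], b[-1]), "unbalanced")

  # planted pattern: strong data-type shift, weak model-type shift, no interaction
  set.seed(17)
  n <- 78
  dt <- rep(c("imu", "imu_ecg"), each = 2 * n)
  mt <- rep(rep(c("single", "specific"), each = n), 2)
  vals <- rnorm(4 * n, 1.5, 0.4) - 0.5 * (dt == "imu_ecg") - 0.1 * (mt == "specific")
  res <- anova_2x2(vals, dt, mt)
  expect_gt(res$F[1], res$F[2])
  expect_gt(res$p[3], 0.05)
})
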