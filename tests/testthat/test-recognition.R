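test_that("z-scaler: hand case, train moments, exact inverse, no leakage", {
  sc <- zscore_fit(matrix(c(1, 3), ncol = 1, dimnames = list(NULL, "f")))
  expect_equal(as.numeric(zscore_apply(sc, matrix(c(1, 3), ncol = 1))),
               c(-1, 1) / sqrt(2))   # sample SD sqrt(2)
  expect_equal(as.numeric(zscore_apply(sc, matrix(3, ncol = 1))),
               (3 - 2) / sqrt(2))

  set.seed(8)
  tr <- matrix(rnorm(200, 5, 3), ncol = 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  sc2 <- zscore_fit(tr)
  z <- zscore_apply(sc2, tr)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
  expect_equal(zscore_invert(sc2, z), tr, tolerance = 1e-12)

  const <- zscore_fit(cbind(a = c(2, 2, 2)))
  expect_identical(const$flags, "a")
  expect_equal(as.numeric(zscore_apply(const, cbind(a = 2))), 0)
  expect_error(zscore_fit(matrix(numeric(0), 0, 2)), "empty")
})

test_that("Mann-Whitney U: symmetry, exact enumeration and separated-class power", {
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)           # n*m/2
  expect_gt(same$p, 0.95)

  sep <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 2 / 6, tolerance = 1e-12)

  # class-conditional mean-HR statistics of the sitting vs standing windows:
  # P(X < Y) = pnorm(8.66 / 13.74) = 0.74, so the rank test rejects at
  # conventional levels essentially always and at the 0.1% level ~90% of runs
  hits001 <- 0L; hits01 <- 0L
  set.seed(77)
  for (i in 1:100) {
    x <- rnorm(65, 71.23, 9.11)
    y <- rnorm(65, 79.89, 10.29)
    p <- mann_whitney_u(x, y)$p
    if (p < 0.001) hits001 <- hits001 + 1L
    if (p < 0.01) hits01 <- hits01 + 1L
  }
  expect_gte(hits001, 90L)
  expect_gte(hits01, 99L)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("feature ranking degenerates correctly at k = 0 and k = 31", {
  m <- simulate_feature_cohort(n_subjects = 5, seed = 3)
  expect_length(select_hrv_features(m, 0), 0L)
  all31 <- select_hrv_features(m, 31)
  expect_length(all31, 31L)
  expect_setequal(as.character(all31), hrv_parameter_names())
  expect_error(select_hrv_features(m[m$activity != "ST", ], 2), "SI, ST, WK, AS")
})

test_that("closed-form LDA agrees with an established reference implementation", {
  set.seed(19)
  x <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 2.5), ncol = 2),
             matrix(rnorm(100, c(0, 4)), ncol = 2))
  colnames(x) <- c("u", "v")
  y <- rep(c("a", "b", "c"), each = 50)
  mine <- predict_labels(fit_classifier("lda", x, y), x)
  ref <- predict(MASS::lda(x, grouping = y), x)$class
  expect_equal(as.character(mine), as.character(ref))
})

test_that("fold plans are disjoint, exhaustive and sized n-2 / n-1", {
  ids <- sprintf("S%02d", 1:13)
  rec <- loso_folds(ids)
  expect_length(rec, 13L)
  expect_setequal(vapply(rec, `[[`, "", "test"), ids)
  for (f in rec) {
    expect_length(f$train, 11L)
    expect_length(intersect(f$test, f$validation), 0L)
    expect_length(intersect(c(f$test, f$validation), f$train), 0L)
  }
  ee <- ee_folds(ids)
  expect_true(all(vapply(ee, function(f) length(f$train), 0L) == 12L))
  expect_error(loso_folds(c("a", "b")), "3 subjects")
})

test_that("confusion metrics: perfect diagonal, majority baseline, undefined precision", {
  eye <- diag(c(65, 65, 130, 130, 130))
  m <- confusion_metrics(eye)
  expect_equal(unname(m$recall), rep(100, 5))
  expect_equal(unname(m$precision), rep(100, 5))
  expect_equal(m$accuracy, 100)

  # a classifier that always answers the majority class scores its prevalence
  maj <- matrix(0, 5, 5); maj[, 3] <- c(65, 65, 130, 130, 130)
  mm <- confusion_metrics(maj)
  expect_equal(mm$accuracy, 100 * 130 / 520)
  expect_true(is.na(mm$precision[1]))
  expect_true("undefined-precision" %in% mm$flags)
  expect_error(confusion_metrics(matrix(0, 5, 5)), "all-zero")
})

test_that("LOSO recognition: 13 folds, 520 pooled minutes, leakage-free bookkeeping", {
  m <- simulate_feature_cohort(seed = 4, schedule = default_schedule(include_rest = TRUE))
  rep1 <- run_loso(m, scenario = 1, classifier = "lda")
  expect_length(rep1$fold_accuracy, 13L)
  expect_equal(rep1$n_pooled, 520L)
  expect_setequal(vapply(rep1$chosen, `[[`, "", "test"), unique(m$subject_id))
  expect_equal(unname(rowSums(rep1$confusion)),
               unname(table(m$activity[m$activity != "REST"])[rownames(rep1$confusion)]),
               ignore_attr = TRUE)

  rep2 <- run_loso(m, scenario = 2, classifier = "lda")
  expect_true(all(vapply(rep2$chosen, function(ch) length(ch$features), 0L) == 35L))

  # determinism: same data, same result
  rep1b <- run_loso(m, scenario = 1, classifier = "lda")
  expect_identical(rep1$fold_accuracy, rep1b$fold_accuracy)
})

test_that("selected-feature scenarios improve on IMU-only and keep static-vs-walking confusion", {
  m <- simulate_feature_cohort(seed = 2)
  r1 <- run_loso(m, scenario = 1, classifier = "lda")
  r5 <- run_loso(m, scenario = 5, classifier = "lda")
  c1 <- r1$confusion; c5 <- r5$confusion
  # heart-rate features separate the pairs an accelerometer confuses
  expect_lt(c5["SI", "ST"] + c5["ST", "SI"], c1["SI", "ST"] + c1["ST", "SI"])
  expect_lte(c5["WK", "AS"] + c5["AS", "WK"], c1["WK", "AS"] + c1["AS", "WK"])
  # but ECG alone cannot tell quiet standing from walking reliably
  expect_gt(c5["ST", "WK"] + c5["SI", "WK"], 0)
})
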