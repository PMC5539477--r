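test_that("Poincare dispersions: degenerate, alternating and exact RMSSD relation", {
  expect_equal(unname(hrv_poincare(rep(1000, 50))), c(0, 0))

  alt <- rep(c(800, 860), 60)
  expect_lt(abs(hrv_poincare(alt)[["SD1"]] - 60 / sqrt(2)), 0.5)

  set.seed(5)
  x <- rnorm(90, 850, 40)
  f <- hrv_time(x); p <- hrv_poincare(x)
  M <- length(x) - 1
  dbar <- mean(diff(x))
  # sample-SD convention: SD1^2 = (M*RMSSD^2 - M*dbar^2) / (2*(M-1))
  expect_equal(p[["SD1"]]^2,
               (M * f[["RMSSD"]]^2 - M * dbar^2) / (2 * (M - 1)),
               tolerance = 1e-9)
  expect_error(hrv_poincare(c(1, 2)), "3 RR")
})

test_that("entropies: conventions and brute-force oracle equivalence", {
  const <- hrv_entropy(rep(1000, 30))
  expect_equal(as.numeric(const), c(0, 0))
  expect_identical(attr(const, "flags"), "constant")

  # perfectly periodic alternation: every template recurs, SampEn = 0
  per <- hrv_entropy(rep(c(1, 2), 10), m = 2, r = 0.1)
  expect_equal(per[["SampEn"]], 0)

  set.seed(9)
  for (n in c(60, 150)) {
    x <- rnorm(n, 850, 40)
    r <- 0.2 * sd(x)
    f <- hrv_entropy(x, m = 2, r = r)
    expect_equal(f[["ApEn"]], brute_apen(x, 2, r), tolerance = 1e-9)
    expect_equal(f[["SampEn"]], brute_sampen(x, 2, r), tolerance = 1e-9)
  }
  expect_error(hrv_entropy(c(1, 2, 3), m = 2), "m \\+ 2")
})

test_that("DFA exponents recover the theoretical 0.5 / 1.5 scaling", {
  set.seed(13)
  a_white <- a_integrated <- numeric(50)
  for (i in 1:50) {
    w <- rnorm(1000)
    a_white[i] <- hrv_dfa(w)[["Alpha1"]]
    a_integrated[i] <- hrv_dfa(cumsum(rnorm(1000)))[["Alpha1"]]
  }
  expect_gt(mean(a_white), 0.4); expect_lt(mean(a_white), 0.6)
  expect_gt(mean(a_integrated), 1.3); expect_lt(mean(a_integrated), 1.7)

  expect_error(hrv_dfa(rep(1000, 100)), "zero-fluctuation")
  short <- hrv_dfa(rnorm(25, 850, 30))
  expect_true(is.na(short[["Alpha2"]]))
  expect_identical(attr(short, "flags"), "alpha2-short-series")
})

test_that("correlation dimension: degenerate zero, limit cycle near 1, exact correlation sums", {
  z <- hrv_d2(rep(1000, 60))
  expect_equal(as.numeric(z), 0)
  expect_identical(attr(z, "flags"), "degenerate")

  cyc <- 100 * sin(2 * pi * 0.05 * seq_len(600)) + 850
  d2 <- as.numeric(hrv_d2(cyc, m = 10))
  expect_gt(d2, 0.8); expect_lt(d2, 1.2)

  set.seed(23)
  x <- rnorm(80, 850, 40)
  radii <- exp(seq(log(20), log(400), length.out = 10))
  expect_equal(correlation_sums(x, radii, m = 5),
               brute_corr_sums(x, radii, m = 5), tolerance = 1e-12)
})

test_that("recurrence statistics: trivial plots and full oracle equivalence", {
  # all-recurrent plot: REC is exactly 100; DET sits just below because the
  # two corner diagonals of a finite plot have length 1 < lmin
  const <- hrv_rqa(rep(1000, 30), m = 10, threshold = 1)
  expect_equal(const[["REC"]], 100)
  expect_gt(const[["DET"]], 99)
  expect_equal(const[["DET"]], 100 * (420 - 2) / 420, tolerance = 1e-9)

  apart <- hrv_rqa(seq(300, 1900, by = 100), m = 2, threshold = 10)
  expect_equal(apart[["REC"]], 0)
  expect_equal(apart[["DET"]], 0)
  expect_identical(attr(apart, "flags"), "no-recurrence")

  set.seed(31)
  x <- rnorm(12, 850, 40)
  thr <- 60
  f <- hrv_rqa(x, m = 3, delay = 1, threshold = thr, lmin = 2)
  o <- brute_rqa(x, 3, 1, thr, 2)
  expect_equal(unname(f[names(o)]), unname(o), tolerance = 1e-9)

  for (n in c(40, 120)) {
    x <- rnorm(n, 850, 40)
    thr <- sqrt(10) * sd(x)
    f <- hrv_rqa(x, m = 10, threshold = thr)
    o <- brute_rqa(x, 10, 1, thr, 2)
    expect_equal(unname(f[names(o)]), unname(o), tolerance = 1e-9)
  }
})

test_that("the assembled window vector has exactly 31 canonically named values", {
  prof <- base_profile()
  rr <- generate_rr_series("SI", 300, prof, seed = 51)
  f <- hrv_features(window_rr(rr)[[1]])
  expect_length(f, 31L)
  expect_identical(names(f), hrv_parameter_names())

  batch <- hrv_features_by_minute(rr)
  expect_equal(nrow(batch), 5L)

  # constant window: conventions apply and every degenerate stage is flagged
  constf <- hrv_features(rep(1000, 65))
  expect_equal(unname(constf[c("SDRR", "RMSSD", "NN50", "pNN50")]), c(0, 0, 0, 0))
  expect_equal(unname(constf[c("ApEn", "SampEn", "D2")]), c(0, 0, 0))
  expect_equal(unname(constf[["REC"]]), 100)
  expect_gt(constf[["DET"]], 99)
  expect_true(is.na(constf[["Alpha1"]]))
  flags <- attr(constf, "flags")
  expect_true(any(grepl("entropy:constant", flags)))
  expect_true(any(grepl("dfa:unavailable", flags)))
  expect_error(hrv_features(numeric(0)), "empty")
})
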