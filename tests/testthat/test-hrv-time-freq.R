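test_that("time-domain parameters match hand arithmetic", {
  const <- hrv_time(rep(1000, 60))
  expect_equal(unname(const[c("mRR", "SDRR", "mHR", "SDHR", "RMSSD", "NN50", "pNN50")]),
               c(1000, 0, 60, 0, 0, 0, 0))

  f <- hrv_time(c(800, 860, 800, 860))
  expect_equal(unname(f["mRR"]), 830)
  expect_equal(unname(f["RMSSD"]), 60)
  expect_equal(unname(f["NN50"]), 3)
  expect_equal(unname(f["pNN50"]), 75)
  expect_equal(unname(f["mHR"]), mean(60000 / c(800, 860, 800, 860)))

  expect_error(hrv_time(1000), "2 RR")
})

test_that("time-domain parameters equal a one-line-per-formula reference on random windows", {
  set.seed(71)
  for (rep in 1:5) {
    x <- rnorm(80, 850, 50)
    f <- hrv_time(x)
    d <- diff(x)
    expect_equal(unname(f["mRR"]), mean(x), tolerance = 1e-9)
    expect_equal(unname(f["SDRR"]), sd(x), tolerance = 1e-9)
    expect_equal(unname(f["SDHR"]), sd(60000 / x), tolerance = 1e-9)
    expect_equal(unname(f["RMSSD"]), sqrt(mean(d^2)), tolerance = 1e-9)
    expect_equal(unname(f["pNN50"]), 100 * sum(abs(d) > 50) / length(x), tolerance = 1e-9)
  }
})

# helper: beat sequence whose tachogram follows rr_of_t (ms as function of s)
tachogram_series <- function(rr_of_t, duration) {
  t <- 0; tt <- numeric(0); rr <- numeric(0)
  while (t < duration) {
    r <- rr_of_t(t) / 1000
    t <- t + r
    tt <- c(tt, t); rr <- c(rr, r * 1000)
  }
  rr_series(tt, rr)
}

test_that("frequency stage recovers a pure HF tone and flags zero power", {
  rr <- tachogram_series(function(t) 1000 + 50 * sin(2 * pi * 0.25 * t), 120)
  f <- hrv_freq(rr)
  expect_lt(abs(f[["HF"]] - 0.25), 4 / 128 + 1e-9)   # one Welch bin
  expect_gt(f[["pHF"]], 10 * f[["pLF"]])
  expect_equal(f[["nLF"]] + f[["nHF"]], 1, tolerance = 1e-9)

  const <- hrv_freq(rr_from_intervals(rep(1000, 90)))
  expect_lt(const[["pHF"]], 1e-6)
  expect_identical(attr(const, "flags"), "zero-power")
  expect_equal(unname(const[c("nLF", "nHF", "LF_HF")]), c(0, 0, 0))

  expect_error(hrv_freq(rep(1000, 10)), "30 RR")
})

test_that("equal-amplitude LF and HF tones give a balanced band ratio", {
  rr <- tachogram_series(function(t)
    1000 + 40 * sin(2 * pi * 0.10 * t) + 40 * sin(2 * pi * 0.30 * t + 1), 180)
  f <- hrv_freq(rr)
  expect_gt(f[["LF_HF"]], 0.8)
  expect_lt(f[["LF_HF"]], 1.25)
  expect_equal(f[["nLF"]] + f[["nHF"]], 1, tolerance = 1e-9)
  expect_equal(f[["LF_HF"]], f[["nLF"]] / f[["nHF"]], tolerance = 1e-9)
  expect_lt(abs(f[["LF"]] - 0.10), 4 / 128 + 1e-9)
  expect_lt(abs(f[["HF"]] - 0.30), 4 / 128 + 1e-9)
})

test_that("Welch PSD satisfies Parseval for a known tone", {
  fs <- 4; n <- 480
  x <- 30 * sin(2 * pi * 0.2 * (0:(n - 1)) / fs)
  sp <- hrvee:::welch_psd(x, fs, nseg = 128)
  total <- hrvee:::trapz(sp$freq, sp$psd)
  expect_lt(abs(total - 30^2 / 2) / (30^2 / 2), 0.05)
})

test_that("relative band powers sum to 100 under the band-limited convention", {
  prof <- base_profile()
  rr <- generate_rr_series("SI", 120, prof, seed = 41)
  f <- hrv_freq(window_rr(rr)[[1]])
  expect_equal(f[["prcVLF"]] + f[["prcLF"]] + f[["prcHF"]], 100, tolerance = 1e-9)
})

test_that("linear time-domain and Poincare parameters scale with the RR series", {
  set.seed(17)
  x <- rnorm(100, 900, 60)
  c_scale <- 1.7
  f1 <- hrv_time(x); f2 <- hrv_time(c_scale * x)
  for (p in c("mRR", "SDRR", "RMSSD"))
    expect_equal(f2[[p]], c_scale * f1[[p]], tolerance = 1e-9)
  p1 <- hrv_poincare(x); p2 <- hrv_poincare(c_scale * x)
  expect_equal(unname(p2), c_scale * unname(p1), tolerance = 1e-9)
})
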