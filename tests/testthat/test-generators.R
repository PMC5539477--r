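test_that("RR generator converges to the configured class mean and honours the noise-free case", {
  prof <- base_profile()
  rr <- generate_rr_series("SI", 300, prof, seed = 11)
  x <- rr$rr_ms / 1000
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.86), 3 * se + 1e-9)

  quiet <- prof
  quiet$cardiac$jitter_sd <- 0
  quiet$cardiac$lf_amp <- 0
  quiet$cardiac$hf_amp <- 0
  rr0 <- generate_rr_series("WK", 120, quiet, seed = 1)
  expect_true(all(abs(rr0$rr_ms - 610) < 1e-9))

  expect_error(generate_rr_series("SI", 30, prof), "60 s")
  expect_error(generate_rr_series("JOG", 120, prof), "unknown activity")
})

test_that("configured WK > AS mean-RR ordering survives sampling in (almost) every replicate", {
  ok <- 0L
  for (s in 1:100) {
    m <- simulate_feature_cohort(n_subjects = 13, seed = s)
    if (mean(m$mRR[m$activity == "WK"]) > mean(m$mRR[m$activity == "AS"]))
      ok <- ok + 1L
  }
  expect_gte(ok, 99L)
})

test_that("ECG synthesis places the QRS maximum at each true R-peak sample", {
  rr <- rr_from_intervals(c(1000, 1000, 1000))
  ecg <- generate_ecg_waveform(rr, fs = 256)
  expect_equal(round(rr$t * 256), c(256, 512, 768))
  for (p in rr$t) {
    idx0 <- round(p * 256)                   # 0-based sample of the peak
    win <- ecg$ecg[(idx0 - 12):(idx0 + 14)]  # 1-based slice centred on idx0+1
    expect_equal(which.max(win), 14L)
  }
  expect_error(generate_ecg_waveform(rr_series(numeric(0), numeric(0)), fs = 256),
               "empty")
})

test_that("accelerometer generator: silent standing, exact dominant frequency, amplitude ordering", {
  prof <- base_profile()
  still <- prof
  still$accel$noise_sd <- 0
  a <- generate_accel("ST", 60, still, seed = 1)
  feats <- imu_window_features(segment_accel(a)[[1]], fs = 128)
  expect_equal(unname(feats["sd"]), 0)
  expect_equal(unname(feats["rms"]), 0)

  loud <- still
  loud$accel$amp_g[loud$accel$activity == "RU"] <- 2.0
  loud$accel$gait_freq[loud$accel$activity == "RU"] <- 2.5
  a2 <- generate_accel("RU", 60, loud, seed = 2)
  f2 <- imu_features_by_minute(a2)
  expect_lt(abs(f2$f_dominant[1] - 2.5), 0.5 + 1e-9)  # one bin at 0.5 Hz resolution

  for (s in 1:100) {
    rms <- vapply(c("SI", "ST", "WK", "AS", "RU"), function(act) {
      mean(imu_features_by_minute(generate_accel(act, 60, prof,
                                                 seed = s * 10 + match(act, activity_labels())))$rms)
    }, numeric(1))
    expect_lt(max(rms["SI"], rms["ST"]), rms["WK"])
    expect_lt(rms["WK"], min(rms["AS"], rms["RU"]))
  }
})

test_that("cohort generation is deterministic and bookkeeps labelled minutes", {
  co1 <- generate_cohort(n_subjects = 3, seed = 42)
  co2 <- generate_cohort(n_subjects = 3, seed = 42)
  expect_identical(co1$labels, co2$labels)
  expect_identical(co1$subjects[[2]]$blocks[[3]]$rr$rr_ms,
                   co2$subjects[[2]]$blocks[[3]]$rr$rr_ms)

  expect_equal(nrow(co1$labels), 3 * sum(default_schedule()$minutes))
  counts <- table(co1$labels$activity) / 3
  expect_equal(unname(counts[c("SI", "ST", "WK", "AS", "RU")]),
               c(5, 5, 10, 10, 10), ignore_attr = TRUE)
  expect_error(generate_cohort(n_subjects = 2), "3 subjects")
})

test_that("noise-free reference EE equals the generative linear predictor", {
  model <- default_ee_model(noise_sd = 0)
  co <- generate_cohort(n_subjects = 3, ee_model = model, seed = 5)
  for (sub in co$subjects) {
    lab <- co$labels[co$labels$subject_id == sub$profile$subject_id, ]
    for (blk in sub$blocks) {
      truth <- hrvee:::true_minute_features(sub$profile, blk$activity)
      mu <- hrvee:::ee_linear_predictor(model, activity_category(blk$activity), truth)
      expect_equal(lab$ee_kcal_per_min[lab$activity == blk$activity],
                   rep(mu, blk$minutes), tolerance = 1e-12)
    }
  }
})

test_that("REST heart rate decays from the preceding dynamic level towards sitting", {
  prof <- base_profile()
  rr <- generate_rr_series("REST", 300, prof, seed = 9, rest_from = "RU")
  first30 <- rr$rr_ms[rr$t <= 30]
  last60 <- rr$rr_ms[rr$t >= 240]
  expect_lt(mean(first30), mean(last60))        # intervals lengthen as HR recovers
  expect_lt(mean(first30) / 1000, 0.7)          # starts near the running level
  expect_gt(mean(last60) / 1000, 0.7)           # approaches the sitting level
})
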