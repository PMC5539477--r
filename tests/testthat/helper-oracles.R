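# Independent brute-force oracles for the nonlinear HRV measures.  These
# are written as direct index loops over the definitions, sharing no code
# with the package implementations.

brute_phi <- function(x, m, r) {
  N <- length(x)
  M <- N - m + 1L
  cnt <- integer(M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      d <- 0
      for (k in 0:(m - 1L)) d <- max(d, abs(x[i + k] - x[j + k]))
      if (d <= r) cnt[i] <- cnt[i] + 1L
    }
  }
  mean(log(cnt / M))
}

brute_apen <- function(x, m, r) brute_phi(x, m, r) - brute_phi(x, m + 1L, r)

brute_sampen <- function(x, m, r) {
  N <- length(x)
  count_pairs <- function(mm, M) {
    n_match <- 0L
    for (i in seq_len(M - 1L)) {
      for (j in (i + 1L):M) {
        d <- 0
        for (k in 0:(mm - 1L)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) n_match <- n_match + 1L
      }
    }
    n_match
  }
  B <- count_pairs(m, N - m)
  A <- count_pairs(m + 1L, N - m)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

brute_rqa <- function(x, m, delay, thr, lmin) {
  M <- length(x) - (m - 1L) * delay
  R <- matrix(FALSE, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) next
      ss <- 0
      for (k in 0:(m - 1L)) ss <- ss + (x[i + k * delay] - x[j + k * delay])^2
      R[i, j] <- sqrt(ss) <= thr
    }
  }
  n_rec <- sum(R)
  if (n_rec == 0)
    return(c(Lmean = 0, Lmax = 0, REC = 0, DET = 0, ShanEn = 0))
  lens <- integer(0)
  for (k in c(-(M - 1L):-1L, 1L:(M - 1L))) {
    run <- 0L
    for (i in seq_len(M)) {
      j <- i + k
      inside <- j >= 1L && j <= M
      if (inside && R[i, j]) run <- run + 1L
      else { if (run > 0L) lens <- c(lens, run); run <- 0L }
    }
    if (run > 0L) lens <- c(lens, run)
  }
  keep <- lens[lens >= lmin]
  if (length(keep)) {
    p <- table(keep) / length(keep)
    shan <- -sum(p * log(p))
    out <- c(Lmean = mean(keep), Lmax = max(keep),
             REC = 100 * n_rec / (M * (M - 1L)),
             DET = 100 * sum(keep) / n_rec, ShanEn = shan)
  } else {
    out <- c(Lmean = 0, Lmax = 0, REC = 100 * n_rec / (M * (M - 1L)),
             DET = 0, ShanEn = 0)
  }
  out
}

brute_corr_sums <- function(x, radii, m) {
  M <- length(x) - m + 1L
  d <- numeric(M * (M - 1L) / 2L)
  idx <- 0L
  for (i in seq_len(M - 1L)) {
    for (j in (i + 1L):M) {
      ss <- 0
      for (k in 0:(m - 1L)) ss <- ss + (x[i + k] - x[j + k])^2
      idx <- idx + 1L
      d[idx] <- sqrt(ss)
    }
  }
  vapply(radii, function(r) mean(d <= r), numeric(1))
}

# Two-way balanced ANOVA by textbook sums-of-squares arithmetic.
brute_anova_2x2 <- function(v, a, b) {
  a <- as.character(a); b <- as.character(b)
  la <- sort(unique(a)); lb <- sort(unique(b))
  n <- sum(a == la[1] & b == lb[1])
  grand <- mean(v)
  ss_a <- 0
  for (ai in la) ss_a <- ss_a + sum(a == ai) * (mean(v[a == ai]) - grand)^2
  ss_b <- 0
  for (bi in lb) ss_b <- ss_b + sum(b == bi) * (mean(v[b == bi]) - grand)^2
  ss_cells <- 0
  for (ai in la) for (bi in lb) {
    sel <- a == ai & b == bi
    ss_cells <- ss_cells + sum(sel) * (mean(v[sel]) - grand)^2
  }
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((v - grand)^2) - ss_cells
  df_err <- length(v) - 4L
  list(F_a = (ss_a / 1) / (ss_err / df_err),
       F_b = (ss_b / 1) / (ss_err / df_err),
       F_ab = (ss_ab / 1) / (ss_err / df_err),
       df_err = df_err)
}

# A subject profile fixed at the population class means (no between-subject
# draw), for tests that target the configured class-conditional statistics.
base_profile <- function() {
  list(subject_id = "S00", height = 170, weight = 70,
       cardiac = default_cardiac_params(),
       accel = default_accel_params())
}

# Published five-class confusion tables used as metric-arithmetic fixtures
# (linear-SVM results of a wrist accelerometer + chest ECG benchmark;
# rows = ground truth SI/ST/WK/RU/AS, columns = predicted).
benchmark_confusion_imu_only <- function() {
  matrix(c(33, 31, 1, 0, 0,
           21, 44, 0, 0, 0,
           1, 0, 98, 0, 31,
           0, 0, 0, 130, 0,
           0, 0, 3, 0, 127),
         nrow = 5, byrow = TRUE,
         dimnames = list(truth = c("SI", "ST", "WK", "RU", "AS"),
                         predicted = c("SI", "ST", "WK", "RU", "AS")))
}

benchmark_confusion_imu_ecg <- function() {
  matrix(c(49, 13, 3, 0, 0,
           9, 56, 0, 0, 0,
           0, 2, 128, 0, 0,
           0, 0, 0, 130, 0,
           0, 0, 0, 0, 130),
         nrow = 5, byrow = TRUE,
         dimnames = list(truth = c("SI", "ST", "WK", "RU", "AS"),
                         predicted = c("SI", "ST", "WK", "RU", "AS")))
}
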