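test_that("HRV features match direct formula evaluation", {
  f <- hrv_features(list(intervals = c(800, 800, 800)))
  expect_equal(unname(f["RMSSD"]), 0)
  expect_equal(unname(f["mean_RR"]), 800)
  expect_equal(unname(f["mean_HR"]), 75)
  expect_equal(unname(f["std_RR"]), 0)
  expect_equal(unname(hrv_features(list(intervals = c(800, 850)))["RMSSD"]),
               50)
  f3 <- hrv_features(list(intervals = c(700, 720, 710, 730)))
  expect_equal(unname(f3["RMSSD"]), sqrt((20^2 + 10^2 + 20^2) / 3),
               tolerance = 1e-12)
  expect_equal(unname(f3["RMSSD"]), 17.3205, tolerance = 1e-4)
  expect_error(hrv_features(list(intervals = 800)), "at least 2")
})

test_that("RMSSD and SDs are shift-invariant; mean shifts", {
  set.seed(3)
  for (i in 1:20) {
    nn <- runif(sample(3:30, 1), 600, 1100)
    a <- hrv_features(list(intervals = nn))
    b <- hrv_features(list(intervals = nn + 150))
    expect_equal(a["RMSSD"], b["RMSSD"])
    expect_equal(a["std_RR"], b["std_RR"])
    expect_equal(unname(b["mean_RR"] - a["mean_RR"]), 150)
  }
})

test_that("EMG block change is the baseline-subtracted mean", {
  seg <- make_segment(rep(3, 100), 100, baseline = rep(1, 20))
  expect_equal(emg_block_change(seg), 2)
  seg2 <- make_segment(rep(1.5, 100), 100, baseline = rep(1.5, 20))
  expect_equal(emg_block_change(seg2), 0)
  # ramped envelope against an independent mean-difference computation
  env <- seq(0, 1, length.out = 120)
  seg3 <- make_segment(env[21:120], 100, baseline = env[1:20])
  expect_equal(emg_block_change(seg3), mean(env[21:120]) - mean(env[1:20]))
  expect_error(emg_block_change(make_segment(1:5, 10)), "baseline")
})

test_that("within-subject z-scoring", {
  expect_equal(zscore_within_subject(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zscore_within_subject(rep(7, 4)), rep(0, 4))
  set.seed(9)
  z <- zscore_within_subject(rnorm(10, 5, 2))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_error(zscore_within_subject(3), "at least 2")
})

test_that("SCL features on degenerate segments", {
  fs <- 32
  const <- make_segment(rep(5, 20 * fs), fs)
  f <- scl_features(const)
  expect_equal(unname(f["SCL_mean"]), 5)
  expect_equal(unname(f["SCL_std"]), 0)
  expect_equal(unname(f[c("SCL_fd_raw", "SCL_fd_norm", "SCL_sd_raw",
                          "SCL_sd_norm")]), rep(0, 4))
  expect_equal(unname(f["SCL_n_extrema"]), 0)
  expect_equal(unname(f["SCL_integral"]), 100)
  expect_equal(unname(f["SCL_slope"]), 0)
  ramp <- make_segment(seq(0, 2, length.out = 20 * fs), fs)
  fr <- scl_features(ramp)
  expect_equal(unname(fr["SCL_slope"]), 0.1, tolerance = 0.01)
  expect_equal(unname(fr["SCL_n_extrema"]), 0)
  expect_equal(unname(fr["SCL_integral"]), 20, tolerance = 0.1)
  expect_error(scl_features(make_segment(c(1, 2), fs)), "3 samples")
})

test_that("extrema amplitudes respect the 0.05 uS threshold", {
  fs <- 32
  bump <- function(h) {
    x <- rep(5, 200)
    x[81:100] <- 5 + h * seq(0.05, 1, length.out = 20)
    x[101:120] <- 5 + h * seq(0.95, 0, length.out = 20)
    make_segment(x, fs)
  }
  f1 <- scl_features(bump(1))
  expect_equal(unname(f1["SCL_n_max"]), 1)
  expect_equal(unname(f1["SCL_mean_amp_max"]), 1)
  f0 <- scl_features(bump(0.01))
  expect_equal(unname(f0["SCL_n_max"]), 0)
  expect_equal(unname(f0["SCL_mean_amp_max"]), 0)
})

test_that("SCL features agree with the naive oracle on random walks", {
  set.seed(17)
  for (i in 1:200) {
    fs <- sample(c(16, 32, 64), 1)
    n <- sample(50:400, 1)
    x <- 5 + cumsum(rnorm(n, 0, 0.05))
    got <- scl_features(make_segment(x, fs))
    want <- naive_scl_features(x, fs)
    expect_equal(got, want[names(got)], tolerance = 1e-10)
  }
})

test_that("SCL integral is additive over a partition", {
  set.seed(5)
  x <- 5 + cumsum(rnorm(300, 0, 0.05))
  fs <- 32
  whole <- scl_features(make_segment(x, fs))["SCL_integral"]
  parts <- scl_features(make_segment(x[1:120], fs))["SCL_integral"] +
    scl_features(make_segment(x[121:300], fs))["SCL_integral"]
  expect_equal(unname(whole), unname(parts), tolerance = 1e-12)
})

test_that("raising the amplitude threshold never increases the counts", {
  set.seed(23)
  x <- 5 + cumsum(rnorm(300, 0, 0.05))
  seg <- make_segment(x, 32)
  thr <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  nmax <- vapply(thr, function(a) scl_features(seg, a)["SCL_n_max"],
                 numeric(1))
  nmin <- vapply(thr, function(a) scl_features(seg, a)["SCL_n_min"],
                 numeric(1))
  expect_true(all(diff(nmax) <= 0))
  expect_true(all(diff(nmin) <= 0))
})

test_that("condition pooling averages the two blocks of a condition", {
  bf <- data.frame(condition = rep(affect_conditions(), each = 2))
  for (f in feature_names()) bf[[f]] <- 0
  bf$SCL_mean <- rep(c(1, 3), 5)               # blocks a and b
  bf$mean_RR <- seq_len(10)
  fm <- assemble_feature_matrix(bf, "S9")
  expect_equal(nrow(fm), 5)
  expect_true(all(fm$SCL_mean == 2))           # (a + b) / 2
  expect_equal(fm$mean_RR,
               c(1.5, 3.5, 5.5, 7.5, 9.5))
  # identical blocks reproduce the block value
  bf$SCL_mean <- 4
  expect_true(all(assemble_feature_matrix(bf, "S9")$SCL_mean == 4))
  bf$SCL_mean[1] <- NA
  expect_error(assemble_feature_matrix(bf, "S9"), "missing")
})

test_that("SCL_n_extrema is the sum of the max and min counts", {
  cf <- small_cohort_features()
  fm <- cf$features
  expect_equal(fm$SCL_n_extrema, fm$SCL_n_max + fm$SCL_n_min)
  expect_true(all(fm$RMSSD >= 0))
  expect_true(all(fm$std_RR >= 0))
  expect_true(all(fm$SCL_std >= 0))
  expect_true(all(fm[, c("SCL_fd_raw", "SCL_fd_norm", "SCL_sd_raw",
                         "SCL_sd_norm")] >= 0))
  # exactly 5 condition rows per subject
  expect_equal(unname(table(fm$subject_id)), rep(5L, 12),
               ignore_attr = TRUE)
  # EMG z-scores average to 0 across a subject's conditions only in
  # expectation; their per-subject block z-scores do sum to ~0
  expect_equal(nrow(fm), 60)
})
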