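# Shared fixtures and independent oracles.

# Small study design used across tests: full paradigm, fewer subjects,
# EMG at 600 Hz to keep filtering cheap.
small_design <- function(n_subjects = 12, seed = 5, ...) {
  study_design(n_subjects = n_subjects, seed = seed,
               sampling_rates = c(emg_corrugator = 600,
                                  emg_zygomaticus = 600,
                                  scl = 32, bvp = 128), ...)
}

# One small cohort with extracted features, computed once per run.
.fixture_env <- new.env(parent = emptyenv())
small_cohort_features <- function() {
  if (is.null(.fixture_env$cf))
    .fixture_env$cf <- simulate_and_extract(small_design())
  .fixture_env$cf
}

# Amplitude of the frequency-f component of x (discrete Fourier
# transform; f must sit on the frequency grid).
fft_amplitude <- function(x, fs, f) {
  n <- length(x)
  k <- round(f * n / fs)
  2 * Mod(stats::fft(x)[k + 1]) / n
}

# Naive direct-summation oracle for the 13 SCL features: explicit loops
# over the printed formulas, lm() for the regression slope.
naive_scl_features <- function(x, fs, thr = 0.05) {
  N <- length(x)
  mu <- sum(x) / N
  sdev <- sqrt(sum((x - mu)^2) / (N - 1))
  z <- if (sdev > 0) (x - mu) / sdev else rep(0, N)
  fd <- function(v) {
    s <- 0
    for (i in 1:(N - 1)) s <- s + abs(v[i + 1] - v[i])
    s / (N - 1)
  }
  sd2 <- function(v) {
    s <- 0
    for (i in 1:(N - 2)) s <- s + abs(v[i + 2] - v[i])
    s / (N - 2)
  }
  # walk the series collecting alternating extrema (plateaus collapse)
  amps_max <- c(); amps_min <- c()
  dirs <- sign(diff(x)); dirs <- dirs[dirs != 0]
  idxs <- which(sign(diff(x)) != 0)
  ref <- x[1]; last_dir <- if (length(dirs)) dirs[1] else 0
  if (length(dirs) >= 2) {
    for (j in 2:length(dirs)) {
      if (dirs[j] != last_dir) {
        v <- x[idxs[j]]
        if (last_dir > 0) amps_max <- c(amps_max, v - ref)
        else amps_min <- c(amps_min, ref - v)
        ref <- v
        last_dir <- dirs[j]
      }
    }
  }
  amps_max <- amps_max[amps_max > thr]
  amps_min <- amps_min[amps_min > thr]
  t <- (seq_len(N) - 1) / fs
  c(SCL_mean = mu, SCL_std = sdev,
    SCL_fd_raw = fd(x), SCL_fd_norm = fd(z),
    SCL_sd_raw = sd2(x), SCL_sd_norm = sd2(z),
    SCL_n_max = length(amps_max), SCL_n_min = length(amps_min),
    SCL_n_extrema = length(amps_max) + length(amps_min),
    SCL_mean_amp_max = if (length(amps_max)) mean(amps_max) else 0,
    SCL_mean_amp_min = if (length(amps_min)) mean(amps_min) else 0,
    SCL_integral = sum(x) / fs,
    SCL_slope = unname(stats::coef(stats::lm(x ~ t))[2]))
}

# Naive HRV oracle (explicit loops).
naive_hrv_features <- function(nn_ms) {
  n <- length(nn_ms)
  hr <- 60000 / nn_ms
  ssq <- 0
  for (j in 1:(n - 1)) ssq <- ssq + (nn_ms[j + 1] - nn_ms[j])^2
  c(mean_RR = mean(nn_ms), std_RR = stats::sd(nn_ms),
    mean_HR = mean(hr), std_HR = stats::sd(hr),
    RMSSD = sqrt(ssq / (n - 1)))
}

# Synthetic BVP pulse train with beats at the given onset times:
# one raised-cosine hump of 0.3 s per beat.
pulse_train <- function(beat_times, fs, total) {
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (b in beat_times) {
    sel <- t >= b & t < b + 0.3
    x[sel] <- x[sel] + 0.5 * (1 - cos(2 * pi * (t[sel] - b) / 0.3))
  }
  x
}

# A segment object without running the preprocessing chain.
make_segment <- function(samples, fs, condition = "neutral",
                         baseline = numeric(0)) {
  structure(list(samples = samples, fs = fs, condition = condition,
                 baseline_samples = baseline, onset = NA_real_),
            class = "segment")
}

# Hand-built feature matrix: one row per subject x condition with
# all-canonical columns, default zero, selected columns overridden.
toy_feature_matrix <- function(subjects, conditions, override = list(),
                               seed = 1, features = feature_names()) {
  rows <- expand.grid(subject_id = subjects, condition = conditions,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  for (f in features)
    rows[[f]] <- stats::rnorm(nrow(rows), 0, 1e-3)
  for (nm in names(override)) rows[[nm]] <- override[[nm]]
  emophys:::as_feature_matrix(rows, provenance = "reduced")
}
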