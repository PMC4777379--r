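# The 20 canonical features per (subject x condition):
#   1 mean_RR   2 std_RR   3 mean_HR   4 std_HR   5 RMSSD
#   6 mean_amp_Corr   7 mean_amp_Zyg
#   8 SCL_mean  9 SCL_std  10 SCL_fd_raw  11 SCL_fd_norm  12 SCL_sd_raw
#   13 SCL_sd_norm  14 SCL_n_max  15 SCL_n_min  16 SCL_n_extrema
#   17 SCL_mean_amp_max  18 SCL_mean_amp_min  19 SCL_integral  20 SCL_slope

#' Time-domain heart-rate-variability features
#'
#' Computes the five HRV features from an NN-interval series:
#' mean and sample standard deviation of the NN intervals (ms), mean and
#' sample standard deviation of the per-beat heart rate (60000/NN, bpm),
#' and RMSSD, the root mean square of successive differences,
#' \code{sqrt(sum((NN[j+1] - NN[j])^2) / (n - 1))} over the n intervals.
#'
#' @param nn An \code{\link{nn_series}} (or list with an \code{intervals}
#'   element in ms) with at least 2 intervals.
#' @return Named numeric vector: \code{mean_RR}, \code{std_RR},
#'   \code{mean_HR}, \code{std_HR}, \code{RMSSD}.
#' @export
hrv_features <- function(nn) {
  x <- nn$intervals
  if (length(x) < 2L)
    stopf("hrv_features: need at least 2 NN intervals, got %d", length(x))
  hr <- 60000 / x
  c(mean_RR = mean(x), std_RR = stats::sd(x),
    mean_HR = mean(hr), std_HR = stats::sd(hr),
    RMSSD = sqrt(sum(diff(x)^2) / (length(x) - 1L)))
}

#' Baseline-corrected mean EMG envelope of a block
#'
#' Mean of the RMS envelope over the picture block minus the mean over
#' the pre-block baseline window.
#'
#' @param segment A \code{segment} of the EMG envelope with a non-empty
#'   \code{baseline_samples} window.
#' @return The baseline-subtracted mean envelope (scalar).
#' @export
emg_block_change <- function(segment) {
  if (length(segment$baseline_samples) == 0L)
    stopf("emg_block_change: segment has an empty baseline window")
  mean(segment$samples) - mean(segment$baseline_samples)
}

#' Within-subject z-scoring of block values
#'
#' Standardizes a subject's per-block values (one site at a time) to
#' mean 0 and sample SD 1. All-equal values map to all zeros.
#'
#' @param values Numeric vector of per-block values for one subject and
#'   one site (>= 2 blocks).
#' @return The standardized values.
#' @export
zscore_within_subject <- function(values) {
  if (length(values) < 2L)
    stopf("zscore_within_subject: need at least 2 blocks, got %d",
          length(values))
  s <- stats::sd(values)
  if (s == 0) return(rep(0, length(values)))
  (values - mean(values)) / s
}

#' The 13 skin-conductance-level features of a segment
#'
#' Computes, on the low-pass-filtered SCL segment X of length N:
#' \itemize{
#'   \item \code{SCL_mean}, \code{SCL_std}: mean and sample SD;
#'   \item \code{SCL_fd_raw}: mean |X[n+1] - X[n]|;
#'   \item \code{SCL_fd_norm}: the same on the within-segment z-scored
#'     signal;
#'   \item \code{SCL_sd_raw}, \code{SCL_sd_norm}: mean |X[n+2] - X[n]| on
#'     the raw and z-scored signal;
#'   \item \code{SCL_n_max}, \code{SCL_n_min}: counts of local maxima
#'     (minima) whose amplitude -- rise from the preceding minimum
#'     (drop from the preceding maximum; the first extremum is measured
#'     from the segment's first sample) -- exceeds \code{amp_threshold};
#'   \item \code{SCL_n_extrema} = \code{SCL_n_max + SCL_n_min};
#'   \item \code{SCL_mean_amp_max}, \code{SCL_mean_amp_min}: mean
#'     amplitude of the retained maxima / minima (positive magnitudes;
#'     0 if none retained);
#'   \item \code{SCL_integral}: integral over time, each sample covering
#'     one sample period (\code{sum(X)/fs}, uS s), so the integral is
#'     additive over a partition of the segment;
#'   \item \code{SCL_slope}: ordinary-least-squares slope of X against
#'     time (uS/s).
#' }
#'
#' @param segment A \code{segment} of the smoothed SCL (>= 3 samples).
#' @param amp_threshold Minimum extremum amplitude in uS (default
#'   0.05 uS).
#' @return Named numeric vector of the 13 SCL features.
#' @export
scl_features <- function(segment, amp_threshold = 0.05) {
  x <- segment$samples
  fs <- segment$fs
  n <- length(x)
  if (n < 3L)
    stopf("scl_features: segment must have at least 3 samples, got %d", n)
  mu <- mean(x)
  sdev <- stats::sd(x)
  z <- if (sdev > 0) (x - mu) / sdev else rep(0, n)
  fd <- function(v) mean(abs(v[-1L] - v[-length(v)]))
  sd2 <- function(v) mean(abs(v[-(1:2)] - v[seq_len(length(v) - 2L)]))
  ext <- scl_extrema(x, amp_threshold)
  t <- (seq_len(n) - 1) / fs
  slope <- if (stats::var(t) > 0)
    stats::cov(t, x) / stats::var(t) else 0
  c(SCL_mean = mu,
    SCL_std = sdev,
    SCL_fd_raw = fd(x),
    SCL_fd_norm = fd(z),
    SCL_sd_raw = sd2(x),
    SCL_sd_norm = sd2(z),
    SCL_n_max = ext$n_max,
    SCL_n_min = ext$n_min,
    SCL_n_extrema = ext$n_max + ext$n_min,
    SCL_mean_amp_max = ext$mean_amp_max,
    SCL_mean_amp_min = ext$mean_amp_min,
    SCL_integral = sum(x) / fs,
    SCL_slope = slope)
}

# Local extrema as sign changes of the first difference (plateaus carry
# the previous direction); amplitude = excursion from the preceding
# opposite extremum, the first extremum measured from the first sample.
scl_extrema <- function(x, amp_threshold) {
  s <- sign(diff(x))
  nz <- which(s != 0)
  amp_max <- numeric(0)
  amp_min <- numeric(0)
  if (length(nz) >= 2L) {
    prev_idx <- 1L   # reference point for the next amplitude
    last_dir <- s[nz[1L]]
    for (k in nz[-1L]) {
      dir <- s[k]
      if (dir != last_dir) {
        ei <- k  # extremum at the start of the new run
        if (last_dir > 0) amp_max <- c(amp_max, x[ei] - x[prev_idx])
        else amp_min <- c(amp_min, x[prev_idx] - x[ei])
        prev_idx <- ei
        last_dir <- dir
      }
    }
  }
  amp_max <- amp_max[amp_max > amp_threshold]
  amp_min <- amp_min[amp_min > amp_threshold]
  list(n_max = length(amp_max), n_min = length(amp_min),
       mean_amp_max = if (length(amp_max)) mean(amp_max) else 0,
       mean_amp_min = if (length(amp_min)) mean(amp_min) else 0)
}

#' Assemble per-block features into the (subject x condition) matrix
#'
#' Pools the blocks of each condition by the arithmetic mean, giving one
#' row per (subject, condition) with the canonical feature columns.
#'
#' @param block_features Data frame with a \code{condition} column and
#'   one column per extracted feature, one row per stimulation block.
#' @param subject_id Subject identifier for the emitted rows.
#' @return A \code{feature_matrix} data frame (provenance \code{"raw"}).
#' @export
assemble_feature_matrix <- function(block_features, subject_id) {
  if (anyNA(block_features))
    stopf("assemble_feature_matrix: missing feature values for subject %s",
          subject_id)
  feats <- intersect(feature_names(), names(block_features))
  if (length(feats) == 0L)
    stopf("assemble_feature_matrix: no canonical feature columns present")
  conds <- intersect(affect_conditions(), unique(block_features$condition))
  rows <- lapply(conds, function(cond) {
    sub <- block_features[block_features$condition == cond, feats,
                          drop = FALSE]
    cbind(data.frame(subject_id = subject_id, condition = cond,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(sub))))
  })
  fm <- do.call(rbind, rows)
  as_feature_matrix(fm, provenance = "raw")
}

as_feature_matrix <- function(df, provenance = "raw") {
  attr(df, "provenance") <- provenance
  class(df) <- unique(c("feature_matrix", class(df)))
  df
}

#' @export
print.feature_matrix <- function(x, ...) {
  feats <- intersect(feature_names(), names(x))
  cat(sprintf("Feature matrix (%s): %d rows (%d subjects x conditions), %d features\n",
              attr(x, "provenance") %||% "raw", nrow(x),
              length(unique(x$subject_id)), length(feats)))
  NextMethod()
}

#' Extract all features of one recording
#'
#' Runs the full preprocessing and feature chain for a single subject:
#' EMG band-pass, power-line notch and RMS envelope; SCL low-pass; BVP
#' beat detection with artifact screening; segmentation by the timeline;
#' per-block features; within-subject z-scoring of the EMG block changes
#' per site; and condition pooling.
#'
#' Only the channels present in \code{recording} are processed, and only
#' their feature columns appear in the result (all 20 when all four
#' channels are present).
#'
#' @param recording A \code{raw_recording}.
#' @param timeline The \code{event_timeline} of the session.
#' @param baseline_window EMG/SCL pre-block baseline length in seconds.
#' @param amp_threshold SCR-amplitude threshold for the extrema counts
#'   (uS).
#' @param scl_baseline_correct If \code{TRUE}, subtract the preceding
#'   fixation interval's mean level from \code{SCL_mean} and its
#'   level-equivalent from \code{SCL_integral} (level features only;
#'   shape and count features are never corrected). Off by default so
#'   the features follow their printed formulas exactly.
#' @param hrv_baseline_correct If \code{TRUE}, subtract the HRV features
#'   of the preceding fixation interval from each block's HRV features.
#'   Off by default.
#' @return A \code{feature_matrix} with one row per condition.
#' @export
extract_features <- function(recording, timeline, baseline_window = 2,
                             amp_threshold = 0.05,
                             scl_baseline_correct = FALSE,
                             hrv_baseline_correct = FALSE) {
  validate_timeline(timeline)
  chans <- names(recording$channels)
  bl <- timeline_blocks(timeline)
  out <- data.frame(condition = bl$label, stringsAsFactors = FALSE)

  for (site in c("emg_corrugator", "emg_zygomaticus")) {
    if (!site %in% chans) next
    ch <- recording$channels[[site]]
    env <- rms_envelope(remove_powerline(bandpass_emg(ch$samples, ch$fs),
                                         ch$fs), ch$fs)
    segs <- segment_by_timeline(env, ch$fs, timeline, baseline_window)
    changes <- vapply(segs, emg_block_change, numeric(1))
    col <- if (site == "emg_corrugator") "mean_amp_Corr" else "mean_amp_Zyg"
    out[[col]] <- zscore_within_subject(changes)
  }

  if ("scl" %in% chans) {
    ch <- recording$channels$scl
    sm <- lowpass_scl(ch$samples, ch$fs)
    segs <- segment_by_timeline(sm, ch$fs, timeline, baseline_window)
    sclf <- t(vapply(segs, scl_features, numeric(13),
                     amp_threshold = amp_threshold))
    if (scl_baseline_correct) {
      fix <- fixation_before_blocks(timeline)
      for (i in seq_len(nrow(bl))) {
        i0 <- round(fix$onset[i] * ch$fs) + 1L
        i1 <- round((fix$onset[i] + fix$duration[i]) * ch$fs)
        base_mean <- mean(sm[i0:min(i1, length(sm))])
        sclf[i, "SCL_mean"] <- sclf[i, "SCL_mean"] - base_mean
        sclf[i, "SCL_integral"] <- sclf[i, "SCL_integral"] -
          base_mean * bl$duration[i]
      }
    }
    out <- cbind(out, as.data.frame(sclf))
  }

  if ("bvp" %in% chans) {
    ch <- recording$channels$bvp
    nn <- detect_beats(ch$samples, ch$fs)
    hrv <- t(vapply(seq_len(nrow(bl)), function(i) {
      block_hrv(nn, bl$onset[i], bl$onset[i] + bl$duration[i])
    }, numeric(5)))
    if (hrv_baseline_correct) {
      fix <- fixation_before_blocks(timeline)
      for (i in seq_len(nrow(bl)))
        hrv[i, ] <- hrv[i, ] -
          block_hrv(nn, fix$onset[i], fix$onset[i] + fix$duration[i])
    }
    out <- cbind(out, as.data.frame(hrv))
  }

  assemble_feature_matrix(out, recording$subject_id)
}

# The fixation interval immediately preceding each stimulation block.
fixation_before_blocks <- function(tl) {
  idx <- which(tl$label != "fixation")
  tl[idx - 1L, c("onset", "duration"), drop = FALSE]
}

block_hrv <- function(nn, from, to) {
  sel <- nn$beat_times[-1L] >= from & nn$beat_times[-1L] <= to
  if (sum(sel) < 2L)
    stopf("block HRV: fewer than 2 NN intervals in [%g, %g] s", from, to)
  hrv_features(list(intervals = nn$intervals[sel]))
}

#' Extract features for a whole cohort
#'
#' @param cohort A list as returned by \code{\link{simulate_cohort}}
#'   (elements \code{timeline}, \code{profiles}, \code{recordings}).
#' @param ... Passed to \code{\link{extract_features}}.
#' @return A \code{feature_matrix} with one row per subject and
#'   condition.
#' @export
extract_cohort_features <- function(cohort, ...) {
  fm <- do.call(rbind, lapply(cohort$recordings, extract_features,
                              timeline = cohort$timeline, ...))
  rownames(fm) <- NULL
  as_feature_matrix(fm, provenance = "raw")
}

#' Simulate a cohort and extract its features, one subject at a time
#'
#' Streaming equivalent of \code{\link{simulate_cohort}} followed by
#' \code{\link{extract_cohort_features}}: each subject's recording is
#' synthesized, featurized and discarded, so cohort size is not limited
#' by holding raw signals in memory.
#'
#' @param design A \code{\link{study_design}}.
#' @param channels Channels to synthesize (all four by default; with a
#'   subset, only that subset's feature columns are produced).
#' @param ... Passed to \code{\link{extract_features}}.
#' @return A list with \code{design}, \code{timeline}, \code{profiles}
#'   and \code{features} (a \code{feature_matrix}).
#' @export
simulate_and_extract <- function(design = study_design(),
                                 channels = c("emg_corrugator",
                                              "emg_zygomaticus",
                                              "scl", "bvp"), ...) {
  validate_study_design(design)
  timeline <- generate_timeline(design)
  profiles <- generate_profiles(design)
  mid <- mean(design$age_range)
  fm <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
    rec <- synthesize_recording(profiles[i, ], timeline,
                                params = design$effect_params,
                                sampling_rates = design$sampling_rates,
                                seed = substream_seed(design$seed, i),
                                age_midpoint = mid, channels = channels)
    extract_features(rec, timeline, ...)
  }))
  rownames(fm) <- NULL
  list(design = design, timeline = timeline, profiles = profiles,
       features = as_feature_matrix(fm, provenance = "raw"))
}
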