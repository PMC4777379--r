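# Preprocessing: EMG band-pass + notch, RMS envelope, SCL smoothing,
# BVP beat detection, timeline segmentation.

# One IIR pass with zero initial conditions (direct-form transposed
# split into its FIR and recursive parts; exact, and much faster than a
# pure-R recursion on long channels).
iir_pass <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x), b, sides = 1)
  v <- as.numeric(v)[nb - 1L + seq_along(x)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v / a[1L]
}

# Zero-phase (forward-backward) filtering with odd-reflection padding to
# suppress edge transients; `pad` in samples.
zero_phase <- function(b, a, x, pad = 3L * max(length(a), length(b))) {
  n <- length(x)
  pad <- max(0L, min(as.integer(pad), n - 1L))
  if (pad > 0L) {
    left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xe <- c(left, x, right)
  } else xe <- x
  y <- iir_pass(b, a, xe)
  y <- rev(iir_pass(b, a, rev(y)))
  y[pad + seq_len(n)]
}

#' Band-pass filter raw facial EMG
#'
#' 20--250 Hz 4th-order Butterworth band-pass, applied forward-backward
#' (zero phase), removing motion-related low-frequency components and
#' high-frequency noise.
#'
#' @param samples Numeric vector of raw EMG samples.
#' @param fs Sampling rate in Hz; must exceed 500 Hz so the 250 Hz band
#'   edge is below Nyquist.
#' @return Filtered samples, same length as the input.
#' @export
bandpass_emg <- function(samples, fs) {
  if (fs <= 500) stopf("bandpass_emg: fs must exceed 500 Hz, got %g", fs)
  bt <- signal::butter(4, c(20, 250) / (fs / 2), type = "pass")
  zero_phase(bt$b, bt$a, samples, pad = round(0.2 * fs))
}

#' Suppress power-line interference
#'
#' Narrow second-order IIR notch (quality factor \code{q}, default 30)
#' at the line frequency, applied zero-phase. The notch places a zero
#' exactly on the line frequency, so a pure line-frequency sinusoid is
#' removed while components 10 Hz away are attenuated by well under 3 dB.
#'
#' @inheritParams bandpass_emg
#' @param line_freq Interference frequency in Hz (50 by default).
#' @param q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return Filtered samples, same length as the input.
#' @export
remove_powerline <- function(samples, fs, line_freq = 50, q = 30) {
  if (fs <= 2 * line_freq)
    stopf("remove_powerline: fs must exceed 2 x line_freq (%g Hz)",
          2 * line_freq)
  w0 <- 2 * pi * line_freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  zero_phase(b, a, samples, pad = round(0.5 * fs))
}

#' Sliding-window RMS envelope
#'
#' Centred root-mean-square over a sliding window (125 ms by default),
#' the standard rectify-and-smooth step for surface EMG. Edges use
#' truncated windows; the output has the length of the input and is
#' non-negative everywhere.
#'
#' @inheritParams bandpass_emg
#' @param window Window length in seconds.
#' @return The RMS envelope, same length as the input.
#' @export
rms_envelope <- function(samples, fs, window = 0.125) {
  w <- round(window * fs)
  if (w < 2) stopf("rms_envelope: window must span at least 2 samples")
  n <- length(samples)
  half_lo <- floor((w - 1) / 2)
  half_hi <- ceiling((w - 1) / 2)
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  cs <- c(0, cumsum(samples^2))
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Low-pass smooth the skin conductance level
#'
#' 4th-order Butterworth low-pass (0.2 Hz cutoff by default), applied
#' zero-phase; unit DC gain, so tonic levels pass through unchanged.
#'
#' @inheritParams bandpass_emg
#' @param cutoff Cutoff frequency in Hz.
#' @return Filtered samples, same length as the input.
#' @export
lowpass_scl <- function(samples, fs, cutoff = 0.2) {
  if (fs <= 2 * cutoff)
    stopf("lowpass_scl: fs must exceed 2 x cutoff (%g Hz)", 2 * cutoff)
  bt <- signal::butter(4, cutoff / (fs / 2), type = "low")
  # anchor at the first sample: the filter has unit DC gain, so
  # filtering the deviation from a constant is exact for constants and
  # much better conditioned for tonic signals with a large offset
  base <- samples[1L]
  zero_phase(bt$b, bt$a, samples - base,
             pad = round(5 * fs / cutoff)) + base
}

#' Detect heart beats in a blood-volume-pulse signal
#'
#' Band-passes the BVP to 0.5--8 Hz (zero phase), locates pulse peaks as
#' local maxima above an adaptive threshold with a 300 ms minimum
#' inter-peak distance, and screens the resulting inter-beat intervals
#' with an automatic artifact rule: intervals outside [300, 2000] ms, or
#' deviating more than 25\% from the running median of the five preceding
#' intervals, are discarded.
#'
#' @param bvp_samples Numeric vector of raw BVP samples (>= 10 s).
#' @param fs Sampling rate in Hz.
#' @return An \code{nn_series}: list with \code{intervals} (ms),
#'   \code{beat_times} (s; onset of the first kept interval followed by
#'   the terminating beat of every kept interval) and \code{n}
#'   (= number of intervals).
#' @export
detect_beats <- function(bvp_samples, fs) {
  if (length(bvp_samples) < 10 * fs)
    stopf("detect_beats: recording must be at least 10 s long")
  bt <- signal::butter(2, c(0.5, 8) / (fs / 2), type = "pass")
  z <- zero_phase(bt$b, bt$a, bvp_samples, pad = round(4 * fs))
  n <- length(z)
  cand <- which(z[2:(n - 1L)] > z[1:(n - 2L)] &
                z[2:(n - 1L)] >= z[3:n]) + 1L
  thr <- 0.5 * stats::quantile(z, 0.98, names = FALSE)
  cand <- cand[z[cand] > thr]
  if (length(cand) < 3L)
    stopf("detect_beats: signal quality too poor (fewer than 3 beats)")
  # enforce minimum inter-peak distance, keeping the taller peak
  min_dist <- round(0.3 * fs)
  keep <- logical(length(cand))
  ord <- order(z[cand], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (!any(abs(cand[i] - taken) < min_dist)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  beats <- sort(cand[keep])
  if (length(beats) < 3L)
    stopf("detect_beats: signal quality too poor (fewer than 3 beats)")
  bt_s <- (beats - 1) / fs
  raw_nn <- diff(bt_s) * 1000
  kept <- logical(length(raw_nn))
  for (j in seq_along(raw_nn)) {
    ref <- raw_nn[max(1L, j - 5L):max(1L, j - 1L)]
    med <- stats::median(if (j == 1L) raw_nn else ref)
    kept[j] <- raw_nn[j] >= 300 && raw_nn[j] <= 2000 &&
      abs(raw_nn[j] - med) <= 0.25 * med
  }
  if (!any(kept))
    stopf("detect_beats: no plausible inter-beat intervals survived screening")
  k <- which(kept)
  nn_series(intervals = raw_nn[k],
            beat_times = c(bt_s[k[1L]], bt_s[k + 1L]))
}

#' @rdname detect_beats
#' @param intervals Inter-beat intervals in ms.
#' @param beat_times Beat times in seconds.
#' @export
nn_series <- function(intervals, beat_times) {
  if (any(intervals <= 0)) stopf("nn_series: intervals must be > 0")
  if (any(diff(beat_times) <= 0))
    stopf("nn_series: beat_times must be strictly increasing")
  if (length(beat_times) != length(intervals) + 1L)
    stopf("nn_series: need one more beat time than intervals")
  structure(list(intervals = intervals, beat_times = beat_times,
                 n = length(intervals)),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("NN series: %d intervals, mean %.1f ms (%.1f bpm)\n",
              x$n, mean(x$intervals), 60000 / mean(x$intervals)))
  invisible(x)
}

#' Segment a channel by the event timeline
#'
#' Cuts one \code{segment} per stimulation block, carrying the block's
#' condition label and the immediately preceding \code{baseline_window}
#' seconds of samples.
#'
#' @inheritParams bandpass_emg
#' @param timeline An \code{event_timeline}.
#' @param baseline_window Pre-block baseline length in seconds.
#' @return A list of \code{segment} objects: \code{samples}, \code{fs},
#'   \code{condition}, \code{baseline_samples}, \code{onset}.
#' @export
segment_by_timeline <- function(samples, fs, timeline, baseline_window = 2) {
  validate_timeline(timeline)
  bl <- timeline_blocks(timeline)
  n <- length(samples)
  lapply(seq_len(nrow(bl)), function(i) {
    i0 <- round(bl$onset[i] * fs) + 1L
    len <- round(bl$duration[i] * fs)
    if (i0 + len - 1L > n)
      stopf("segment_by_timeline: block %d (%s) extends past the recording end",
            i, bl$label[i])
    b0 <- round((bl$onset[i] - baseline_window) * fs) + 1L
    if (b0 < 1L)
      stopf("segment_by_timeline: block %d begins before %g s of baseline is available",
            i, baseline_window)
    structure(list(samples = samples[i0:(i0 + len - 1L)], fs = fs,
                   condition = bl$label[i],
                   baseline_samples = samples[b0:(i0 - 1L)],
                   onset = bl$onset[i]),
              class = "segment")
  })
}
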