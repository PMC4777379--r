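#' Generate the block-design induction timeline
#'
#' Builds the ordered event timeline of the induction session: each of the
#' five core affects appears in \code{blocks_per_condition} stimulation
#' blocks, every block is immediately preceded by a fixation interval, and
#' the block order is a seeded random permutation. Block duration is
#' \code{pictures_per_block * picture_duration} seconds.
#'
#' @param design A \code{\link{study_design}}.
#' @param seed Seed for the block-order permutation; defaults to a
#'   substream of \code{design$seed}.
#' @return An \code{event_timeline}: a data frame with columns
#'   \code{onset}, \code{duration}, \code{label} (seconds; label is
#'   \code{"fixation"} or a condition), carrying the picture grid as
#'   attributes \code{pictures_per_block} and \code{picture_duration}.
#' @export
generate_timeline <- function(design, seed = NULL) {
  validate_study_design(design)
  if (is.null(seed)) seed <- substream_seed(design$seed, 0L, salt = 2L)
  conds <- affect_conditions()
  block_dur <- design$pictures_per_block * design$picture_duration
  order <- with_seed(seed, sample(rep(conds, design$blocks_per_condition)))
  n_blocks <- length(order)
  onset <- numeric(2L * n_blocks)
  duration <- numeric(2L * n_blocks)
  label <- character(2L * n_blocks)
  t <- 0
  for (i in seq_len(n_blocks)) {
    onset[2L * i - 1L] <- t
    duration[2L * i - 1L] <- design$fixation_duration
    label[2L * i - 1L] <- "fixation"
    t <- t + design$fixation_duration
    onset[2L * i] <- t
    duration[2L * i] <- block_dur
    label[2L * i] <- order[i]
    t <- t + block_dur
  }
  tl <- data.frame(onset = onset, duration = duration, label = label,
                   stringsAsFactors = FALSE)
  attr(tl, "pictures_per_block") <- design$pictures_per_block
  attr(tl, "picture_duration") <- design$picture_duration
  class(tl) <- c("event_timeline", "data.frame")
  validate_timeline(tl)
  tl
}

validate_timeline <- function(tl) {
  if (nrow(tl) == 0L) stopf("timeline is empty")
  offs <- tl$onset + tl$duration
  if (any(tl$duration <= 0)) stopf("timeline: durations must be > 0")
  if (nrow(tl) > 1L &&
      any(abs(tl$onset[-1L] - offs[-nrow(tl)]) > 1e-9))
    stopf("timeline: intervals must be contiguous and ordered")
  blocks <- which(tl$label != "fixation")
  if (any(blocks == 1L) ||
      any(tl$label[blocks - 1L] != "fixation"))
    stopf("timeline: every stimulation block must follow a fixation interval")
  invisible(tl)
}

timeline_blocks <- function(tl) {
  tl[tl$label != "fixation", , drop = FALSE]
}

timeline_duration <- function(tl) {
  n <- nrow(tl)
  tl$onset[n] + tl$duration[n]
}

# Condition label in force at each time point; "rest" outside blocks.
condition_at <- function(tl, t) {
  lab <- rep("rest", length(t))
  bl <- timeline_blocks(tl)
  for (i in seq_len(nrow(bl))) {
    sel <- t >= bl$onset[i] & t < bl$onset[i] + bl$duration[i]
    lab[sel] <- bl$label[i]
  }
  lab
}

# Stimulation-block index at each time point; 0 outside blocks.
block_index_at <- function(tl, t) {
  idx <- rep(0L, length(t))
  bl <- timeline_blocks(tl)
  for (i in seq_len(nrow(bl))) {
    sel <- t >= bl$onset[i] & t < bl$onset[i] + bl$duration[i]
    idx[sel] <- i
  }
  idx
}

# Picture onset times (seconds), the loci of phasic SCR events.
picture_onsets <- function(tl) {
  ppb <- attr(tl, "pictures_per_block") %||% 1L
  pd <- attr(tl, "picture_duration") %||%
    min(timeline_blocks(tl)$duration)
  bl <- timeline_blocks(tl)
  unlist(lapply(seq_len(nrow(bl)), function(i)
    bl$onset[i] + (seq_len(ppb) - 1L) * pd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate subject profiles
#'
#' Draws \code{n_subjects} profiles: the female count is fixed at
#' \code{round(fraction_female * n_subjects)} (gender assignment is a
#' seeded permutation), ages are uniform over \code{age_range}, and the
#' six trait scores are truncated normal within their instrument ranges
#' (NEO-FFI extraversion/neuroticism 0--48, BIS 7--28, BAS 13--52, BSRI
#' femininity/masculinity subscale means 1--7).
#'
#' @inheritParams generate_timeline
#' @return A data frame with columns \code{subject_id}, \code{age},
#'   \code{gender}, \code{extraversion}, \code{neuroticism}, \code{bis},
#'   \code{bas}, \code{femininity}, \code{masculinity}.
#' @export
generate_profiles <- function(design, seed = NULL) {
  validate_study_design(design)
  if (is.null(seed)) seed <- substream_seed(design$seed, 0L, salt = 1L)
  n <- design$n_subjects
  n_female <- as.integer(round(design$fraction_female * n))
  with_seed(seed, {
    gender <- rep("male", n)
    gender[sample.int(n, n_female)] <- "female"
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = runif(n, design$age_range[1], design$age_range[2]),
      gender = gender,
      extraversion = rtruncnorm(n, 24, 8, 0, 48),
      neuroticism = rtruncnorm(n, 22, 8, 0, 48),
      bis = rtruncnorm(n, 18, 4, 7, 28),
      bas = rtruncnorm(n, 34, 6, 13, 52),
      femininity = rtruncnorm(n, 4.8, 0.8, 1, 7),
      masculinity = rtruncnorm(n, 4.5, 0.8, 1, 7),
      stringsAsFactors = FALSE
    )
  })
}

# Truncated normal by rejection; bounds are instrument limits, so the
# acceptance region is wide and rejection is cheap.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Synthesize one multichannel recording
#'
#' Generates the four raw channels for one subject over the given
#' timeline:
#' \itemize{
#'   \item \code{scl} (uS): an age-dependent tonic level
#'     (\code{scl_base + age_scl_slope * (age - age_midpoint)} plus a
#'     between-subject tonic deviation), one skin conductance response per
#'     picture onset (difference-of-exponentials kernel, rise 0.75 s,
#'     decay 2 s, amplitude = condition SCR target x gender gain x
#'     subject reactivity), a slow sinusoidal drift and white noise;
#'   \item \code{bvp} (arbitrary units): a pulse waveform whose per-beat
#'     inter-beat intervals are the condition mean heart period plus
#'     Gaussian jitter;
#'   \item \code{emg_corrugator}, \code{emg_zygomaticus} (mV): zero-mean
#'     broadband noise whose SD tracks the condition envelope target
#'     during blocks and the resting level during fixation, plus a 50 Hz
#'     line-interference sinusoid.
#' }
#'
#' @param profile One-row data frame (or list) with at least
#'   \code{subject_id}, \code{age}, \code{gender}.
#' @param timeline An \code{event_timeline}.
#' @param params An \code{\link{effect_params}}.
#' @param sampling_rates Named per-channel rates in Hz.
#' @param seed Integer seed for this recording.
#' @param age_midpoint Age (years) at which the tonic SCL equals
#'   \code{scl_base}.
#' @param channels Which channels to synthesize; per-channel substreams
#'   make a subset identical to the same channels of a full synthesis.
#' @return A \code{raw_recording}: list with \code{subject_id} and
#'   \code{channels}, each channel a list \code{(samples, fs, units)}.
#'   The number of inserted SCRs is attached as attribute \code{n_scr}
#'   of the \code{scl} channel.
#' @export
synthesize_recording <- function(profile, timeline, params = effect_params(),
                                 sampling_rates = c(emg_corrugator = 1000,
                                                    emg_zygomaticus = 1000,
                                                    scl = 32, bvp = 128),
                                 seed = 1L, age_midpoint = 47.5,
                                 channels = c("emg_corrugator",
                                              "emg_zygomaticus",
                                              "scl", "bvp")) {
  validate_timeline(timeline)
  validate_effect_params(params)
  total <- timeline_duration(timeline)
  gender <- as.character(profile$gender)
  if (!gender %in% c("female", "male"))
    stopf("profile gender must be 'female' or 'male'")

  # subject-level draws from a dedicated substream (independent of which
  # channels are requested)
  subj <- with_seed(substream_seed(seed, 0L, salt = 3L), list(
    tonic_dev = rnorm(1, 0, params$scl_tonic_sd),
    react_gain = exp(rnorm(1, 0, params$subject_reactivity_sd)),
    hp_gain = exp(rnorm(1, 0, 0.05))
  ))
  gains <- params$gender_condition_gain[gender, ]

  out <- list(subject_id = as.character(profile$subject_id),
              channels = list())
  units <- c(emg_corrugator = "mV", emg_zygomaticus = "mV",
             scl = "uS", bvp = "a.u.")

  for (ch in channels) {
    fs <- sampling_rates[[ch]]
    sub <- substream_seed(seed, match(ch, names(units)), salt = 4L)
    samples <- with_seed(sub, switch(
      ch,
      scl = synth_scl(profile, timeline, params, fs, total,
                      age_midpoint, subj, gains),
      bvp = synth_bvp(timeline, params, fs, total, subj),
      emg_corrugator = synth_emg(timeline, params$corrugator_env, params,
                                 fs, total, subj, gains),
      emg_zygomaticus = synth_emg(timeline, params$zygomaticus_env, params,
                                  fs, total, subj, gains),
      stopf("unknown channel '%s'", ch)
    ))
    out$channels[[ch]] <- list(samples = samples, fs = fs,
                               units = units[[ch]])
  }
  class(out) <- "raw_recording"
  out
}

# SCR kernel: difference of exponentials, unit peak amplitude.
scr_kernel <- function(fs, rise = 0.75, decay = 2, span = 10) {
  t <- seq(0, span, by = 1 / fs)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

synth_scl <- function(profile, timeline, params, fs, total,
                      age_midpoint, subj, gains) {
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  tonic <- params$scl_base +
    params$age_scl_slope * (profile$age - age_midpoint) + subj$tonic_dev
  x <- rep(tonic, n)
  # slow drift
  x <- x + params$drift_amplitude *
    sin(2 * pi * t / 120 + runif(1, 0, 2 * pi))
  # one SCR per picture onset; block-level lability on top of the
  # per-event amplitude jitter
  kern <- scr_kernel(fs)
  onsets <- picture_onsets(timeline)
  labs <- condition_at(timeline, onsets + 1e-9)
  n_blocks <- nrow(timeline_blocks(timeline))
  block_gain <- exp(rnorm(n_blocks, 0, params$block_reactivity_sd))
  response <- ifelse(runif(length(onsets)) < params$scr_nonresponse_prob,
                     0.1, 1)
  amps <- params$scr_amplitude[labs] * gains[labs] * subj$react_gain *
    block_gain[block_index_at(timeline, onsets + 1e-9)] * response *
    exp(rnorm(length(onsets), 0, params$scr_amp_jitter_sd))
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * fs) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    x[idx] <- x[idx] + amps[i] * kern[seq_along(idx)]
  }
  x <- x + rnorm(n, 0, params$noise_sd[["scl"]])
  x <- pmax(x, 0.01)  # conductance is strictly positive
  attr(x, "n_scr") <- length(onsets)
  x
}

synth_bvp <- function(timeline, params, fs, total, subj) {
  # beat onsets from per-beat inter-beat intervals
  beat_on <- numeric(0)
  t <- 0
  hp <- params$heart_period
  n_blocks <- nrow(timeline_blocks(timeline))
  block_shift <- rnorm(n_blocks, 0, 0.05 * params$block_reactivity_sd)
  while (t < total) {
    beat_on <- c(beat_on, t)
    lab <- condition_at(timeline, t)
    bi <- block_index_at(timeline, t)
    ibi <- hp[[lab]] * subj$hp_gain +
      (if (bi > 0L) block_shift[bi] else 0) +
      rnorm(1, 0, params$heart_period_jitter)
    ibi <- max(ibi, 0.3)
    t <- t + ibi
  }
  n <- round(total * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  tau_p <- 0.15  # pulse peak at a fixed latency after the beat onset
  for (k in seq_along(beat_on)) {
    end <- if (k < length(beat_on)) beat_on[k + 1L] else total
    i0 <- round(beat_on[k] * fs) + 1L
    i1 <- min(n, ceiling(end * fs))
    if (i0 > n) break
    tau <- tt[i0:i1] - beat_on[k]
    x[i0:i1] <- (tau / tau_p) * exp(1 - tau / tau_p)
  }
  x + rnorm(n, 0, params$noise_sd[["bvp"]])
}

synth_emg <- function(timeline, env, params, fs, total, subj, gains) {
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  bl <- timeline_blocks(timeline)
  block_gain <- exp(rnorm(nrow(bl), 0, params$block_reactivity_sd))
  sd_t <- rep(env[["rest"]], n)
  for (i in seq_len(nrow(bl))) {
    cond <- bl$label[i]
    sel <- t >= bl$onset[i] & t < bl$onset[i] + bl$duration[i]
    # multiplicative lability on the reactivity plus an additive
    # block-tone fluctuation; floored so the envelope stays positive
    sd_t[sel] <- max(0.2 * env[["rest"]],
                     env[["rest"]] +
                       (env[[cond]] - env[["rest"]]) * gains[[cond]] *
                       subj$react_gain * block_gain[i] +
                       rnorm(1, 0, 0.15 * env[["rest"]]))
  }
  rnorm(n) * sd_t +
    params$line_amplitude * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("Raw recording, subject", x$subject_id, "\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-16s %8d samples @ %6g Hz (%s), %.1f s\n", nm,
                length(ch$samples), ch$fs, ch$units,
                length(ch$samples) / ch$fs))
  }
  invisible(x)
}

#' Simulate a full cohort
#'
#' Convenience wrapper: one timeline, \code{n_subjects} profiles and one
#' recording per subject, all derived from \code{design$seed}.
#'
#' @param design A \code{\link{study_design}}.
#' @param channels Channels to synthesize (all four by default).
#' @return A list with \code{design}, \code{timeline}, \code{profiles}
#'   and \code{recordings} (named by subject id).
#' @export
simulate_cohort <- function(design = study_design(),
                            channels = c("emg_corrugator",
                                         "emg_zygomaticus",
                                         "scl", "bvp")) {
  validate_study_design(design)
  timeline <- generate_timeline(design)
  profiles <- generate_profiles(design)
  mid <- mean(design$age_range)
  recordings <- lapply(seq_len(nrow(profiles)), function(i) {
    synthesize_recording(profiles[i, ], timeline,
                         params = design$effect_params,
                         sampling_rates = design$sampling_rates,
                         seed = substream_seed(design$seed, i),
                         age_midpoint = mid, channels = channels)
  })
  names(recordings) <- profiles$subject_id
  list(design = design, timeline = timeline, profiles = profiles,
       recordings = recordings)
}
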