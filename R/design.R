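#' Study design for a synthetic induction cohort
#'
#' Describes the cohort and the block-design picture induction: five core
#' affects, each presented in \code{blocks_per_condition} blocks of
#' \code{pictures_per_block} pictures shown for \code{picture_duration}
#' seconds each, every block preceded by a \code{fixation_duration}-second
#' fixation cross. The defaults reproduce the reference design: 100
#' subjects (64\% female, aged 20--75), 5 conditions x 2 blocks, 10
#' pictures of 2 s per block, 20 s fixation, for a 400 s session.
#'
#' @param n_subjects Number of subjects (>= 2 for downstream analyses).
#' @param fraction_female Fraction of female subjects; the realized count
#'   is \code{round(fraction_female * n_subjects)}, not a random draw.
#' @param age_range Two-element numeric, minimum and maximum age in years.
#' @param seed Integer master seed; all randomness derives from it.
#' @param effect_params An \code{\link{effect_params}} object.
#' @param sampling_rates Named numeric vector of per-channel sampling rates
#'   in Hz. Names: \code{emg_corrugator}, \code{emg_zygomaticus},
#'   \code{scl}, \code{bvp}.
#' @param pictures_per_block,picture_duration,blocks_per_condition,fixation_duration
#'   Timeline parameters (counts and seconds).
#' @return An object of class \code{"study_design"}.
#' @export
study_design <- function(n_subjects = 100L,
                         fraction_female = 0.64,
                         age_range = c(20, 75),
                         seed = 1L,
                         effect_params = emophys::effect_params(),
                         sampling_rates = c(emg_corrugator = 1000,
                                            emg_zygomaticus = 1000,
                                            scl = 32, bvp = 128),
                         pictures_per_block = 10L,
                         picture_duration = 2,
                         blocks_per_condition = 2L,
                         fixation_duration = 20) {
  d <- structure(list(
    n_subjects = as.integer(n_subjects),
    fraction_female = fraction_female,
    age_range = as.numeric(age_range),
    seed = as.integer(seed),
    effect_params = effect_params,
    sampling_rates = sampling_rates,
    pictures_per_block = as.integer(pictures_per_block),
    picture_duration = picture_duration,
    blocks_per_condition = as.integer(blocks_per_condition),
    fixation_duration = fixation_duration
  ), class = "study_design")
  validate_study_design(d)
  d
}

validate_study_design <- function(d) {
  if (d$n_subjects < 2L)
    stopf("study_design: n_subjects must be >= 2, got %d", d$n_subjects)
  if (d$fraction_female < 0 || d$fraction_female > 1)
    stopf("study_design: fraction_female must lie in [0, 1]")
  if (length(d$age_range) != 2L || diff(d$age_range) <= 0)
    stopf("study_design: age_range must be [min, max] with max > min")
  req <- c("emg_corrugator", "emg_zygomaticus", "scl", "bvp")
  if (!all(req %in% names(d$sampling_rates)))
    stopf("study_design: sampling_rates must name channels %s",
          paste(req, collapse = ", "))
  if (any(d$sampling_rates <= 0))
    stopf("study_design: sampling rates must be > 0")
  if (d$pictures_per_block < 1L || d$blocks_per_condition < 1L)
    stopf("study_design: block counts must be >= 1")
  if (d$picture_duration <= 0 || d$fixation_duration <= 0)
    stopf("study_design: durations must be > 0")
  invisible(d)
}

#' Effect parameters of the synthetic-signal generator
#'
#' Controls the statistical structure injected into synthetic recordings:
#' an age-dependent tonic skin conductance level, condition-dependent
#' facial-EMG, electrodermal and cardiac reactivity, and a gender-by-
#' condition modulation of phasic reactivity.
#'
#' The defaults target a population age--tonic-SCL Pearson correlation of
#' about -0.45 in a 100-subject cohort aged 20--75 (slope -0.05 uS/year
#' against a between-subject tonic standard deviation of 1.6 uS),
#' corrugator reactivity highest under negative valence (LVHA, LVLA),
#' zygomaticus reactivity highest under positive valence (HVHA, HVLA),
#' larger skin conductance responses under high arousal, mild cardiac
#' acceleration (shorter heart periods) under high arousal, and phasic
#' gains of 2 for females under LVHA and for males under HVHA.
#'
#' @param age_scl_slope Tonic SCL change per year of age (uS/year;
#'   negative by default).
#' @param scl_base Tonic SCL in uS at the midpoint of the age range.
#' @param scl_tonic_sd Between-subject SD of the tonic level (uS).
#' @param gender_condition_gain Numeric matrix, rows \code{female},
#'   \code{male}, columns the five conditions; multiplies phasic
#'   reactivity (SCR amplitudes and EMG reactivity above rest).
#' @param corrugator_env,zygomaticus_env Named target EMG envelope SD (mV)
#'   per condition plus a \code{rest} entry used during fixation.
#' @param scr_amplitude Named SCR amplitude targets per condition (uS).
#' @param scr_nonresponse_prob Probability that a picture elicits only a
#'   minimal (10\%-amplitude) response; emulates the frequent
#'   non-responses of real electrodermal recordings while keeping one
#'   response event per picture.
#' @param scr_amp_jitter_sd Log-normal SD of the per-picture SCR
#'   amplitude jitter.
#' @param heart_period Named mean inter-beat interval per condition plus
#'   \code{rest} (seconds).
#' @param heart_period_jitter Per-beat SD of the inter-beat interval (s).
#' @param subject_reactivity_sd SD of the per-subject log-normal gain on
#'   phasic reactivity (0 disables between-subject reactivity variation).
#' @param block_reactivity_sd SD of the per-block log-normal gain on
#'   phasic reactivity (EMG reactivity above rest, SCR amplitudes) and
#'   of the per-block heart-period shift (x 0.05 s); emulates the
#'   block-to-block lability of real psychophysiological responses.
#' @param noise_sd Named measurement-noise SD per channel
#'   (\code{scl} in uS, \code{bvp} in arbitrary units; EMG noise is the
#'   signal itself and has no separate term).
#' @param line_amplitude Amplitude of the 50 Hz interference added to each
#'   EMG channel (mV).
#' @param drift_amplitude Amplitude of the slow sinusoidal SCL drift (uS).
#' @return An object of class \code{"effect_params"}.
#' @export
effect_params <- function(age_scl_slope = -0.05,
                          scl_base = 8,
                          scl_tonic_sd = 1.6,
                          gender_condition_gain = default_gender_gain(),
                          corrugator_env = c(rest = 0.010, neutral = 0.012,
                                             HVHA = 0.012, HVLA = 0.011,
                                             LVHA = 0.018, LVLA = 0.015),
                          zygomaticus_env = c(rest = 0.010, neutral = 0.012,
                                              HVHA = 0.018, HVLA = 0.015,
                                              LVHA = 0.012, LVLA = 0.011),
                          scr_amplitude = c(neutral = 0.10, HVHA = 0.28,
                                            HVLA = 0.16, LVHA = 0.28,
                                            LVLA = 0.16),
                          scr_nonresponse_prob = 0.3,
                          scr_amp_jitter_sd = 0.5,
                          heart_period = c(rest = 0.86, neutral = 0.85,
                                           HVHA = 0.82, HVLA = 0.84,
                                           LVHA = 0.83, LVLA = 0.845),
                          heart_period_jitter = 0.03,
                          subject_reactivity_sd = 0.4,
                          block_reactivity_sd = 0.8,
                          noise_sd = c(scl = 0.02, bvp = 0.05),
                          line_amplitude = 0.01,
                          drift_amplitude = 0.2) {
  p <- structure(list(
    age_scl_slope = age_scl_slope,
    scl_base = scl_base,
    scl_tonic_sd = scl_tonic_sd,
    gender_condition_gain = gender_condition_gain,
    corrugator_env = corrugator_env,
    zygomaticus_env = zygomaticus_env,
    scr_amplitude = scr_amplitude,
    scr_nonresponse_prob = scr_nonresponse_prob,
    scr_amp_jitter_sd = scr_amp_jitter_sd,
    heart_period = heart_period,
    heart_period_jitter = heart_period_jitter,
    subject_reactivity_sd = subject_reactivity_sd,
    block_reactivity_sd = block_reactivity_sd,
    noise_sd = noise_sd,
    line_amplitude = line_amplitude,
    drift_amplitude = drift_amplitude
  ), class = "effect_params")
  validate_effect_params(p)
  p
}

default_gender_gain <- function() {
  g <- matrix(1, nrow = 2, ncol = 5,
              dimnames = list(c("female", "male"), affect_conditions()))
  g["female", "LVHA"] <- 2.0
  g["male", "HVHA"] <- 2.0
  g
}

validate_effect_params <- function(p) {
  conds <- affect_conditions()
  if (!all(conds %in% colnames(p$gender_condition_gain)) ||
      !all(c("female", "male") %in% rownames(p$gender_condition_gain)))
    stopf("effect_params: gender_condition_gain needs rows female/male and the 5 condition columns")
  for (nm in c("corrugator_env", "zygomaticus_env"))
    if (!all(c("rest", conds) %in% names(p[[nm]])))
      stopf("effect_params: %s must name rest and the 5 conditions", nm)
  if (!all(conds %in% names(p$scr_amplitude)))
    stopf("effect_params: scr_amplitude must name the 5 conditions")
  if (!all(c("rest", conds) %in% names(p$heart_period)))
    stopf("effect_params: heart_period must name rest and the 5 conditions")
  if (any(p$heart_period <= 0))
    stopf("effect_params: heart periods must be > 0")
  invisible(p)
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_subjects, "subjects,",
      sprintf("%.0f%% female, ages %g-%g\n", 100 * x$fraction_female,
              x$age_range[1], x$age_range[2]))
  cat(sprintf("  timeline: %d conditions x %d blocks, %d pictures x %g s per block, %g s fixation\n",
              length(affect_conditions()), x$blocks_per_condition,
              x$pictures_per_block, x$picture_duration, x$fixation_duration))
  cat("  sampling rates:",
      paste(sprintf("%s=%g Hz", names(x$sampling_rates), x$sampling_rates),
            collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
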