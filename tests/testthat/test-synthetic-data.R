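test_that("default timeline reproduces the block design", {
  d <- small_design()
  tl <- generate_timeline(d)
  blocks <- tl[tl$label != "fixation", ]
  expect_equal(nrow(blocks), 10)
  expect_true(all(blocks$duration == 20))
  # every block immediately preceded by a 20 s fixation interval
  idx <- which(tl$label != "fixation")
  expect_true(all(tl$label[idx - 1] == "fixation"))
  expect_true(all(tl$duration[idx - 1] == 20))
  # contiguous, 400 s total, each condition exactly twice
  expect_equal(tl$onset[-1], (tl$onset + tl$duration)[-nrow(tl)])
  expect_equal(max(tl$onset + tl$duration), 400)
  expect_equal(unname(table(blocks$label)[affect_conditions()]),
               rep(2L, 5), ignore_attr = TRUE)
})

test_that("minimal design and determinism of the timeline", {
  d <- small_design(blocks_per_condition = 1, pictures_per_block = 1)
  tl <- generate_timeline(d)
  blocks <- tl[tl$label != "fixation", ]
  expect_equal(nrow(blocks), 5)
  expect_true(all(blocks$duration == 2))
  expect_identical(generate_timeline(small_design()),
                   generate_timeline(small_design()))
  # different seed permutes the block order
  tl2 <- generate_timeline(small_design(seed = 6))
  expect_false(identical(tl$label, tl2$label) &&
               identical(nrow(tl), nrow(tl2)))
})

test_that("profiles have the fixed gender split and in-range traits", {
  d <- study_design(n_subjects = 100, fraction_female = 0.64, seed = 3)
  pr <- generate_profiles(d)
  expect_equal(nrow(pr), 100)
  expect_equal(sum(pr$gender == "female"), 64)
  expect_true(all(pr$age >= 20 & pr$age <= 75))
  expect_true(all(pr$extraversion >= 0 & pr$extraversion <= 48))
  expect_true(all(pr$neuroticism >= 0 & pr$neuroticism <= 48))
  expect_true(all(pr$bis >= 7 & pr$bis <= 28))
  expect_true(all(pr$bas >= 13 & pr$bas <= 52))
  expect_true(all(pr$femininity >= 1 & pr$femininity <= 7))
  expect_true(all(pr$masculinity >= 1 & pr$masculinity <= 7))
  expect_identical(pr, generate_profiles(d))
})

test_that("ages are uniform over the age range", {
  d <- study_design(n_subjects = 10000, seed = 11)
  pr <- generate_profiles(d)
  ks <- suppressWarnings(
    stats::ks.test(pr$age, "punif", 20, 75))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate effect parameters give flat signals", {
  ep <- effect_params(age_scl_slope = 0, scl_tonic_sd = 0,
                      scr_amplitude = c(neutral = 0, HVHA = 0, HVLA = 0,
                                        LVHA = 0, LVLA = 0),
                      scr_nonresponse_prob = 0, scr_amp_jitter_sd = 0,
                      heart_period = c(rest = 0.8, neutral = 0.8,
                                       HVHA = 0.8, HVLA = 0.8,
                                       LVHA = 0.8, LVLA = 0.8),
                      heart_period_jitter = 0, subject_reactivity_sd = 0,
                      block_reactivity_sd = 0,
                      noise_sd = c(scl = 0, bvp = 0),
                      drift_amplitude = 0)
  d <- small_design(effect_params = ep)
  tl <- generate_timeline(d)
  pr <- generate_profiles(d)
  rec <- synthesize_recording(pr[1, ], tl, ep, d$sampling_rates, seed = 9)
  # SCL constant (zero-amplitude SCRs, no drift, no noise)
  expect_lt(diff(range(rec$channels$scl$samples)), 1e-12)
  # all NN intervals equal up to the sampling grid (beat onsets and
  # detected peaks each quantized to the grid: 3 sample periods)
  nn <- detect_beats(rec$channels$bvp$samples, rec$channels$bvp$fs)
  expect_lte(diff(range(nn$intervals)), 3 * 1000 / rec$channels$bvp$fs)
  expect_equal(mean(nn$intervals), 800, tolerance = 0.01)
})

test_that("recordings are deterministic and conserve SCR count", {
  d <- small_design()
  tl <- generate_timeline(d)
  pr <- generate_profiles(d)
  r1 <- synthesize_recording(pr[2, ], tl, d$effect_params,
                             d$sampling_rates, seed = 21)
  r2 <- synthesize_recording(pr[2, ], tl, d$effect_params,
                             d$sampling_rates, seed = 21)
  expect_identical(r1, r2)
  # one SCR per picture onset: 10 blocks x 10 pictures
  expect_equal(attr(r1$channels$scl$samples, "n_scr"), 100)
  # channel durations agree within one sample period
  durs <- vapply(r1$channels, function(ch) length(ch$samples) / ch$fs,
                 numeric(1))
  expect_lt(diff(range(durs)), 1 / min(d$sampling_rates))
  # SCL strictly positive
  expect_true(all(r1$channels$scl$samples > 0))
})

test_that("a channel subset reproduces the same channels of a full synthesis", {
  d <- small_design()
  tl <- generate_timeline(d)
  pr <- generate_profiles(d)
  full <- synthesize_recording(pr[1, ], tl, d$effect_params,
                               d$sampling_rates, seed = 33)
  only_scl <- synthesize_recording(pr[1, ], tl, d$effect_params,
                                   d$sampling_rates, seed = 33,
                                   channels = "scl")
  expect_identical(only_scl$channels$scl, full$channels$scl)
})

test_that("EMG channels are zero-mean broadband noise", {
  d <- small_design()
  tl <- generate_timeline(d)
  pr <- generate_profiles(d)
  rec <- synthesize_recording(pr[3, ], tl, d$effect_params,
                              d$sampling_rates, seed = 44,
                              channels = c("emg_corrugator",
                                           "emg_zygomaticus"))
  for (ch in rec$channels) {
    expect_lt(abs(mean(ch$samples)), 0.01 * stats::sd(ch$samples))
    # 50 Hz interference present
    expect_gt(fft_amplitude(ch$samples, ch$fs, 50), 0.005)
  }
})

test_that("invalid designs are rejected", {
  expect_error(study_design(n_subjects = 1), "n_subjects")
  expect_error(study_design(age_range = c(50, 50)), "age_range")
  expect_error(study_design(picture_duration = 0), "durations")
  expect_error(study_design(fraction_female = 1.2), "fraction_female")
})
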