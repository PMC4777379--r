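test_that("subgroup splitting is deterministic and partitions subjects", {
  pr <- data.frame(subject_id = c("s1", "s2"), age = c(24, 60),
                   gender = c("female", "male"),
                   stringsAsFactors = FALSE)
  gr <- suppressWarnings(split_subgroups(pr))
  expect_equal(gr$young_female, "s1")
  expect_equal(gr$elderly_male, "s2")
  expect_setequal(names(gr), c("all", "young_all", "young_female",
                               "young_male", "elderly_all",
                               "elderly_female", "elderly_male",
                               "female", "male"))
  pr2 <- data.frame(subject_id = sprintf("s%d", 1:4), age = 30,
                    gender = c("female", "male", "female", "male"),
                    stringsAsFactors = FALSE)
  expect_warning(gr2 <- split_subgroups(pr2), "empty subgroup")
  expect_length(gr2$elderly_all, 0)
  # partitions are consistent
  cf <- small_cohort_features()
  gr3 <- suppressWarnings(split_subgroups(cf$profiles))
  expect_setequal(c(gr3$young_all, gr3$elderly_all), gr3$all)
  expect_setequal(c(gr3$female, gr3$male), gr3$all)
  expect_length(gr3$all,
                length(gr3$young_female) + length(gr3$young_male) +
                length(gr3$elderly_female) + length(gr3$elderly_male))
})

test_that("LOSO folds hold out each subject exactly once", {
  ids <- sprintf("s%02d", 1:9)
  folds <- loso_folds(ids)
  expect_length(folds, 9)
  expect_setequal(vapply(folds, `[[`, "", "test"), ids)
  for (f in folds) {
    expect_false(f$test %in% f$train)
    expect_length(f$train, 8)
  }
  expect_error(loso_folds("s1"), "2 subjects")
})

test_that("task specifications map conditions to classes", {
  v3 <- task_spec("valence3")
  expect_equal(unname(v3$classes[c("HVHA", "HVLA")]),
               c("positive", "positive"))
  expect_equal(unname(v3$classes[c("LVHA", "LVLA")]),
               c("negative", "negative"))
  a5 <- task_spec("affect5")
  expect_length(unique(a5$classes), 5)
  b <- task_spec("neutral_vs_LVHA")
  expect_setequal(names(b$classes), c("neutral", "LVHA"))
  expect_error(task_spec("neutral_vs_rest"), "unknown condition")
  expect_error(task_spec("arousal7"), "unknown task")
})

test_that("forward selection finds the separating feature first", {
  # score function: only feature 'mean_RR' carries information
  score <- function(fs) 0.9 * ("mean_RR" %in% fs) + 0.001 * length(fs)
  sel <- wrapper_select(feature_names(), score, method = "forward")
  expect_equal(sel[1], "mean_RR")
  # adding more features keeps improving by the length bonus, so the
  # greedy path must have started with the informative one
  score2 <- function(fs) 0.9 * ("SCL_slope" %in% fs)
  sel2 <- wrapper_select(feature_names(), score2, method = "forward")
  expect_equal(sel2, "SCL_slope")
})

test_that("ties collapse to a single canonical feature", {
  sel <- wrapper_select(feature_names(), function(fs) 0.5,
                        method = "forward")
  expect_equal(sel, feature_names()[1])
})

test_that("backward elimination keeps a jointly required pair", {
  score <- function(fs)
    if (all(c("SCL_mean", "SCL_std") %in% fs))
      1 - 0.001 * length(fs) else 0.4
  sel <- wrapper_select(c("SCL_mean", "SCL_std", "RMSSD", "mean_RR"),
                        score, method = "backward")
  expect_true(all(c("SCL_mean", "SCL_std") %in% sel))
  expect_false("RMSSD" %in% sel)
})

test_that("perfectly separable features classify at 100%", {
  subjects <- sprintf("s%02d", 1:8)
  fm <- toy_feature_matrix(subjects, affect_conditions(),
                           features = c("SCL_mean", "SCL_std", "RMSSD"))
  level <- c(neutral = 0, HVHA = 5, HVLA = 5, LVHA = 10, LVLA = 10)
  for (f in c("SCL_mean", "SCL_std", "RMSSD"))
    fm[[f]] <- level[fm$condition] + fm[[f]]
  res <- classify_task(fm, subjects, "valence3", selection = "none")
  expect_equal(res$accuracy, 100)
  expect_equal(res$n_subjects, 8)
  expect_equal(res$n_rows, 40)
})

test_that("reported accuracy is the max over both selection methods", {
  subjects <- sprintf("s%02d", 1:8)
  fm <- toy_feature_matrix(subjects, c("neutral", "HVHA"), seed = 4,
                           features = c("mean_RR", "mean_amp_Zyg",
                                        "SCL_mean", "SCL_std",
                                        "SCL_slope"))
  fm$mean_amp_Zyg <- ifelse(fm$condition == "HVHA", 2, -2) +
    0.5 * fm$mean_amp_Zyg * 1e3
  res <- classify_task(fm, subjects, "neutral_vs_HVHA",
                       selection = "both")
  expect_equal(res$accuracy, unname(max(res$accuracy_by_method)))
  expect_length(res$accuracy_by_method, 2)
  expect_true(res$method %in% c("forward", "backward"))
  expect_true(all(res$selected %in% feature_names()))
  # determinism: identical inputs give identical reports
  res2 <- classify_task(fm, subjects, "neutral_vs_HVHA",
                        selection = "both")
  expect_identical(res[names(res) != "selected_by_fold"],
                   res2[names(res2) != "selected_by_fold"])
})

test_that("degenerate classification inputs error cleanly", {
  subjects <- sprintf("s%02d", 1:8)
  fm <- toy_feature_matrix(subjects, c("neutral", "LVHA"))
  expect_error(classify_task(fm, subjects[1], "neutral_vs_LVHA"),
               "2 subjects")
  fm_one <- fm[fm$condition == "neutral", ]
  expect_error(classify_task(fm_one, subjects, "neutral_vs_LVHA"),
               "single class")
})

test_that("selection ranking counts and signal-group shares", {
  mk <- function(selected) {
    structure(list(selected = selected, features = feature_names(),
                   accuracy = 80, method = "forward"),
              class = "classification_result")
  }
  res <- list(g1 = list(mk("mean_amp_Corr")),
              g2 = list(mk(c("mean_amp_Corr", "RMSSD", "SCL_mean"))))
  rk <- rank_selected_features(res)
  expect_equal(rk$ranking$amount[rk$ranking$feature == "mean_amp_Corr"], 2)
  expect_equal(rk$ranking$feature[1], "mean_amp_Corr")
  expect_equal(rk$ranking$ranking, seq_len(20))
  # shares sum to 1 within each subgroup
  sums <- as.numeric(tapply(rk$shares$share, rk$shares$subgroup, sum))
  expect_equal(sums, rep(1, 2), tolerance = 1e-12)
  # a run selecting every feature once gives uniform counts
  rk2 <- rank_selected_features(list(all = list(mk(feature_names()))))
  expect_true(all(rk2$ranking$amount == 1))
})

test_that("label permutation leaves the held-out predictions at chance", {
  # leakage guard: fold models never see the held-out subject, so
  # permuting one held-out subject's labels cannot change predictions
  subjects <- sprintf("s%02d", 1:8)
  fm <- toy_feature_matrix(subjects, c("neutral", "LVHA"), seed = 6,
                           features = c("SCL_mean", "SCL_std", "RMSSD"))
  fm$SCL_mean <- ifelse(fm$condition == "LVHA", 5, 0)
  res <- classify_task(fm, subjects, "neutral_vs_LVHA", selection = "none")
  fm_swapped <- fm
  idx <- fm_swapped$subject_id == "s01"
  fm_swapped$condition[idx] <- rev(fm_swapped$condition[idx])
  res_swapped <- classify_task(fm_swapped, subjects, "neutral_vs_LVHA",
                               selection = "none")
  # same number of rows predicted; s01's accuracy flips, others identical
  expect_equal(res$n_rows, res_swapped$n_rows)
  expect_equal(res$accuracy - res_swapped$accuracy,
               100 * sum(idx) / res$n_rows)
})
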