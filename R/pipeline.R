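#' Pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic study design,
#' preprocessing settings, the reduction threshold, the screening
#' variables and family alpha, and the classification tasks, subgroups
#' and SVM settings. Serializes losslessly to YAML via
#' \code{\link{write_config}} / \code{\link{read_config}}.
#'
#' @param design A \code{\link{study_design}}.
#' @param baseline_window Pre-block baseline window (s).
#' @param amp_threshold SCR-amplitude threshold (uS).
#' @param reduction_threshold Absolute-correlation removal threshold.
#' @param screening_variables Profile variables to screen.
#' @param family_alpha Family-wise alpha for screening.
#' @param tasks Character vector of task names (empty to stop the
#'   pipeline after screening).
#' @param subgroups Subgroup names to classify (subset of the nine
#'   emitted by \code{\link{split_subgroups}}).
#' @param age_cutoff Young/elderly boundary (years).
#' @param selection Wrapper-selection mode for classification.
#' @param svm \code{\link{svm_params}}.
#' @param write_signals Also write the raw channel signals as text
#'   (large; off by default).
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(design = study_design(),
                            baseline_window = 2,
                            amp_threshold = 0.05,
                            reduction_threshold = 0.95,
                            screening_variables = c("age", "masculinity",
                                                    "femininity",
                                                    "extraversion",
                                                    "neuroticism",
                                                    "bis", "bas"),
                            family_alpha = 0.05,
                            tasks = c("valence3", "affect5"),
                            subgroups = "all",
                            age_cutoff = 45,
                            selection = "both",
                            svm = svm_params(),
                            write_signals = FALSE) {
  if (reduction_threshold <= 0 || reduction_threshold > 1)
    stopf("pipeline_config: reduction_threshold must lie in (0, 1]")
  if (family_alpha <= 0 || family_alpha >= 1)
    stopf("pipeline_config: family_alpha must lie in (0, 1)")
  validate_study_design(design)
  structure(list(design = design, baseline_window = baseline_window,
                 amp_threshold = amp_threshold,
                 reduction_threshold = reduction_threshold,
                 screening_variables = screening_variables,
                 family_alpha = family_alpha, tasks = tasks,
                 subgroups = subgroups, age_cutoff = age_cutoff,
                 selection = selection, svm = svm,
                 write_signals = write_signals),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$design <- unclass(lst$design)
  ep <- unclass(lst$design$effect_params)
  g <- ep$gender_condition_gain
  ep$gender_condition_gain <-
    list(female = as.list(stats::setNames(g["female", ], colnames(g))),
         male = as.list(stats::setNames(g["male", ], colnames(g))))
  # named atomic vectors must become lists: YAML sequences drop names
  for (nm in c("corrugator_env", "zygomaticus_env", "scr_amplitude",
               "heart_period", "noise_sd"))
    ep[[nm]] <- as.list(ep[[nm]])
  lst$design$effect_params <- ep
  lst$design$sampling_rates <- as.list(lst$design$sampling_rates)
  lst$svm <- unclass(lst$svm)
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ep <- lst$design$effect_params
  g <- rbind(female = unlist(ep$gender_condition_gain$female),
             male = unlist(ep$gender_condition_gain$male))
  params <- effect_params(
    age_scl_slope = ep$age_scl_slope, scl_base = ep$scl_base,
    scl_tonic_sd = ep$scl_tonic_sd, gender_condition_gain = g,
    corrugator_env = unlist(ep$corrugator_env),
    zygomaticus_env = unlist(ep$zygomaticus_env),
    scr_amplitude = unlist(ep$scr_amplitude),
    scr_nonresponse_prob = ep$scr_nonresponse_prob,
    scr_amp_jitter_sd = ep$scr_amp_jitter_sd,
    heart_period = unlist(ep$heart_period),
    heart_period_jitter = ep$heart_period_jitter,
    subject_reactivity_sd = ep$subject_reactivity_sd,
    block_reactivity_sd = ep$block_reactivity_sd,
    noise_sd = unlist(ep$noise_sd),
    line_amplitude = ep$line_amplitude,
    drift_amplitude = ep$drift_amplitude)
  d <- lst$design
  design <- study_design(
    n_subjects = d$n_subjects, fraction_female = d$fraction_female,
    age_range = unlist(d$age_range), seed = d$seed,
    effect_params = params, sampling_rates = unlist(d$sampling_rates),
    pictures_per_block = d$pictures_per_block,
    picture_duration = d$picture_duration,
    blocks_per_condition = d$blocks_per_condition,
    fixation_duration = d$fixation_duration)
  pipeline_config(
    design = design, baseline_window = lst$baseline_window,
    amp_threshold = lst$amp_threshold,
    reduction_threshold = lst$reduction_threshold,
    screening_variables = unlist(lst$screening_variables),
    family_alpha = lst$family_alpha, tasks = unlist(lst$tasks),
    subgroups = unlist(lst$subgroups), age_cutoff = lst$age_cutoff,
    selection = lst$selection,
    svm = do.call(svm_params, lst$svm[c("cost", "gamma", "tune",
                                        "cost_grid",
                                        "gamma_scale_grid")]),
    write_signals = lst$write_signals)
}

#' Run the end-to-end pipeline
#'
#' Simulate -> preprocess/extract -> reduce -> screen -> classify ->
#' rank, writing every stage's artifact into \code{out_dir}:
#' \code{profiles.csv}, \code{events.tsv}, optionally
#' \code{signals/}, \code{features_raw.csv}, \code{reduction.json},
#' \code{features_reduced.csv}, \code{screening.csv},
#' \code{classification/<subgroup>_<task>.json}, \code{ranking.csv},
#' \code{shares.csv}, plus \code{config.yaml}, a \code{manifest.json}
#' (config hash, seed, package version) and a structured
#' \code{pipeline.log}. With no classification tasks configured, the
#' run stops after \code{screening.csv}.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory.
#' @return The collected results, invisibly: list with
#'   \code{features}, \code{reduction}, \code{screening},
#'   \code{results}, \code{ranking}.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stopf("run_pipeline: config must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_stage <- function(stage, ...) {
    cat(sprintf("[%s] %s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage, sprintf(...)), file = logf, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  # simulate + extract subject by subject so raw signals never pile up
  design <- config$design
  timeline <- run_stage("simulate", generate_timeline(design))
  profiles <- run_stage("simulate", generate_profiles(design))
  write_profiles(profiles, file.path(out_dir, "profiles.csv"))
  write_timeline(timeline, file.path(out_dir, "events.tsv"))
  log_stage("simulate", "%d subjects, %d timeline events",
            nrow(profiles), nrow(timeline))

  mid <- mean(design$age_range)
  features <- run_stage("extract", {
    fm <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
      rec <- synthesize_recording(
        profiles[i, ], timeline, params = design$effect_params,
        sampling_rates = design$sampling_rates,
        seed = substream_seed(design$seed, i), age_midpoint = mid)
      if (isTRUE(config$write_signals))
        write_recording(rec, file.path(out_dir, "signals"))
      extract_features(rec, timeline,
                       baseline_window = config$baseline_window,
                       amp_threshold = config$amp_threshold)
    }))
    rownames(fm) <- NULL
    as_feature_matrix(fm, provenance = "raw")
  })
  write_feature_matrix(features, file.path(out_dir, "features_raw.csv"))
  log_stage("extract", "%d feature rows", nrow(features))
  cohort <- list(profiles = profiles, timeline = timeline)

  reduction <- run_stage("reduce", reduce_by_correlation(
    features, threshold = config$reduction_threshold))
  write_reduction(reduction, file.path(out_dir, "reduction.json"))
  reduced <- apply_reduction(features, reduction)
  write_feature_matrix(reduced, file.path(out_dir, "features_reduced.csv"))
  log_stage("reduce", "%d features retained", length(reduction$retained))

  screening <- run_stage("screen", screen_variables(
    features, cohort$profiles, variables = config$screening_variables,
    family_alpha = config$family_alpha))
  write_screening(screening, file.path(out_dir, "screening.csv"))
  log_stage("screen", "%d tests, %d significant", nrow(screening),
            sum(screening$significant))

  results <- NULL
  ranking <- NULL
  if (length(config$tasks)) {
    groups <- split_subgroups(cohort$profiles, config$age_cutoff)
    dir.create(file.path(out_dir, "classification"), showWarnings = FALSE)
    results <- list()
    for (sg in intersect(config$subgroups, names(groups))) {
      if (length(groups[[sg]]) < 2L) next
      results[[sg]] <- list()
      for (tk in config$tasks) {
        res <- run_stage("classify", classify_task(
          reduced, groups[[sg]], tk, params = config$svm,
          selection = config$selection))
        results[[sg]][[tk]] <- res
        jsonlite::write_json(
          list(subgroup = sg, task = tk, accuracy = res$accuracy,
               method = res$method,
               accuracy_by_method = as.list(res$accuracy_by_method),
               selected = res$selected, n_subjects = res$n_subjects,
               n_rows = res$n_rows, config_hash = cfg_hash),
          file.path(out_dir, "classification",
                    sprintf("%s_%s.json", sg, tk)),
          auto_unbox = TRUE, digits = NA)
        log_stage("classify", "%s/%s accuracy %.1f%%", sg, tk,
                  res$accuracy)
      }
    }
    ranking <- run_stage("rank", rank_selected_features(results))
    utils::write.csv(ranking$ranking, file.path(out_dir, "ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(ranking$shares, file.path(out_dir, "shares.csv"),
                     row.names = FALSE)
  }

  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = config$design$seed,
         package = "emophys",
         version = as.character(utils::packageVersion("emophys"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  log_stage("done", "artifacts in %s", out_dir)
  invisible(list(features = features, reduction = reduction,
                 screening = screening, results = results,
                 ranking = ranking))
}
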