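# Subgroup-specific affect classification: RBF-kernel SVM under
# leave-one-subject-out validation with wrapper feature selection.

#' Split subjects into gender-by-age subgroups
#'
#' Deterministic assignment: \code{age < age_cutoff} is "young",
#' otherwise "elderly". Emits the nine named subgroups
#' \code{all, young_all, young_female, young_male, elderly_all,
#' elderly_female, elderly_male, female, male}; empty subgroups are kept
#' (with a warning) so callers can skip them.
#'
#' @param profiles Subject profiles.
#' @param age_cutoff Boundary between young and elderly, in years.
#' @return Named list of subject-id character vectors.
#' @export
split_subgroups <- function(profiles, age_cutoff = 45) {
  if (nrow(profiles) == 0L) stopf("split_subgroups: no profiles")
  young <- profiles$age < age_cutoff
  fem <- profiles$gender == "female"
  ids <- profiles$subject_id
  gr <- list(all = ids,
             young_all = ids[young],
             young_female = ids[young & fem],
             young_male = ids[young & !fem],
             elderly_all = ids[!young],
             elderly_female = ids[!young & fem],
             elderly_male = ids[!young & !fem],
             female = ids[fem],
             male = ids[!fem])
  empty <- names(gr)[vapply(gr, length, 1L) == 0L]
  if (length(empty))
    warning("empty subgroup(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  gr
}

#' Leave-one-subject-out folds
#'
#' One fold per subject; all rows of a subject stay on the same side of
#' the split, and the held-out subject never appears in its own
#' training set.
#'
#' @param subject_ids Character vector of subject ids (>= 2).
#' @return List of \code{list(train, test)} id sets.
#' @export
loso_folds <- function(subject_ids) {
  subject_ids <- unique(subject_ids)
  if (length(subject_ids) < 2L)
    stopf("loso_folds: need at least 2 subjects, got %d",
          length(subject_ids))
  lapply(subject_ids, function(s)
    list(train = setdiff(subject_ids, s), test = s))
}

#' Classification task specifications
#'
#' \describe{
#'   \item{\code{affect5}}{all five conditions as singleton classes
#'     (chance 20\%).}
#'   \item{\code{valence3}}{neutral vs positive (HVHA + HVLA) vs
#'     negative (LVHA + LVLA) (chance 33.3\%).}
#'   \item{\code{neutral_vs_<COND>}}{neutral against one arousing
#'     condition; remaining rows are dropped (chance 50\%).}
#' }
#'
#' @param name Task name, e.g. \code{"affect5"}, \code{"valence3"},
#'   \code{"neutral_vs_LVHA"}.
#' @return A \code{task_spec}: list with \code{name} and \code{classes},
#'   a named map condition -> class label (conditions absent from the
#'   map are excluded from the task).
#' @export
task_spec <- function(name) {
  conds <- affect_conditions()
  classes <- if (name == "affect5") {
    stats::setNames(conds, conds)
  } else if (name == "valence3") {
    c(neutral = "neutral", HVHA = "positive", HVLA = "positive",
      LVHA = "negative", LVLA = "negative")
  } else if (grepl("^neutral_vs_", name)) {
    other <- sub("^neutral_vs_", "", name)
    if (!other %in% conds[-1])
      stopf("task_spec: unknown condition '%s'", other)
    stats::setNames(c("neutral", other), c("neutral", other))
  } else {
    stopf("task_spec: unknown task '%s'", name)
  }
  structure(list(name = name, classes = classes), class = "task_spec")
}

#' SVM hyper-parameters
#'
#' Radial-basis-kernel SVM settings. With \code{tune = TRUE}, cost and
#' kernel width are selected per outer fold by an inner
#' leave-one-subject-out grid search over \code{cost_grid} x
#' \code{gamma_scale_grid} (the latter multiplies the default width
#' 1/n_features) on the training subjects only.
#'
#' @param cost Soft-margin cost C.
#' @param gamma Kernel width; \code{NULL} uses 1/n_features.
#' @param tune Tune cost and width per outer fold.
#' @param cost_grid,gamma_scale_grid Log-spaced grids used when tuning.
#' @return A list of class \code{"svm_params"}.
#' @export
svm_params <- function(cost = 1, gamma = NULL, tune = FALSE,
                       cost_grid = c(0.1, 1, 10),
                       gamma_scale_grid = c(0.25, 1, 4)) {
  structure(list(cost = cost, gamma = gamma, tune = tune,
                 cost_grid = cost_grid,
                 gamma_scale_grid = gamma_scale_grid),
            class = "svm_params")
}

# Fit an RBF SVM with inverse-class-frequency weights; constant columns
# are dropped before fitting (scaling is fit on training rows only).
fit_svm <- function(x, y, params) {
  keep <- which(apply(x, 2, stats::sd) > 0)
  if (length(keep) == 0L) keep <- 1L
  w <- 1 / table(y)
  w <- w * length(w) / sum(w)
  gamma <- params$gamma %||% (1 / length(keep))
  fit <- e1071::svm(x[, keep, drop = FALSE], factor(y),
                    kernel = "radial", cost = params$cost, gamma = gamma,
                    class.weights = w, scale = TRUE)
  list(fit = fit, keep = keep)
}

predict_svm <- function(model, x) {
  as.character(stats::predict(model$fit, x[, model$keep, drop = FALSE]))
}

# Inner LOSO accuracy of a feature subset on the training subjects.
inner_loso_score <- function(x, y, groups, feats, params) {
  ids <- unique(groups)
  correct <- 0L
  total <- 0L
  for (s in ids) {
    tr <- groups != s
    if (length(unique(y[tr])) < 2L) next
    m <- fit_svm(x[tr, feats, drop = FALSE], y[tr], params)
    pred <- predict_svm(m, x[!tr, feats, drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
    total <- total + sum(!tr)
  }
  if (total == 0L) return(0)
  correct / total
}

#' Greedy wrapper feature selection
#'
#' Forward selection starts from the empty set and greedily adds the
#' feature that maximizes the scorer, stopping when no addition
#' improves the score; backward elimination starts from the full set
#' and greedily removes the feature whose removal maximizes the score,
#' stopping when no removal improves it. Ties are broken by canonical
#' feature order, and the returned subset is never empty.
#'
#' @param features Candidate feature names (canonical order).
#' @param score_fn Function(feature subset) -> score to maximize
#'   (typically inner leave-one-subject-out accuracy).
#' @param method \code{"forward"} or \code{"backward"}.
#' @return Character vector of selected features.
#' @export
wrapper_select <- function(features, score_fn,
                           method = c("forward", "backward")) {
  method <- match.arg(method)
  eps <- 1e-9
  if (method == "forward") {
    sel <- character(0)
    best <- -Inf
    repeat {
      cand <- setdiff(features, sel)
      if (!length(cand)) break
      scores <- vapply(cand, function(f) score_fn(c(sel, f)), numeric(1))
      i <- which.max(scores)  # first max = canonical tie-break
      if (scores[i] > best + eps) {
        sel <- c(sel, cand[i])
        best <- scores[i]
      } else break
    }
    if (!length(sel)) sel <- features[1L]
    sel
  } else {
    sel <- features
    best <- score_fn(sel)
    while (length(sel) > 1L) {
      scores <- vapply(sel, function(f) score_fn(setdiff(sel, f)),
                       numeric(1))
      i <- which.max(scores)
      if (scores[i] > best + eps) {
        sel <- setdiff(sel, sel[i])
        best <- scores[i]
      } else break
    }
    sel
  }
}

#' Leave-one-subject-out SVM classification of one task
#'
#' For each outer fold (one held-out subject), optionally tunes the SVM
#' on the training subjects, runs wrapper feature selection with an
#' inner leave-one-subject-out scorer on the training subjects only,
#' fits the SVM on the selected features (scaling fit on training rows),
#' and predicts every row of the held-out subject. Accuracy is the
#' percentage of correctly classified held-out rows pooled over folds.
#' When both selection methods run, the reported accuracy is their
#' maximum.
#'
#' @param matrix A \code{feature_matrix} (typically reduced).
#' @param subgroup Character vector of subject ids to analyze.
#' @param task A \code{\link{task_spec}} (or task name).
#' @param params \code{\link{svm_params}}.
#' @param selection \code{"both"}, \code{"forward"}, \code{"backward"},
#'   or \code{"none"} (no selection; all features used).
#' @return A \code{classification_result}: \code{accuracy} (\%; max over
#'   the selection methods run), \code{method} (winning method),
#'   \code{accuracy_by_method}, \code{selected} (features chosen in more
#'   than half of the winning method's folds), \code{selected_by_fold},
#'   \code{n_subjects}, \code{n_rows}, \code{subgroup_name},
#'   \code{task}.
#' @export
classify_task <- function(matrix, subgroup, task,
                          params = svm_params(),
                          selection = c("both", "forward", "backward",
                                        "none")) {
  selection <- match.arg(selection)
  if (is.character(task)) task <- task_spec(task)
  feats <- intersect(feature_names(), names(matrix))
  rows <- matrix[matrix$subject_id %in% subgroup &
                 matrix$condition %in% names(task$classes), , drop = FALSE]
  if (nrow(rows) == 0L)
    stopf("classify_task: no rows for task '%s' in this subgroup",
          task$name)
  y <- unname(task$classes[rows$condition])
  if (length(unique(y)) < 2L)
    stopf("classify_task: task '%s' has a single class here", task$name)
  groups <- rows$subject_id
  ids <- unique(groups)
  if (length(ids) < 2L)
    stopf("classify_task: need at least 2 subjects, got %d", length(ids))
  x <- as.matrix(rows[, feats, drop = FALSE])

  methods <- switch(selection,
                    both = c("forward", "backward"),
                    none = "none",
                    selection)
  pred <- lapply(methods, function(m) character(nrow(x)))
  names(pred) <- methods
  sel_by_fold <- lapply(methods, function(m) list())
  names(sel_by_fold) <- methods

  for (fold in loso_folds(ids)) {
    tr <- groups %in% fold$train
    te <- !tr
    if (length(unique(y[tr])) < 2L) {
      warning("degenerate fold (single training class) skipped for subject ",
              fold$test, call. = FALSE)
      next
    }
    p_fold <- params
    if (isTRUE(params$tune)) {
      grid <- expand.grid(cost = params$cost_grid,
                          gs = params$gamma_scale_grid)
      sc <- vapply(seq_len(nrow(grid)), function(i) {
        pi <- params
        pi$cost <- grid$cost[i]
        pi$gamma <- grid$gs[i] / length(feats)
        inner_loso_score(x[tr, , drop = FALSE], y[tr], groups[tr],
                         feats, pi)
      }, numeric(1))
      p_fold$cost <- grid$cost[which.max(sc)]
      p_fold$gamma <- grid$gs[which.max(sc)] / length(feats)
      p_fold$tune <- FALSE
    }
    for (m in methods) {
      sel <- if (m == "none") feats else
        wrapper_select(feats, function(fs)
          inner_loso_score(x[tr, , drop = FALSE], y[tr], groups[tr],
                           fs, p_fold),
          method = m)
      fitted <- fit_svm(x[tr, sel, drop = FALSE], y[tr], p_fold)
      pred[[m]][te] <- predict_svm(fitted, x[te, sel, drop = FALSE])
      sel_by_fold[[m]][[fold$test]] <- sel
    }
  }

  scored <- !vapply(seq_len(nrow(x)), function(i)
    all(vapply(methods, function(m) pred[[m]][i] == "", TRUE)), TRUE)
  acc <- vapply(methods, function(m)
    100 * mean(pred[[m]][scored] == y[scored]), numeric(1))
  winner <- methods[which.max(acc)]
  n_folds <- length(sel_by_fold[[winner]])
  counts <- table(unlist(sel_by_fold[[winner]]))
  majority <- names(counts)[counts > n_folds / 2]
  structure(list(
    accuracy = unname(max(acc)),
    method = winner,
    accuracy_by_method = acc,
    selected = intersect(feats, majority),
    selected_by_fold = sel_by_fold,
    n_subjects = length(ids),
    n_rows = sum(scored),
    task = task$name,
    features = feats
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Task %s: accuracy %.1f%% (%s selection; %d subjects, %d rows)\n",
              x$task, x$accuracy, x$method, x$n_subjects, x$n_rows))
  if (length(x$selected))
    cat("  selected (majority of folds):",
        paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Rank selected features across classification runs
#'
#' Counts, per feature, how many runs selected it (one selection set per
#' run: the winning method's majority-of-folds set), and computes
#' per-signal-group selection shares: each group's count divided by the
#' number of candidate features in the group, normalized to sum to 1
#' within each subgroup.
#'
#' @param results Named list (names = subgroup labels) of lists of
#'   \code{classification_result}s, or a flat list with a
#'   \code{subgroup} attribute per element.
#' @return List with \code{ranking} (data frame \code{feature},
#'   \code{signal}, \code{amount}, \code{ranking}) and \code{shares}
#'   (data frame \code{subgroup}, \code{signal}, \code{share}).
#' @export
rank_selected_features <- function(results) {
  if (length(results) == 0L) stopf("rank_selected_features: no results")
  if (!is.list(results[[1L]]) || inherits(results[[1L]], "classification_result"))
    results <- list(all = results)
  grp <- feature_signal_groups()
  universe <- unique(unlist(lapply(unlist(results, recursive = FALSE),
                                   function(r) r$features)))
  universe <- intersect(feature_names(), universe)
  counts <- stats::setNames(rep(0L, length(universe)), universe)
  share_rows <- list()
  for (sg in names(results)) {
    sg_counts <- stats::setNames(rep(0L, length(universe)), universe)
    for (r in results[[sg]]) {
      sel <- intersect(universe, r$selected)
      counts[sel] <- counts[sel] + 1L
      sg_counts[sel] <- sg_counts[sel] + 1L
    }
    g_share <- vapply(unique(grp[universe]), function(g) {
      members <- universe[grp[universe] == g]
      sum(sg_counts[members]) / length(members)
    }, numeric(1))
    if (sum(g_share) > 0) g_share <- g_share / sum(g_share)
    share_rows[[sg]] <- data.frame(subgroup = sg,
                                   signal = names(g_share),
                                   share = unname(g_share),
                                   stringsAsFactors = FALSE)
  }
  ord <- order(-counts, match(names(counts), feature_names()))
  ranking <- data.frame(feature = names(counts)[ord],
                        signal = unname(grp[names(counts)[ord]]),
                        amount = unname(counts[ord]),
                        ranking = seq_along(counts),
                        stringsAsFactors = FALSE)
  list(ranking = ranking, shares = do.call(rbind, share_rows))
}

#' Permute condition labels within each subject
#'
#' Utility for permutation-null checks: shuffles the condition labels of
#' each subject's rows, so features and labels become independent while
#' the per-subject label balance is preserved.
#'
#' @param matrix A \code{feature_matrix}.
#' @param seed Integer seed.
#' @return The matrix with permuted \code{condition} labels.
#' @export
permute_conditions <- function(matrix, seed = 1L) {
  with_seed(seed, {
    for (s in unique(matrix$subject_id)) {
      idx <- which(matrix$subject_id == s)
      matrix$condition[idx] <- sample(matrix$condition[idx])
    }
  })
  matrix
}
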