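#' Bonferroni-corrected significance level
#'
#' @param family_alpha Family-wise error rate (default 0.05).
#' @param m Number of screened variables (>= 1).
#' @return \code{family_alpha / m}; with the seven screened subject
#'   variables this is 0.00714..., the conventional "p < 0.007" level.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m) {
  if (length(m) != 1L || is.na(m) || m < 1)
    stopf("bonferroni_alpha: m must be a positive count")
  family_alpha / m
}

#' Screen subject variables against every feature and condition
#'
#' Pearson-correlates each subject-specific variable (age, gender-role
#' and personality scores; gender itself is excluded and enters only at
#' the subgrouping stage) with every feature in every condition, across
#' subjects. Two-sided p-values come from the t transform of r with
#' n - 2 degrees of freedom; the significance flag applies the
#' Bonferroni-corrected level \code{family_alpha / length(variables)}.
#'
#' @param matrix A \code{feature_matrix}.
#' @param profiles Subject profiles (one row per subject in
#'   \code{matrix}).
#' @param variables Profile columns to screen; defaults to age, the two
#'   BSRI gender-role scores, the two NEO-FFI scores, BIS and BAS.
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return A \code{screening_table} data frame with columns
#'   \code{feature}, \code{condition}, \code{variable}, \code{r},
#'   \code{p}, \code{significant}, plus attributes \code{alpha} (the
#'   corrected level) and \code{n} (subjects).
#' @export
screen_variables <- function(matrix, profiles,
                             variables = c("age", "masculinity",
                                           "femininity", "extraversion",
                                           "neuroticism", "bis", "bas"),
                             family_alpha = 0.05) {
  allowed <- c("age", "masculinity", "femininity", "extraversion",
               "neuroticism", "bis", "bas")
  bad <- setdiff(variables, allowed)
  if (length(bad))
    stopf("screen_variables: unsupported variable(s): %s (gender enters at the subgrouping stage, not here)",
          paste(bad, collapse = ", "))
  miss <- setdiff(unique(matrix$subject_id), profiles$subject_id)
  if (length(miss))
    stopf("screen_variables: no profile for subject(s) %s",
          paste(miss, collapse = ", "))
  profiles <- profiles[profiles$subject_id %in% matrix$subject_id, ,
                       drop = FALSE]
  n <- length(unique(matrix$subject_id))
  if (n < 4L)
    stopf("screen_variables: need at least 4 subjects, got %d", n)
  alpha <- bonferroni_alpha(family_alpha, length(variables))
  feats <- intersect(feature_names(), names(matrix))
  conds <- intersect(affect_conditions(), unique(matrix$condition))
  rows <- vector("list", length(feats) * length(conds) * length(variables))
  k <- 0L
  for (cond in conds) {
    sub <- matrix[matrix$condition == cond, , drop = FALSE]
    sub <- sub[match(profiles$subject_id, sub$subject_id), , drop = FALSE]
    for (f in feats) {
      fv <- sub[[f]]
      for (v in variables) {
        ct <- suppressWarnings(
          stats::cor.test(profiles[[v]], fv, method = "pearson"))
        k <- k + 1L
        rows[[k]] <- data.frame(
          feature = f, condition = cond, variable = v,
          r = unname(ct$estimate), p = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha
  attr(out, "alpha") <- alpha
  attr(out, "n") <- n
  class(out) <- c("screening_table", "data.frame")
  out
}

#' @export
print.screening_table <- function(x, ...) {
  sig <- x[x$significant, , drop = FALSE]
  cat(sprintf("Screening: %d tests over %d subjects, alpha = %.4g; %d significant\n",
              nrow(x), attr(x, "n") %||% NA, attr(x, "alpha") %||% NA,
              nrow(sig)))
  if (nrow(sig)) {
    sig <- sig[order(sig$p), , drop = FALSE]
    for (i in seq_len(min(15L, nrow(sig))))
      cat(sprintf("  %s_%s ~ %s: r = %.3f, p = %.4g\n", sig$feature[i],
                  sig$condition[i], sig$variable[i], sig$r[i], sig$p[i]))
    if (nrow(sig) > 15L) cat("  ...\n")
  }
  invisible(x)
}
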