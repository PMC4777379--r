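#' Remove redundant features by pairwise correlation
#'
#' Repeatedly computes all pairwise Pearson correlations over the rows of
#' the feature matrix and, while any pair reaches \code{|r| >=
#' threshold}, removes the higher-indexed (in canonical feature order)
#' member of the most-correlated pair, then recomputes. The procedure is
#' deterministic: ties on |r| are broken by canonical order.
#'
#' Constant columns have no defined correlation; they are flagged with a
#' warning and always retained.
#'
#' @param matrix A \code{feature_matrix} (>= 3 rows, no missing values).
#' @param threshold Absolute-correlation removal threshold (default
#'   0.95, applying to correlations of 0.95 and -0.95 alike).
#' @return A \code{reduction_report}: list with \code{threshold},
#'   \code{removed} (data frame \code{feature}, \code{partner},
#'   \code{r}, in removal order) and \code{retained}.
#' @export
reduce_by_correlation <- function(matrix, threshold = 0.95) {
  feats <- intersect(feature_names(), names(matrix))
  x <- as.matrix(matrix[, feats, drop = FALSE])
  if (nrow(x) < 3L)
    stopf("reduce_by_correlation: need at least 3 rows, got %d", nrow(x))
  if (anyNA(x))
    stopf("reduce_by_correlation: missing values are not allowed")
  if (threshold <= 0 || threshold > 1)
    stopf("reduce_by_correlation: threshold must lie in (0, 1]")
  const <- feats[apply(x, 2, stats::sd) == 0]
  if (length(const))
    warning("constant feature column(s) retained (undefined correlation): ",
            paste(const, collapse = ", "), call. = FALSE)
  active <- setdiff(feats, const)
  removed <- data.frame(feature = character(0), partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  while (length(active) >= 2L) {
    cm <- stats::cor(x[, active, drop = FALSE])
    diag(cm) <- 0
    am <- abs(cm)
    top <- max(am)
    if (top < threshold) break
    hit <- which(am == top, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # canonical tie-break: earliest pair in feature order
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    keep_f <- active[hit[1, 1]]
    drop_f <- active[hit[1, 2]]
    removed <- rbind(removed, data.frame(
      feature = drop_f, partner = keep_f,
      r = cm[hit[1, 1], hit[1, 2]], stringsAsFactors = FALSE))
    active <- setdiff(active, drop_f)
  }
  structure(list(threshold = threshold, removed = removed,
                 retained = intersect(feats, c(active, const))),
            class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("Correlation reduction at |r| >= %g: %d removed, %d retained\n",
              x$threshold, nrow(x$removed), length(x$retained)))
  if (nrow(x$removed))
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("  - %s (r = %.3f with %s)\n", x$removed$feature[i],
                  x$removed$r[i], x$removed$partner[i]))
  invisible(x)
}

#' Apply a reduction report to a feature matrix
#'
#' @param matrix A \code{feature_matrix}.
#' @param report A \code{reduction_report}.
#' @return The matrix restricted to the retained features, provenance
#'   flagged \code{"reduced"}.
#' @export
apply_reduction <- function(matrix, report) {
  keep <- c(setdiff(names(matrix), feature_names()), report$retained)
  as_feature_matrix(matrix[, intersect(names(matrix), keep), drop = FALSE],
                    provenance = "reduced")
}
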