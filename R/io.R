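# Plain-text external formats: per-channel signal files + JSON sidecar,
# BIDS-events-style timelines, CSV profiles / features / screening
# tables, JSON reduction reports.

#' Write and read a raw recording
#'
#' One delimited-text file per channel (columns \code{time_s},
#' \code{value}) plus a JSON sidecar with subject id, per-channel units
#' and sampling rates.
#'
#' @param recording A \code{raw_recording}.
#' @param dir Output directory (created if needed).
#' @return \code{write_recording}: the sidecar path, invisibly;
#'   \code{read_recording}: a \code{raw_recording}.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sid <- recording$subject_id
  meta <- list(subject_id = sid, channels = list())
  for (nm in names(recording$channels)) {
    ch <- recording$channels[[nm]]
    path <- file.path(dir, sprintf("%s_%s.tsv", sid, nm))
    t_s <- (seq_along(ch$samples) - 1) / ch$fs
    utils::write.table(
      data.frame(time_s = sprintf("%.6f", t_s),
                 value = sprintf("%.8g", ch$samples)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta$channels[[nm]] <- list(fs = ch$fs, units = ch$units,
                                file = basename(path))
  }
  side <- file.path(dir, sprintf("%s.json", sid))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname write_recording
#' @param subject_id Subject whose sidecar to read.
#' @export
read_recording <- function(dir, subject_id) {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s.json", subject_id)))
  chans <- lapply(meta$channels, function(m) {
    df <- utils::read.delim(file.path(dir, m$file))
    list(samples = df$value, fs = m$fs, units = m$units)
  })
  structure(list(subject_id = meta$subject_id, channels = chans),
            class = "raw_recording")
}

#' Write and read an event timeline
#'
#' Tab-separated events file with columns \code{onset}, \code{duration},
#' \code{trial_type}.
#'
#' @param timeline An \code{event_timeline}.
#' @param path Output file.
#' @export
write_timeline <- function(timeline, path) {
  utils::write.table(
    data.frame(onset = timeline$onset, duration = timeline$duration,
               trial_type = timeline$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @param pictures_per_block,picture_duration Picture grid of the
#'   stimulation blocks (not representable in the events file itself).
#' @export
read_timeline <- function(path, pictures_per_block = 10L,
                          picture_duration = 2) {
  df <- utils::read.delim(path)
  tl <- data.frame(onset = df$onset, duration = df$duration,
                   label = df$trial_type, stringsAsFactors = FALSE)
  attr(tl, "pictures_per_block") <- pictures_per_block
  attr(tl, "picture_duration") <- picture_duration
  class(tl) <- c("event_timeline", "data.frame")
  validate_timeline(tl)
  tl
}

#' Write and read subject profiles
#' @param profiles Profile data frame.
#' @param path CSV file.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read a feature matrix
#' @param matrix A \code{feature_matrix}.
#' @param path CSV file.
#' @export
write_feature_matrix <- function(matrix, path) {
  utils::write.csv(as.data.frame(matrix), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param provenance Provenance flag of the stored matrix
#'   (\code{"raw"} or \code{"reduced"}).
#' @export
read_feature_matrix <- function(path, provenance = "raw") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyNA(df)) stopf("feature matrix %s contains missing values", path)
  as_feature_matrix(df, provenance = provenance)
}

#' Write a screening table (CSV)
#' @param table A \code{screening_table}.
#' @param path CSV file.
#' @param significant_only Keep only Bonferroni-significant rows,
#'   mirroring a published significant-correlations table.
#' @export
write_screening <- function(table, path, significant_only = FALSE) {
  df <- as.data.frame(table)
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a reduction report (JSON)
#' @param report A \code{reduction_report}.
#' @param path JSON file.
#' @export
write_reduction <- function(report, path) {
  jsonlite::write_json(list(threshold = report$threshold,
                            removed = report$removed,
                            retained = report$retained),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an NN-interval series (two-column delimited text)
#' @param nn An \code{nn_series}.
#' @param path Output file.
#' @export
write_nn_series <- function(nn, path) {
  utils::write.table(
    data.frame(beat_time_s = nn$beat_times[-1L], nn_ms = nn$intervals),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
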