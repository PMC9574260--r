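#' Read a long-format gaze table
#'
#' Reads delimited gaze logs as exported by webcam eye-trackers: one row per
#' sample with columns `participant_id`, `trial_index`, `t_ms`, `x_px`,
#' `y_px`, `screen_w`, `screen_h`.  Blank or NA coordinates mark invalid
#' samples (tracking loss); their rows are kept with `valid = FALSE`.
#' Samples are sorted by time within trial; a duplicated timestamp within a
#' trial is a recording fault and raises an error naming the trial.
#'
#' @param path File to read.
#' @param sep Field delimiter (default comma).
#' @return A data.frame of samples with a logical `valid` column, sorted by
#'   participant, trial and time.
#' @seealso [write_gaze_table()], [split_trials()]
#' @export
read_gaze_table <- function(path, sep = ",") {
  gz <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("participant_id", "trial_index", "t_ms", "x_px", "y_px")
  missing_cols <- setdiff(need, names(gz))
  if (length(missing_cols))
    stop("gaze table lacks column(s): ", paste(missing_cols, collapse = ", "))
  gz$valid <- !(is.na(gz$x_px) | is.na(gz$y_px))
  gz <- gz[order(gz$participant_id, gz$trial_index, gz$t_ms), , drop = FALSE]
  key <- paste(gz$participant_id, gz$trial_index)
  dup <- duplicated(cbind(key, gz$t_ms))
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicated timestamp %s ms in participant %s, trial %s (row %d)",
                 format(gz$t_ms[i]), gz$participant_id[i], gz$trial_index[i], i))
  }
  rownames(gz) <- NULL
  gz
}

#' Write a gaze table
#'
#' @param gaze A data.frame as returned by [read_gaze_table()] or
#'   [generate_cohort()]; the `valid` column, if present, is dropped and
#'   encoded as blank coordinates.
#' @param path Destination file.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(gaze, path, sep = ",") {
  out <- gaze
  if ("valid" %in% names(out)) {
    out$x_px[!out$valid] <- NA
    out$y_px[!out$valid] <- NA
    out$valid <- NULL
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a gaze table into per-trial sample frames
#'
#' @param gaze A gaze data.frame.
#' @return A named list of per-trial data.frames, keyed
#'   `"<participant>.<trial>"`.
#' @export
split_trials <- function(gaze) {
  split(gaze, list(gaze$participant_id, gaze$trial_index), drop = TRUE)
}

#' Write / read a bin table
#'
#' The tidy bin table (one row per subject x trial x 100 ms bin, columns
#' `subject`, `group`, `condition`, `item`, `t_start_rel`, `F`, `N`, `p`) is
#' the single interchange format between preprocessing and all downstream
#' models.
#'
#' @param bins A bin-table data.frame.
#' @param path Destination / source file.
#' @return `write_bins()` returns `path` invisibly; `read_bins()` the
#'   data.frame.
#' @export
write_bins <- function(bins, path) {
  utils::write.csv(bins, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a design table
#'
#' @param design A design data.frame from [build_design()].
#' @param path Destination / source file.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
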