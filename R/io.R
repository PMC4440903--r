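trial_columns <- c("participant_id", "group", "item_id", "rating_1",
                   "drawn_deviation", "presented_deviation", "rating_2")

#' Read and write trial tables
#'
#' The on-disk format is a plain CSV with header `participant_id, group,
#' item_id, rating_1, drawn_deviation, presented_deviation, rating_2`, one
#' row per participant x item. `read_trials()` validates the table: all
#' columns present, deviations in -2..2, group labels in
#' \{control, experimental\}, no duplicated (participant, item) pair, and —
#' for Likert tables — ratings within the 1-6 scale. Tables written in
#' continuous mode carry unbounded real ratings; read those with
#' `discrete = FALSE` to skip the bounds check.
#'
#' @param path File path.
#' @param discrete Logical; validate ratings against the scale bounds
#'   (default `TRUE`).
#' @return `read_trials()`: the validated trial table. `write_trials()`:
#'   `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' trials <- generate_experiment(generator_config(n_per_group = 2,
#'                                                n_items = 12, seed = 9))
#' write_trials(trials, f)
#' identical(read_trials(f)$rating_2, trials$rating_2)
#' @export
read_trials <- function(path, discrete = TRUE) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(what, bad) {
    stop("trial file ", path, ": ", what, " in row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  if (discrete) {
    scale <- rating_scale()
    bad <- trials$rating_1 < scale$minimum | trials$rating_1 > scale$maximum |
      trials$rating_2 < scale$minimum | trials$rating_2 > scale$maximum
    if (any(bad)) bad_row("rating outside the 1-6 scale", bad)
  }
  bad <- !trials$drawn_deviation %in% (-2:2) |
    !trials$presented_deviation %in% (-2:2)
  if (any(bad)) bad_row("deviation outside -2..2", bad)
  bad <- !trials$group %in% c("control", "experimental")
  if (any(bad)) bad_row("unknown group label", bad)
  key <- paste(trials$participant_id, trials$item_id, sep = "\r")
  bad <- duplicated(key)
  if (any(bad)) bad_row("duplicated (participant, item) pair", bad)
  trials
}

#' @rdname read_trials
#' @param trials Trial table (see [generate_experiment()]).
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(trials[trial_columns], path, row.names = FALSE)
  invisible(path)
}
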