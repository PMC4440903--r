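#' Mean-center ratings within participant
#'
#' Subtracts from each rating the mean of that participant's ratings in the
#' same session, removing session-level displacement (a participant rating
#' everything half a point higher the second time). Centering is what makes
#' the per-participant mean rating change exactly zero, which in turn
#' justifies fixing the intercept of the RTM model at zero.
#'
#' @param ratings Numeric vector of raw ratings from one session.
#' @param participant Vector of participant identifiers, same length as
#'   `ratings`.
#' @return Numeric vector of centered ratings; within each participant the
#'   mean of the result is 0.
#' @examples
#' mean_center(c(1, 2, 3, 4, 5, 6), rep("a", 6))
#' @export
mean_center <- function(ratings, participant) {
  if (length(ratings) != length(participant)) {
    stop("`ratings` and `participant` must have equal length", call. = FALSE)
  }
  if (length(ratings) == 0L || anyNA(ratings)) {
    stop("missing or empty ratings: every participant needs at least one ",
         "rating per session", call. = FALSE)
  }
  ratings - stats::ave(ratings, participant)
}

#' Collapse presented deviations to the three-level Deviation factor
#'
#' Negative presented deviations (-2, -1) become `peers_lower`, zero becomes
#' `peers_equal`, and positive deviations (+1, +2) become `peers_higher` —
#' the three-level within-participant factor used in the group-level ANOVAs.
#'
#' @param presented_deviation Integer vector in -2..2.
#' @return Factor with levels `peers_lower`, `peers_equal`, `peers_higher`.
#' @examples
#' bin_deviation(c(-2, -1, 0, 1, 2))
#' @export
bin_deviation <- function(presented_deviation) {
  if (any(!presented_deviation %in% (-2L:2L))) {
    stop("`presented_deviation` must be in -2..2", call. = FALSE)
  }
  factor(ifelse(presented_deviation < 0, "peers_lower",
                ifelse(presented_deviation == 0, "peers_equal", "peers_higher")),
         levels = c("peers_lower", "peers_equal", "peers_higher"))
}

#' Compute centered rating changes from matched sessions
#'
#' Aligns two centered sessions by (participant, item) key and returns the
#' per-item rating change `c = centered_2 - centered_1`. Because both inputs
#' are centered within participant, the per-participant mean of `c` is zero.
#'
#' @param centered_1,centered_2 Data.frames with columns `participant_id`,
#'   `item_id` and `value` (the centered rating for that session).
#' @return Data.frame `participant_id`, `item_id`, `r` (centered session-1
#'   rating), `c` (rating change), in the row order of `centered_1`.
#' @export
compute_rating_changes <- function(centered_1, centered_2) {
  key1 <- paste(centered_1$participant_id, centered_1$item_id, sep = "\r")
  key2 <- paste(centered_2$participant_id, centered_2$item_id, sep = "\r")
  if (anyDuplicated(key1) || anyDuplicated(key2) ||
      !setequal(key1, key2)) {
    stop("sessions are not aligned: (participant, item) keys must match ",
         "one-to-one", call. = FALSE)
  }
  idx <- match(key1, key2)
  data.frame(participant_id = centered_1$participant_id,
             item_id = centered_1$item_id,
             r = centered_1$value,
             c = centered_2$value[idx] - centered_1$value,
             stringsAsFactors = FALSE)
}

#' Preprocess a trial table into centered items
#'
#' Applies the full preprocessing chain to a trial table: mean-center each
#' session within participant, compute per-item rating changes, and bin the
#' presented deviation into the three-level Deviation factor. The binning
#' uses the presented (post-reflection) deviation for both groups; in the
#' control group this is the determined-but-suppressed value.
#'
#' @param trials Trial table as produced by [generate_experiment()] or
#'   [read_trials()].
#' @return Data.frame of centered items: `participant_id`, `group`,
#'   `item_id`, `presented_deviation`, `r` (mean-centered initial rating),
#'   `c` (rating change), `condition` (Deviation factor).
#' @examples
#' trials <- generate_experiment(generator_config(n_per_group = 2,
#'                                                n_items = 12, seed = 1))
#' items <- preprocess_trials(trials)
#' tapply(items$c, items$participant_id, mean)  # all ~0
#' @export
preprocess_trials <- function(trials) {
  needed <- c("participant_id", "group", "item_id", "rating_1",
              "presented_deviation", "rating_2")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(trials$participant_id, trials$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (participant, item) pairs in trial table", call. = FALSE)
  }
  out <- data.frame(
    participant_id = trials$participant_id,
    group = trials$group,
    item_id = trials$item_id,
    presented_deviation = as.integer(trials$presented_deviation),
    r = mean_center(trials$rating_1, trials$participant_id),
    c = mean_center(trials$rating_2, trials$participant_id) -
      mean_center(trials$rating_1, trials$participant_id),
    stringsAsFactors = FALSE)
  out$condition <- bin_deviation(out$presented_deviation)
  out
}
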