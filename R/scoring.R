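#' Fisher-z transform of a correlation
#'
#' `z = arctanh(r)`, with correlations at the boundary clamped to
#' `+/-(1 - 1e-12)` (with a warning) so the transform stays finite (~14.2)
#' without distorting realistic scores.
#'
#' @param r Correlation(s) in \[-1, 1\].
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  r <- pmin(pmax(r, -1), 1)
  if (any(abs(r) > 1 - 1e-12, na.rm = TRUE)) {
    warning("correlation of magnitude 1 clamped before Fisher-z transform")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  atanh(r)
}

#' Conformity score for one participant
#'
#' Pearson correlation, across one participant's items, between the
#' presented deviation (five raw levels -2..+2, not the binned factor) and a
#' rating change, plus its Fisher-z transform. With `change = c` this is the
#' uncorrected score; with the RTM-corrected change `s_hat` it is the
#' corrected score.
#'
#' @param presented_deviation Integer vector of presented deviations.
#' @param change Numeric vector of rating changes (same length).
#' @return List with `r`, `z` and `n`. When either variable has zero
#'   variance the score is undefined: `r` and `z` are `NA` and a warning is
#'   issued (such participants are excluded from aggregates).
#' @examples
#' conformity_score(c(-2, 0, 2, 0, -1, 1), c(-1, 0, 1, 0, 0, 1))
#' @export
conformity_score <- function(presented_deviation, change) {
  n <- length(change)
  if (n != length(presented_deviation) || n < 3L) {
    stop("need >= 3 matched items per participant", call. = FALSE)
  }
  if (stats::var(presented_deviation) == 0 || stats::var(change) == 0) {
    warning("zero variance in deviation or change: conformity score undefined")
    return(list(r = NA_real_, z = NA_real_, n = n))
  }
  r <- stats::cor(presented_deviation, change)
  list(r = r, z = fisher_z(r), n = n)
}

#' Per-participant conformity score table
#'
#' Computes, for every participant in `items`, the uncorrected conformity
#' score (presented deviation vs. observed change `c`) and, when the column
#' `s_hat` is present, the RTM-corrected score (presented deviation vs.
#' `s_hat`), both as Pearson r and Fisher-z.
#'
#' @param items Centered (and optionally corrected) items for one group.
#' @return Data.frame with one row per participant: `participant_id`,
#'   `r_raw`, `z_raw` and, if corrected changes are available, `r_corrected`,
#'   `z_corrected`.
#' @examples
#' cfg <- generator_config(n_per_group = 3, n_items = 30, seed = 2)
#' items <- preprocess_trials(generate_experiment(cfg))
#' ctrl <- items[items$group == "control", ]
#' fit <- fit_control_hlm(ctrl)
#' exp_items <- correct_rating_changes(items[items$group == "experimental", ], fit)
#' conformity_scores(exp_items)
#' @export
conformity_scores <- function(items) {
  stopifnot(all(c("participant_id", "presented_deviation", "c") %in% names(items)))
  has_corr <- "s_hat" %in% names(items)
  by_k <- split(items, items$participant_id, drop = TRUE)
  rows <- lapply(names(by_k), function(k) {
    d <- by_k[[k]]
    raw <- conformity_score(d$presented_deviation, d$c)
    row <- data.frame(participant_id = k, r_raw = raw$r, z_raw = raw$z,
                      stringsAsFactors = FALSE)
    if (has_corr) {
      corr <- conformity_score(d$presented_deviation, d$s_hat)
      row$r_corrected <- corr$r
      row$z_corrected <- corr$z
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
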