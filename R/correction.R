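#' Remove the RTM component from rating changes
#'
#' Subtracts the expected regression-toward-the-mean change from every
#' observed rating change: `s_hat = c - gamma10 * r`, where `gamma10` is the
#' average slope estimated from the control group. The remainder `s_hat` is
#' the per-item change attributable to social influence. The correction uses
#' the single fixed slope for every participant, never participant-specific
#' slope predictions: the control group identifies the average RTM rate, and
#' applying it uniformly is what makes the correction transferable to the
#' experimental group.
#'
#' Applied to the control group itself this is a falsification check: the
#' corrected control-group changes should carry no Deviation effect beyond
#' chance.
#'
#' @param items Centered items (data.frame with columns `r` and `c`), any
#'   group.
#' @param gamma10 The control-group fixed slope: an [fit_control_hlm()]
#'   result or a single finite number.
#' @return `items` with an added column `s_hat`; row count and order
#'   unchanged.
#' @examples
#' items <- data.frame(r = c(-1, 0, 1.2), c = c(0.3, 0, -0.5))
#' correct_rating_changes(items, -0.374)$s_hat
#' @export
correct_rating_changes <- function(items, gamma10) {
  slope <- slope_of(gamma10)
  stopifnot(all(c("r", "c") %in% names(items)))
  items$s_hat <- items$c - slope * items$r
  items
}
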