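#' Configuration for the two-session rating-experiment generator
#'
#' Builds the parameter set for [generate_experiment()]. The generative model
#' is: each item i of participant k has a stable latent value
#' `v_ik ~ Normal(latent_mean, latent_sd^2)`; the session-1 rating is
#' `v_ik + e1` and the session-2 rating is
#' `v_ik + e2 + w_k * presented_deviation` in the experimental group (the
#' conformity term is absent in the control group), with occasion noise
#' `e1, e2 ~ Normal(0, noise_sd^2)` and a participant-specific conformity
#' weight `w_k ~ Normal(conformity_weight_mean, conformity_weight_sd^2)`.
#' Occasion noise around a stable latent value is exactly what produces
#' regression toward the mean: in continuous mode the population slope of
#' rating change on the centered initial rating is
#' `-noise_sd^2 / (latent_sd^2 + noise_sd^2)`.
#'
#' The default `noise_sd` is derived from `rtm_fraction` so that this implied
#' slope is -0.374, the calibration the package uses for control-group
#' simulations; `conformity_weight_mean = 0.15` rating units per deviation
#' unit with between-participant SD 0.05 gives a clearly detectable but
#' realistic conformity effect. These are generator defaults, not estimates
#' from any dataset.
#'
#' @param n_per_group Participants per group (default 27).
#' @param n_items Items rated in both sessions (default 180).
#' @param latent_mean Location of latent item values (default 3.5, the scale
#'   midpoint).
#' @param latent_sd Between-item SD of latent values, rating units (default 1).
#' @param noise_sd Occasion-specific rating noise SD. Default derived from
#'   `rtm_fraction`.
#' @param rtm_fraction Target value of `noise_sd^2 / (latent_sd^2 +
#'   noise_sd^2)`, the magnitude of the implied continuous-mode RTM slope.
#'   Only used when `noise_sd` is `NULL`. Default 0.374.
#' @param conformity_weight_mean Mean rating shift per unit presented
#'   deviation in the experimental group.
#' @param conformity_weight_sd Between-participant SD of that weight.
#' @param discretize Logical; round ratings half-away-from-zero and clamp to
#'   the 1-6 scale (`TRUE`, Likert mode) or keep them continuous (`FALSE`,
#'   used for closed-form checks).
#' @param shared_items Logical; draw one latent value per item shared by all
#'   participants instead of independent per-participant draws (sensitivity
#'   analysis only; the default keeps item-level residuals independent within
#'   participants).
#' @param seed Master seed; every random draw in [generate_experiment()]
#'   flows from it through per-participant substreams.
#' @return A list of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_per_group = 5, n_items = 20)
#' cfg$noise_sd^2 / (cfg$latent_sd^2 + cfg$noise_sd^2)  # 0.374
#' @export
generator_config <- function(n_per_group = 27L,
                             n_items = 180L,
                             latent_mean = 3.5,
                             latent_sd = 1,
                             noise_sd = NULL,
                             rtm_fraction = 0.374,
                             conformity_weight_mean = 0.15,
                             conformity_weight_sd = 0.05,
                             discretize = TRUE,
                             shared_items = FALSE,
                             seed = 1L) {
  if (is.null(noise_sd)) {
    stopifnot(rtm_fraction > 0, rtm_fraction < 1)
    noise_sd <- latent_sd * sqrt(rtm_fraction / (1 - rtm_fraction))
  }
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_items = as.integer(n_items),
              latent_mean = latent_mean,
              latent_sd = latent_sd,
              noise_sd = noise_sd,
              conformity_weight_mean = conformity_weight_mean,
              conformity_weight_sd = conformity_weight_sd,
              discretize = isTRUE(discretize),
              shared_items = isTRUE(shared_items),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  ok <- cfg$n_per_group >= 2L && cfg$n_items >= 2L &&
    cfg$latent_sd > 0 && cfg$noise_sd >= 0 && cfg$conformity_weight_sd >= 0
  if (!ok) {
    stop("invalid generator configuration: need n_per_group >= 2, ",
         "n_items >= 2, latent_sd > 0, noise_sd >= 0, ",
         "conformity_weight_sd >= 0", call. = FALSE)
  }
  if (cfg$n_items %% length(deviation_counts()) == 0L &&
      cfg$n_items != sum(deviation_counts()) && cfg$n_items != 0) {
    # non-180 n_items uses a scaled schedule; nothing to check here
  }
  invisible(cfg)
}

# Deterministic per-participant sub-seed: prefix-stable in n_per_group so
# enlarging a group never reshuffles existing participants. Kept below 2^31.
substream_seed <- function(master, group, index) {
  offset <- switch(group, control = 1, experimental = 2, items = 3,
                   stop("unknown substream group"))
  as.integer((as.double(master) * 69069 + offset * 30011 + index * 7919) %%
               2147483629)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

discretize_rating <- function(x) {
  scale <- rating_scale()
  pmin(pmax(round_half_away(x), scale$minimum), scale$maximum)
}

# Deviation schedule for n_items: the design's 1:1:2:1:1 mix of
# (-2, -1, 0, +1, +2), scaled to n_items (rounded allocation for non-multiples
# of 6), in random order drawn from the current RNG stream.
scaled_schedule <- function(n_items) {
  counts <- deviation_counts()
  scaled <- floor(counts * n_items / sum(counts))
  short <- n_items - sum(scaled)
  if (short > 0) { # pad deterministically, zeros first
    order_pad <- c("0", "-1", "1", "-2", "2")
    for (lv in rep_len(order_pad, short)) scaled[lv] <- scaled[lv] + 1L
  }
  sample(rep(as.integer(names(scaled)), scaled))
}

#' Simulate a complete two-session conformity experiment
#'
#' Generates the full trial table for a control and an experimental group
#' under the generative model documented in [generator_config()]. For every
#' participant a randomized deviation schedule is drawn and the
#' boundary-reflection rule applied against the session-1 rating (the
#' discretized rating in Likert mode; in continuous mode the rating projected
#' onto the scale, since presented feedback is a bounded design variable).
#' Control-group deviations are drawn and reflected identically but never
#' enter the session-2 model — they are the "determined but suppressed"
#' feedback used for falsification analyses.
#'
#' @param config A [generator_config()] object.
#' @return A data.frame with one row per participant x item and columns
#'   `participant_id`, `group`, `item_id`, `rating_1`, `drawn_deviation`,
#'   `presented_deviation`, `rating_2`.
#' @examples
#' trials <- generate_experiment(generator_config(n_per_group = 3,
#'                                                n_items = 18, seed = 7))
#' table(trials$group) / 18
#' @export
generate_experiment <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)

  shared_v <- NULL
  if (config$shared_items) {
    shared_v <- with_local_seed(
      substream_seed(config$seed, "items", 0L),
      stats::rnorm(config$n_items, config$latent_mean, config$latent_sd))
  }

  one_participant <- function(group, idx) {
    with_local_seed(substream_seed(config$seed, group, idx), {
      n <- config$n_items
      v <- if (is.null(shared_v)) {
        stats::rnorm(n, config$latent_mean, config$latent_sd)
      } else shared_v
      e1 <- stats::rnorm(n, 0, config$noise_sd)
      e2 <- stats::rnorm(n, 0, config$noise_sd)
      w <- stats::rnorm(1, config$conformity_weight_mean,
                        config$conformity_weight_sd)
      drawn <- if (n == sum(deviation_counts())) {
        sample(rep(as.integer(names(deviation_counts())), deviation_counts()))
      } else scaled_schedule(n)

      y1 <- v + e1
      rating_1 <- if (config$discretize) discretize_rating(y1) else y1
      feedback <- apply_reflection(discretize_rating(rating_1), drawn)
      influence <- if (group == "experimental") {
        w * feedback$presented_deviation
      } else 0
      y2 <- v + e2 + influence
      rating_2 <- if (config$discretize) discretize_rating(y2) else y2

      data.frame(
        participant_id = sprintf("%s_%02d",
                                 if (group == "control") "ctrl" else "exp",
                                 idx),
        group = group,
        item_id = seq_len(n),
        rating_1 = rating_1,
        drawn_deviation = drawn,
        presented_deviation = feedback$presented_deviation,
        rating_2 = rating_2,
        stringsAsFactors = FALSE)
    })
  }

  out <- do.call(rbind, c(
    lapply(seq_len(config$n_per_group), function(i) one_participant("control", i)),
    lapply(seq_len(config$n_per_group), function(i) one_participant("experimental", i))))
  rownames(out) <- NULL
  out
}
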