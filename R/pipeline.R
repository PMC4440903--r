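#' Run the full conformity analysis pipeline
#'
#' Executes the complete analysis chain on a simulated (or supplied) trial
#' table, in the order the paradigm's analyses are usually reported:
#' baseline group comparison of raw initial ratings; mixed ANOVA of rating
#' changes (Deviation x Group); separate per-group Deviation ANOVAs; the
#' control-group RTM model fit; RTM correction of both groups; per-group
#' ANOVAs of the corrected changes (experimental: the isolated conformity
#' effect; control: the falsification check) with Holm pairwise comparisons;
#' and per-participant conformity scores with score-level t-tests.
#'
#' @param config A [generator_config()]; used to simulate trials when
#'   `trials` is `NULL`, and ignored otherwise.
#' @param trials Optional trial table (e.g. from [read_trials()]). Must
#'   contain both groups; the correction requires a control fit.
#' @param seed Optional master seed overriding `config$seed`.
#' @param out_dir Optional directory; when given, writes `trials.csv`,
#'   `items.csv` (with `r`, `c`, `condition`, `s_hat`),
#'   `scores_experimental.csv`, `scores_control.csv` and `summary.json`.
#' @param sphericity_alpha Alpha gating the Huynh-Feldt correction.
#' @return Object of class `conformity_pipeline`: a list with `trials`,
#'   `items` (corrected), `baseline`, `anova_mixed`, `anova_group` (per-group,
#'   uncorrected), `control_fit`, `anova_corrected` (per-group), `pairwise`
#'   (Holm table, corrected experimental changes), `scores` (per-group score
#'   tables), `score_tests`, and `seed`.
#' @examples
#' res <- run_pipeline(generator_config(n_per_group = 6, n_items = 36,
#'                                      seed = 11))
#' res$control_fit$gamma10
#' @export
run_pipeline <- function(config = generator_config(), trials = NULL,
                         seed = NULL, out_dir = NULL,
                         sphericity_alpha = 0.05) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(trials)) {
    trials <- stage("simulate", generate_experiment(config))
  }
  groups <- unique(trials$group)
  if (!"control" %in% groups) {
    stop("pipeline requires a control group: the RTM correction is fitted ",
         "on control-group data", call. = FALSE)
  }
  if (!"experimental" %in% groups) {
    stop("pipeline requires an experimental group", call. = FALSE)
  }

  baseline <- stage("baseline", {
    m1 <- tapply(trials$rating_1, trials$participant_id, mean)
    grp <- trials$group[match(names(m1), trials$participant_id)]
    two_sample_t(m1[grp == "experimental"], m1[grp == "control"])
  })

  items <- stage("preprocess", preprocess_trials(trials))

  anova_mixed <- stage("anova_mixed",
                       rm_anova_mixed(condition_means(items),
                                      sphericity_alpha = sphericity_alpha))
  anova_group <- stage("anova_group", lapply(
    stats::setNames(nm = c("experimental", "control")),
    function(g) rm_anova_mixed(
      condition_means(items[items$group == g, ]),
      sphericity_alpha = sphericity_alpha)))

  control_fit <- stage("fit_control",
                       fit_control_hlm(items[items$group == "control", ]))

  items <- stage("correct", correct_rating_changes(items, control_fit))

  anova_corrected <- stage("anova_corrected", lapply(
    stats::setNames(nm = c("experimental", "control")),
    function(g) rm_anova_mixed(
      condition_means(items[items$group == g, ], value = "s_hat"),
      sphericity_alpha = sphericity_alpha)))

  pairwise <- stage("pairwise", holm_pairwise(
    condition_means(items[items$group == "experimental", ], value = "s_hat")))

  scores <- stage("score", lapply(
    stats::setNames(nm = c("experimental", "control")),
    function(g) conformity_scores(items[items$group == g, ])))

  score_tests <- stage("score_tests", {
    ex <- scores$experimental
    ct <- scores$control
    list(
      raw_vs_zero = one_sample_t(ex$z_raw),
      corrected_vs_zero = one_sample_t(ex$z_corrected),
      raw_vs_corrected = paired_t(ex$z_raw, ex$z_corrected),
      raw_corrected_correlation =
        pearson_between_participants(ex$z_raw, ex$z_corrected),
      control_corrected_vs_zero = one_sample_t(ct$z_corrected))
  })

  res <- structure(list(trials = trials,
                        items = items,
                        baseline = baseline,
                        anova_mixed = anova_mixed,
                        anova_group = anova_group,
                        control_fit = control_fit,
                        anova_corrected = anova_corrected,
                        pairwise = pairwise,
                        scores = scores,
                        score_tests = score_tests,
                        seed = config$seed,
                        config = config),
                   class = "conformity_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(res$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(res$items, file.path(out_dir, "items.csv"),
                   row.names = FALSE)
  utils::write.csv(res$scores$experimental,
                   file.path(out_dir, "scores_experimental.csv"),
                   row.names = FALSE)
  utils::write.csv(res$scores$control,
                   file.path(out_dir, "scores_control.csv"),
                   row.names = FALSE)
  jsonlite::write_json(pipeline_summary(res),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

anova_summary <- function(a) {
  list(effects = a$effects,
       mauchly = a$mauchly,
       epsilon = a$epsilon,
       correction_applied = a$correction_applied)
}

#' Summarize a pipeline result as plain lists
#'
#' Flattens a [run_pipeline()] result into nested lists of numbers suitable
#' for JSON serialization (this is what `summary.json` contains).
#'
#' @param res A `conformity_pipeline` object.
#' @return Nested list of plain vectors and data.frames.
#' @export
pipeline_summary <- function(res) {
  fit <- res$control_fit
  list(
    seed = res$seed,
    n_per_group = length(unique(
      res$trials$participant_id[res$trials$group == "control"])),
    n_items = length(unique(res$trials$item_id)),
    baseline = res$baseline,
    anova_mixed = anova_summary(res$anova_mixed),
    anova_experimental = anova_summary(res$anova_group$experimental),
    anova_control = anova_summary(res$anova_group$control),
    control_fit = list(gamma10 = fit$gamma10, se_gamma10 = fit$se_gamma10,
                       sigma2_eps = fit$sigma2_eps,
                       sigma2_delta = fit$sigma2_delta,
                       df_satterthwaite = fit$df_satterthwaite,
                       f_stat = fit$f_stat, p_value = fit$p_value,
                       method = fit$method),
    anova_corrected_experimental =
      anova_summary(res$anova_corrected$experimental),
    anova_corrected_control = anova_summary(res$anova_corrected$control),
    pairwise_corrected_experimental = res$pairwise,
    mean_scores = list(
      z_raw = mean(res$scores$experimental$z_raw, na.rm = TRUE),
      z_corrected = mean(res$scores$experimental$z_corrected, na.rm = TRUE),
      control_z_raw = mean(res$scores$control$z_raw, na.rm = TRUE),
      control_z_corrected = mean(res$scores$control$z_corrected,
                                 na.rm = TRUE)),
    score_tests = res$score_tests)
}

#' @export
print.conformity_pipeline <- function(x, ...) {
  cat("Deviance-based conformity pipeline (seed ", x$seed, ")\n\n", sep = "")
  cat(sprintf("Baseline raw initial ratings, experimental vs control:\n  t(%d) = %.3f, p %s, d = %.3f\n\n",
              x$baseline$df, x$baseline$t, format_p(x$baseline$p),
              x$baseline$cohens_d))
  cat("Mixed ANOVA, rating change ~ Deviation x Group:\n")
  print(x$anova_mixed)
  cat("\nControl-group RTM model:\n")
  print(x$control_fit)
  cat("\nCorrected experimental-group Deviation ANOVA:\n")
  print(x$anova_corrected$experimental)
  cat("\nCorrected control-group Deviation ANOVA (falsification):\n")
  print(x$anova_corrected$control)
  st <- x$score_tests
  cat(sprintf("\nConformity scores (experimental): mean z_raw = %.3f, mean z_corrected = %.3f\n",
              mean(x$scores$experimental$z_raw, na.rm = TRUE),
              mean(x$scores$experimental$z_corrected, na.rm = TRUE)))
  cat(sprintf("  corrected vs 0: t(%d) = %.3f, p %s, d = %.3f\n",
              st$corrected_vs_zero$df, st$corrected_vs_zero$t,
              format_p(st$corrected_vs_zero$p), st$corrected_vs_zero$cohens_d))
  cat(sprintf("  raw vs corrected: t(%d) = %.3f, p %s, d = %.3f\n",
              st$raw_vs_corrected$df, st$raw_vs_corrected$t,
              format_p(st$raw_vs_corrected$p), st$raw_vs_corrected$cohens_d))
  invisible(x)
}
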