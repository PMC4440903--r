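#' Per-participant condition means
#'
#' Aggregates centered items to the participant x condition cell means that
#' feed the repeated-measures ANOVAs: one row per participant, one column
#' per Deviation condition.
#'
#' @param items Centered items (one or both groups).
#' @param value Name of the column to average: `"c"` (observed change) or
#'   `"s_hat"` (RTM-corrected change).
#' @return Numeric matrix (participants x conditions) with the participant's
#'   group as attribute `"group"` (a factor aligned with the rows).
#' @examples
#' cfg <- generator_config(n_per_group = 3, n_items = 30, seed = 5)
#' items <- preprocess_trials(generate_experiment(cfg))
#' condition_means(items)
#' @export
condition_means <- function(items, value = "c") {
  stopifnot(value %in% names(items), "condition" %in% names(items))
  tab <- tapply(items[[value]], list(items$participant_id, items$condition),
                mean)
  if (anyNA(tab)) {
    stop("unbalanced design: every participant needs items in all ",
         "conditions", call. = FALSE)
  }
  Y <- as.matrix(tab)
  if ("group" %in% names(items)) {
    grp <- items$group[match(rownames(Y), items$participant_id)]
    attr(Y, "group") <- factor(grp)
  }
  Y
}

#' Mixed repeated-measures ANOVA with sphericity handling
#'
#' Classical split-plot decomposition for one within-participant factor
#' (columns of `cell_means`) and an optional between-participant factor
#' `group`: sums of squares for the between effect, the subject stratum, the
#' within effect, the interaction, and the within error. Sphericity is
#' assessed with Mauchly's W on orthonormalized contrasts of the pooled
#' within-group covariance matrix; when Mauchly's test rejects at
#' `sphericity_alpha`, the within-effect p-values are recomputed with
#' degrees of freedom multiplied by the Huynh-Feldt epsilon (capped at 1),
#' while uncorrected degrees of freedom and epsilon are reported alongside.
#' The Greenhouse-Geisser epsilon is also returned for diagnostics. Effect
#' sizes are generalized eta-squared: each effect's SS divided by itself
#' plus every subject-related error SS in the design.
#'
#' @param cell_means Participant x condition matrix of cell means (see
#'   [condition_means()]).
#' @param group Optional factor of group labels, one per row of
#'   `cell_means`; taken from the matrix's `"group"` attribute when absent.
#'   With a single level the design reduces to a one-way repeated-measures
#'   ANOVA (no between or interaction rows).
#' @param sphericity_alpha Significance level gating the df correction
#'   (default 0.05).
#' @return Object of class `rm_anova`: `effects` (data.frame with `effect`,
#'   `df_num`, `df_den`, `ss`, `F`, `p`, `eta2_G`, `p_corrected`),
#'   `mauchly` (`W`, `chisq`, `df`, `p`), `epsilon` (`gg`, `hf`),
#'   `correction_applied`, and the error-stratum SS.
#' @examples
#' cfg <- generator_config(n_per_group = 6, n_items = 36, seed = 3)
#' items <- preprocess_trials(generate_experiment(cfg))
#' rm_anova_mixed(condition_means(items))
#' @export
rm_anova_mixed <- function(cell_means, group = NULL, sphericity_alpha = 0.05) {
  Y <- as.matrix(cell_means)
  if (anyNA(Y)) stop("unbalanced design: missing cells", call. = FALSE)
  n <- nrow(Y); p <- ncol(Y)
  if (p < 2L) stop("need >= 2 within-factor levels", call. = FALSE)
  if (is.null(group)) group <- attr(cell_means, "group")
  if (is.null(group)) group <- factor(rep("all", n))
  group <- factor(group)
  a <- nlevels(group)
  if (any(table(group) < 2L)) {
    stop("need >= 2 participants per group", call. = FALSE)
  }

  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  cond_means <- colMeans(Y)
  n_g <- as.vector(table(group))
  grp_means <- tapply(subj_means, group, mean)

  ss_subj_total <- p * sum((subj_means - grand)^2)
  ss_group <- if (a > 1) p * sum(n_g * (grp_means - grand)^2) else 0
  ss_subj_err <- ss_subj_total - ss_group
  df_subj_err <- n - a

  ss_within_total <- sum((Y - subj_means)^2)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_inter <- 0
  if (a > 1) {
    cell_gj <- rowsum(Y, group) / n_g # group x condition means
    dev <- sweep(sweep(cell_gj, 1, grp_means), 2, cond_means) + grand
    ss_inter <- sum(n_g * dev^2)
  }
  ss_err_w <- ss_within_total - ss_cond - ss_inter
  df_err_w <- (n - a) * (p - 1)

  # generalized eta-squared: denominator adds all subject-related error SS
  eta2g <- function(ss) {
    if (ss <= 1e-300) return(0)
    ss / (ss + ss_subj_err + ss_err_w)
  }

  eff <- list()
  if (a > 1) {
    eff[["group"]] <- c(ss = ss_group, df1 = a - 1, df2 = df_subj_err,
                        ms_err = ss_subj_err / df_subj_err)
  }
  eff[["condition"]] <- c(ss = ss_cond, df1 = p - 1, df2 = df_err_w,
                          ms_err = ss_err_w / df_err_w)
  if (a > 1) {
    eff[["group:condition"]] <- c(ss = ss_inter, df1 = (a - 1) * (p - 1),
                                  df2 = df_err_w, ms_err = ss_err_w / df_err_w)
  }
  effects <- do.call(rbind, lapply(names(eff), function(nm) {
    e <- eff[[nm]]
    Fv <- if (e[["ss"]] <= 1e-300) 0 else (e[["ss"]] / e[["df1"]]) / e[["ms_err"]]
    data.frame(effect = nm, df_num = e[["df1"]], df_den = e[["df2"]],
               ss = e[["ss"]], F = Fv,
               p = stats::pf(Fv, e[["df1"]], e[["df2"]], lower.tail = FALSE),
               eta2_G = eta2g(e[["ss"]]),
               stringsAsFactors = FALSE)
  }))

  # sphericity on the pooled within-group covariance of the cell means
  sph <- mauchly_sphericity(Y, group)
  within_rows <- effects$effect != "group"
  correction <- !is.na(sph$mauchly$p) && sph$mauchly$p < sphericity_alpha
  effects$p_corrected <- effects$p
  if (correction) {
    e_hf <- sph$epsilon$hf
    effects$p_corrected[within_rows] <- stats::pf(
      effects$F[within_rows],
      effects$df_num[within_rows] * e_hf,
      effects$df_den[within_rows] * e_hf,
      lower.tail = FALSE)
  }

  structure(list(effects = effects,
                 mauchly = sph$mauchly,
                 epsilon = sph$epsilon,
                 correction_applied = correction,
                 sphericity_alpha = sphericity_alpha,
                 ss_subject_error = ss_subj_err,
                 ss_within_error = ss_err_w,
                 n = n, n_levels = p, n_groups = a),
            class = "rm_anova")
}

# Mauchly's W, its chi-square approximation, and the Greenhouse-Geisser /
# Huynh-Feldt epsilons, from the pooled within-group covariance matrix.
mauchly_sphericity <- function(Y, group) {
  n <- nrow(Y); p <- ncol(Y); a <- nlevels(group)
  f <- n - a # error df of the pooled covariance
  if (p == 2L || f < p) {
    # two levels are always spherical; tiny designs give no test
    return(list(mauchly = list(W = 1, chisq = 0, df = 0, p = NA_real_),
                epsilon = list(gg = 1, hf = 1)))
  }
  grp_mean <- rowsum(Y, group) / as.vector(table(group))
  centered <- Y - grp_mean[as.integer(group), , drop = FALSE]
  S_pool <- crossprod(centered) / f
  M <- stats::contr.helmert(p)
  C <- sweep(M, 2, sqrt(colSums(M^2)), `/`) # orthonormal contrasts
  Sc <- t(C) %*% S_pool %*% C
  q <- p - 1
  tol0 <- max(1e-300, 1e-12 * sum(diag(S_pool)))
  if (sum(diag(Sc)) <= tol0) { # no within-participant variance at all
    return(list(mauchly = list(W = 1, chisq = 0, df = q * (q + 1) / 2 - 1,
                               p = NA_real_),
                epsilon = list(gg = 1, hf = 1)))
  }
  W <- det(Sc) / (sum(diag(Sc)) / q)^q
  chisq <- -(f - (2 * q^2 + q + 2) / (6 * q)) * log(W)
  df_chi <- q * (q + 1) / 2 - 1
  p_mauchly <- stats::pchisq(chisq, df_chi, lower.tail = FALSE)
  gg <- sum(diag(Sc))^2 / (q * sum(Sc^2))
  hf <- min(1, ((f + 1) * q * gg - 2) / (q * (f - q * gg)))
  list(mauchly = list(W = W, chisq = chisq, df = df_chi, p = p_mauchly),
       epsilon = list(gg = gg, hf = hf))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$n, " participants, ",
      x$n_levels, " within levels",
      if (x$n_groups > 1) paste0(", ", x$n_groups, " groups"), ")\n", sep = "")
  tab <- x$effects
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-16s F(%g, %g) = %.3f, p %s, eta2_G = %.3f\n",
                tab$effect[i], tab$df_num[i], tab$df_den[i], tab$F[i],
                format_p(tab$p_corrected[i]), tab$eta2_G[i]))
  }
  if (!is.na(x$mauchly$p)) {
    cat(sprintf("  Mauchly W = %.3f, p %s; epsilon (HF) = %.3f, (GG) = %.3f%s\n",
                x$mauchly$W, format_p(x$mauchly$p), x$epsilon$hf, x$epsilon$gg,
                if (x$correction_applied) " [HF correction applied]" else ""))
  }
  invisible(x)
}

#' Holm-adjusted pairwise comparisons of condition means
#'
#' Paired t-tests for every pair of within-factor conditions, with Holm's
#' step-down adjustment of the p-values (sort ascending; adjusted
#' `p_(i) = max_(j<=i) (m-j+1) p_(j)`, capped at 1).
#'
#' @param cell_means Participant x condition matrix.
#' @return Data.frame with one row per pair: `pair`, `mean_difference`, `t`,
#'   `df`, `p`, `p_holm`.
#' @export
holm_pairwise <- function(cell_means) {
  Y <- as.matrix(cell_means)
  nm <- colnames(Y)
  if (is.null(nm)) nm <- paste0("level", seq_len(ncol(Y)))
  pairs <- utils::combn(ncol(Y), 2)
  rows <- apply(pairs, 2, function(ij) {
    tt <- paired_t(Y[, ij[1]], Y[, ij[2]])
    data.frame(pair = paste(nm[ij[1]], nm[ij[2]], sep = " - "),
               mean_difference = tt$mean_difference,
               t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' One-sample, two-sample, and paired t-tests with Cohen's d
#'
#' Thin result wrappers around the standard t statistics, reporting the
#' fields used throughout the analyses: `t`, `df`, `p` (two-sided),
#' `cohens_d`, `mean_difference`. `two_sample_t` is the pooled-variance test
#' (df = n1 + n2 - 2) with d based on the pooled SD; `paired_t` reduces to a
#' one-sample test on the differences with d = mean(diff)/sd(diff).
#'
#' @param values Numeric vector of scores.
#' @param mu0 Reference value (default 0).
#' @return List with `t`, `df`, `p`, `cohens_d`, `mean_difference` (and `n`).
#' @examples
#' one_sample_t(c(0.2, 0.1, 0.3, 0.25))
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need >= 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("degenerate: zero standard deviation", call. = FALSE)
  m <- mean(values) - mu0
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       cohens_d = m / s, mean_difference = m, n = n)
}

#' @rdname one_sample_t
#' @param group_a,group_b Numeric vectors for the two independent groups.
#' @export
two_sample_t <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(group_a) + (n2 - 1) * stats::var(group_b)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("degenerate: zero pooled variance", call. = FALSE)
  m <- mean(group_a) - mean(group_b)
  t <- m / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       cohens_d = m / sqrt(sp2), mean_difference = m, n = c(n1, n2))
}

#' @rdname one_sample_t
#' @param values_a,values_b Matched numeric vectors (same participants).
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  one_sample_t(values_a - values_b, mu0 = 0)
}

#' Pearson correlation across participants
#'
#' Correlation between two per-participant score vectors, with the t-based
#' two-sided p-value on n - 2 degrees of freedom.
#'
#' @param x_scores,y_scores Matched numeric vectors (one value per
#'   participant).
#' @return List with `r`, `df`, `t`, `p`, `n`.
#' @export
pearson_between_participants <- function(x_scores, y_scores) {
  keep <- !is.na(x_scores) & !is.na(y_scores)
  x <- x_scores[keep]; y <- y_scores[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 participants", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined: zero variance in scores", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2
  t <- r * sqrt(df / max(1 - r^2, 1e-300))
  list(r = r, df = df, t = t, p = 2 * stats::pt(-abs(t), df), n = n)
}
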