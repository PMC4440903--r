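# Independent oracles used across tests. These deliberately avoid the code
# paths of the package: full-matrix likelihoods with generic optimizers, and
# sums of squares accumulated with explicit loops over cells.

# Brute-force REML fit of the random-slope zero-intercept model: builds each
# participant's full covariance matrix, inverts it with solve(), and
# maximizes the restricted likelihood over the two variance components with
# a generic quasi-Newton optimizer (slope profiled by GLS).
brute_force_reml <- function(items, start = c(0.5, 0.05)) {
  by_k <- split(items[c("r", "c")], items$participant_id, drop = TRUE)
  gls <- function(theta) {
    num <- 0; den <- 0
    for (d in by_k) {
      Vi <- solve(theta[1] * diag(nrow(d)) + theta[2] * outer(d$r, d$r))
      num <- num + drop(t(d$r) %*% Vi %*% d$c)
      den <- den + drop(t(d$r) %*% Vi %*% d$r)
    }
    c(gamma = num / den, xvx = den)
  }
  m2l <- function(lt) {
    theta <- exp(lt)
    g <- gls(theta)
    val <- 0
    for (d in by_k) {
      V <- theta[1] * diag(nrow(d)) + theta[2] * outer(d$r, d$r)
      e <- d$c - g[["gamma"]] * d$r
      val <- val + drop(determinant(V)$modulus) +
        drop(t(e) %*% solve(V) %*% e)
    }
    val + log(g[["xvx"]])
  }
  o <- stats::nlminb(log(start), m2l,
                     control = list(rel.tol = 1e-14, abs.tol = 0,
                                    eval.max = 2000, iter.max = 1000))
  theta <- exp(o$par)
  g <- gls(theta)
  list(gamma10 = g[["gamma"]], sigma2_eps = theta[1], sigma2_delta = theta[2],
       se_gamma10 = sqrt(1 / g[["xvx"]]), criterion = o$objective)
}

# Brute-force split-plot ANOVA from raw sums-of-squares formulas, looping
# over cells; returns SS, df, F and generalized eta-squared per effect.
brute_force_split_plot <- function(Y, group) {
  n <- nrow(Y); p <- ncol(Y)
  group <- factor(group)
  lev <- levels(group); a <- length(lev)
  grand <- mean(Y)
  ss_subj <- 0; ss_group <- 0; ss_cond <- 0; ss_inter <- 0; ss_err <- 0
  subj_mean <- sapply(seq_len(n), function(s) mean(Y[s, ]))
  cond_mean <- sapply(seq_len(p), function(j) mean(Y[, j]))
  grp_mean <- sapply(lev, function(g) mean(Y[group == g, ]))
  for (g in lev) {
    ng <- sum(group == g)
    ss_group <- ss_group + p * ng * (grp_mean[g] - grand)^2
    for (j in seq_len(p)) {
      cell <- mean(Y[group == g, j])
      ss_inter <- ss_inter +
        ng * (cell - grp_mean[g] - cond_mean[j] + grand)^2
    }
  }
  for (s in seq_len(n)) {
    ss_subj <- ss_subj + p * (subj_mean[s] - grand)^2
    for (j in seq_len(p)) {
      cell <- mean(Y[group == group[s], j])
      ss_err <- ss_err + (Y[s, j] - subj_mean[s] - cell +
                            grp_mean[as.character(group[s])])^2
    }
  }
  for (j in seq_len(p)) ss_cond <- ss_cond + n * (cond_mean[j] - grand)^2
  ss_subj_err <- ss_subj - ss_group
  denom_err <- ss_subj_err + ss_err
  ss_group <- unname(ss_group); ss_inter <- unname(ss_inter)
  ss_cond <- unname(ss_cond); ss_err <- unname(ss_err)
  ss_subj_err <- unname(ss_subj_err); denom_err <- unname(denom_err)
  list(
    ss = c(group = ss_group, condition = ss_cond, interaction = ss_inter,
           subject_error = ss_subj_err, within_error = ss_err),
    F = c(group = (ss_group / (a - 1)) / (ss_subj_err / (n - a)),
          condition = (ss_cond / (p - 1)) / (ss_err / ((n - a) * (p - 1))),
          interaction = (ss_inter / ((a - 1) * (p - 1))) /
            (ss_err / ((n - a) * (p - 1)))),
    eta2_G = c(group = ss_group / (ss_group + denom_err),
               condition = ss_cond / (ss_cond + denom_err),
               interaction = ss_inter / (ss_inter + denom_err)))
}

# Small centered-items dataset with known heterogeneous slopes, for model
# tests (noise drawn from the current RNG stream).
make_toy_items <- function(n_participants, n_items, mean_slope = -0.4,
                           slope_sd = 0.15, noise_sd = 0.5) {
  do.call(rbind, lapply(seq_len(n_participants), function(k) {
    r <- stats::rnorm(n_items)
    r <- r - mean(r)
    slope <- mean_slope + stats::rnorm(1, 0, slope_sd)
    ch <- slope * r + stats::rnorm(n_items, 0, noise_sd)
    ch <- ch - mean(ch)
    data.frame(participant_id = sprintf("p%02d", k), r = r, c = ch,
               stringsAsFactors = FALSE)
  }))
}

# Control-group-only centered items from the generator (continuous mode by
# default), for recovery and falsification studies.
simulate_control_items <- function(seed, n_per_group = 27, n_items = 180,
                                   discretize = FALSE) {
  cfg <- generator_config(n_per_group = n_per_group, n_items = n_items,
                          discretize = discretize, seed = seed)
  trials <- generate_experiment(cfg)
  items <- preprocess_trials(trials[trials$group == "control", ])
  items
}
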