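make_mixed_toy <- function(seed = 7, n_per_group = 5) {
  set.seed(seed)
  n <- 2 * n_per_group
  Y <- matrix(rnorm(n * 3), n, 3) +
    matrix(rep(c(0, 0.5, 0.9), each = n), n, 3)
  Y[, 3] <- Y[, 3] + rnorm(n, 0, 2)
  g <- factor(rep(c("a", "b"), each = n_per_group))
  Y[g == "b", ] <- Y[g == "b", ] + 0.3
  colnames(Y) <- c("lo", "eq", "hi")
  list(Y = Y, g = g)
}

test_that("mixed ANOVA matches the brute-force sums-of-squares oracle", {
  toy <- make_mixed_toy()
  a <- rm_anova_mixed(toy$Y, toy$g)
  oracle <- brute_force_split_plot(toy$Y, toy$g)
  eff <- a$effects
  expect_equal(eff$F[eff$effect == "group"], unname(oracle$F["group"]))
  expect_equal(eff$F[eff$effect == "condition"],
               unname(oracle$F["condition"]))
  expect_equal(eff$F[eff$effect == "group:condition"],
               unname(oracle$F["interaction"]))
  expect_equal(eff$eta2_G[eff$effect == "group"],
               unname(oracle$eta2_G["group"]))
  expect_equal(eff$eta2_G[eff$effect == "condition"],
               unname(oracle$eta2_G["condition"]))
  expect_equal(eff$eta2_G[eff$effect == "group:condition"],
               unname(oracle$eta2_G["interaction"]))
})

test_that("mixed ANOVA agrees with car's multivariate machinery on W and epsilon", {
  library(car)
  toy <- make_mixed_toy()
  a <- rm_anova_mixed(toy$Y, toy$g)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  mlm <- lm(toy$Y ~ toy$g)
  aa <- car::Anova(mlm, idata = data.frame(cond = factor(1:3)),
                   idesign = ~cond, type = 3)
  s <- suppressWarnings(summary(aa, multivariate = FALSE))
  expect_equal(a$mauchly$W, unname(s$sphericity.tests["cond", 1]),
               tolerance = 1e-6)
  expect_equal(a$mauchly$p, unname(s$sphericity.tests["cond", 2]),
               tolerance = 1e-5)
  expect_equal(a$epsilon$gg, unname(s$pval.adjustments["cond", "GG eps"]),
               tolerance = 1e-6)
  # car reports the uncapped HF epsilon; ours is capped at 1
  expect_equal(a$epsilon$hf,
               min(1, unname(s$pval.adjustments["cond", "HF eps"])),
               tolerance = 1e-6)
  tab <- s$univariate.tests
  expect_equal(a$effects$F[a$effects$effect == "condition"],
               unname(tab["cond", "F value"]), tolerance = 1e-8)
  expect_equal(a$effects$F[a$effects$effect == "group"],
               unname(tab["toy$g", "F value"]), tolerance = 1e-8)
})

test_that("single-group call reduces to the one-way repeated-measures ANOVA", {
  set.seed(8)
  Y <- matrix(rnorm(27 * 3), 27, 3) +
    matrix(rep(c(-0.2, 0, 0.25), each = 27), 27, 3)
  a <- rm_anova_mixed(Y)
  expect_equal(a$effects$effect, "condition")
  expect_equal(a$effects$df_den, 52) # (n - 1)(p - 1)
  long <- data.frame(y = as.vector(Y), s = factor(rep(1:27, 3)),
                     cond = factor(rep(1:3, each = 27)))
  ref <- summary(aov(y ~ cond + Error(s / cond), data = long))
  ref_f <- ref[["Error: s:cond"]][[1]]["cond", "F value"]
  expect_equal(a$effects$F, ref_f, tolerance = 1e-10)
})

test_that("flat within-profiles give F = 0 and zero effect size", {
  set.seed(3)
  base <- rnorm(6)
  Y <- matrix(rep(base, 3), 6, 3) # each participant identical across conditions
  a <- rm_anova_mixed(Y)
  expect_equal(a$effects$F, 0)
  expect_equal(a$effects$eta2_G, 0)
})

test_that("exactly spherical contrast covariance gives Mauchly W = 1", {
  set.seed(10)
  n <- 12; p <- 3
  C <- contr.helmert(p)
  C <- sweep(C, 2, sqrt(colSums(C^2)), `/`)
  Z <- matrix(rnorm(n * (p - 1)), n, p - 1)
  Z <- scale(Z, scale = FALSE)
  Z <- Z %*% solve(chol(crossprod(Z) / (n - 1))) # whiten: cov(Z) = I exactly
  Y <- Z %*% t(C) + rnorm(n) # arbitrary subject levels
  a <- rm_anova_mixed(Y)
  expect_equal(a$mauchly$W, 1, tolerance = 1e-10)
  expect_equal(a$epsilon$gg, 1, tolerance = 1e-10)
  expect_false(a$correction_applied)
})

test_that("epsilon bounds hold for the three-level factor", {
  for (seed in 1:5) {
    set.seed(seed)
    Y <- matrix(rnorm(10 * 3), 10, 3)
    Y[, 1] <- Y[, 1] * (1 + seed) # heterogeneous variances
    a <- rm_anova_mixed(Y)
    expect_gte(a$epsilon$gg, 0.5)
    expect_lte(a$epsilon$gg, 1 + 1e-12)
    expect_lte(a$epsilon$hf, 1)
    expect_gte(a$epsilon$hf, a$epsilon$gg - 1e-12)
  }
})

test_that("Huynh-Feldt correction is applied exactly when Mauchly rejects", {
  set.seed(41)
  n <- 20
  Y <- cbind(rnorm(n, 0, 0.2), rnorm(n, 0.3, 0.2), rnorm(n, 0.5, 3))
  a <- rm_anova_mixed(Y)
  expect_lt(a$mauchly$p, 0.05)
  expect_true(a$correction_applied)
  eff <- a$effects[a$effects$effect == "condition", ]
  expect_equal(eff$p_corrected,
               pf(eff$F, eff$df_num * a$epsilon$hf,
                  eff$df_den * a$epsilon$hf, lower.tail = FALSE))
  expect_gte(eff$p_corrected, eff$p) # the correction can only be conservative
})

test_that("missing cells are an unbalanced-design error", {
  Y <- matrix(rnorm(9), 3, 3)
  Y[2, 3] <- NA
  expect_error(rm_anova_mixed(Y), "unbalanced|missing")
  items <- data.frame(participant_id = c("a", "a", "b"),
                      condition = bin_deviation(c(-1, 0, 1)),
                      c = rnorm(3))
  expect_error(condition_means(items), "unbalanced")
})

test_that("Holm pairwise table applies the step-down rule to paired t-tests", {
  set.seed(23)
  Y <- matrix(rnorm(15 * 3, sd = 0.4), 15, 3) +
    matrix(rep(c(-0.5, 0, 0.4), each = 15), 15, 3)
  colnames(Y) <- c("lo", "eq", "hi")
  tab <- holm_pairwise(Y)
  expect_equal(nrow(tab), 3)
  # independent recomputation of each paired test and of the step-down rule
  raw <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ij) {
    t.test(Y[, ij[1]], Y[, ij[2]], paired = TRUE)$p.value
  })
  expect_equal(tab$p, raw, tolerance = 1e-12)
  ord <- order(raw)
  adj <- pmin(1, cummax((3:1) * raw[ord]))[order(ord)]
  expect_equal(tab$p_holm, adj, tolerance = 1e-12)
  expect_equal(tab$mean_difference,
               c(mean(Y[, 1] - Y[, 2]), mean(Y[, 1] - Y[, 3]),
                 mean(Y[, 2] - Y[, 3])))
})

test_that("one-sample t matches hand evaluation and flags degenerate input", {
  v <- c(0.21, 0.10, 0.33, 0.28, 0.05)
  tt <- one_sample_t(v)
  m <- mean(v); s <- sd(v)
  expect_equal(tt$t, m / (s / sqrt(5)), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$cohens_d, m / s, tolerance = 1e-12)
  ref <- t.test(v)
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$p, ref$p.value)
  # symmetric values: t = 0, d = 0
  tt0 <- one_sample_t(c(-0.3, -0.1, 0.1, 0.3))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$cohens_d, 0)
  expect_error(one_sample_t(rep(1, 4)), "degenerate")
  expect_error(one_sample_t(0.5), ">= 2")
})

test_that("two-sample t is the pooled-variance test with pooled-SD d", {
  a <- c(3.1, 2.8, 3.4); b <- c(2.2, 2.9, 2.5)
  tt <- two_sample_t(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  expect_equal(tt$cohens_d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  # translation equivariance
  tt_shift <- two_sample_t(a + 0.7, b)
  expect_equal(tt_shift$mean_difference, tt$mean_difference + 0.7)
  expect_equal(two_sample_t(a, a)$t, 0)
})

test_that("paired t reduces to the one-sample test on differences", {
  a <- c(0.42, 0.31, 0.56, 0.29, 0.44)
  b <- c(0.30, 0.12, 0.41, 0.20, 0.31)
  tt <- paired_t(a, b)
  ref <- one_sample_t(a - b)
  expect_equal(tt, ref)
  expect_equal(tt$cohens_d, mean(a - b) / sd(a - b))
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "degenerate") # constant shift: sd 0
  expect_error(paired_t(a, b[1:3]), "equal length")
})

test_that("between-participant correlation matches cor.test", {
  x <- c(0.1, 0.25, 0.3, 0.18, 0.4)
  y <- c(0.05, 0.2, 0.33, 0.1, 0.35)
  pc <- pearson_between_participants(x, y)
  ref <- cor.test(x, y)
  expect_equal(pc$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(pc$df, unname(ref$parameter))
  expect_equal(pc$p, ref$p.value, tolerance = 1e-10)
  expect_equal(pearson_between_participants(x, x)$r, 1)
  expect_equal(pearson_between_participants(x, -x)$r, -1)
  expect_error(pearson_between_participants(x, rep(1, 5)), "zero variance")
  expect_error(pearson_between_participants(x[1:2], y[1:2]), ">= 3")
})

test_that("ANOVA p-values are calibrated under an i.i.d. null", {
  set.seed(77)
  n_rep <- 400
  pvals <- replicate(n_rep, {
    Y <- matrix(rnorm(20 * 3), 20, 3)
    a <- rm_anova_mixed(Y)
    a$effects$p_corrected[a$effects$effect == "condition"]
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
})
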