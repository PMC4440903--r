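test_that("exact common-slope data is fitted without residual variance", {
  set.seed(5)
  items <- do.call(rbind, lapply(1:4, function(k) {
    r <- rnorm(12); r <- r - mean(r)
    data.frame(participant_id = paste0("p", k), r = r, c = -0.6 * r)
  }))
  fit <- fit_control_hlm(items)
  expect_equal(fit$gamma10, -0.6, tolerance = 1e-8)
  expect_lt(fit$sigma2_eps, 1e-10)
  expect_lt(fit$sigma2_delta, 1e-10)
})

test_that("with slope variance constrained off the fit is pooled through-origin OLS", {
  set.seed(6)
  items <- make_toy_items(5, 20, slope_sd = 0.3)
  fit <- fit_control_hlm(items, lambda_max = 0)
  expect_equal(fit$sigma2_delta, 0)
  expect_equal(fit$gamma10, sum(items$r * items$c) / sum(items$r^2),
               tolerance = 1e-12)
  expect_equal(fit$df_satterthwaite, nrow(items) - 1)
})

test_that("profiled fit matches a brute-force restricted-likelihood optimizer", {
  set.seed(99)
  items <- make_toy_items(6, 40)
  fit <- fit_control_hlm(items)
  oracle <- brute_force_reml(items,
                             start = c(fit$sigma2_eps * 1.4,
                                       max(fit$sigma2_delta, 0.01) * 2))
  expect_equal(fit$gamma10, oracle$gamma10, tolerance = 1e-6)
  expect_equal(fit$sigma2_eps, oracle$sigma2_eps, tolerance = 1e-5)
  expect_equal(fit$sigma2_delta, oracle$sigma2_delta, tolerance = 1e-4)
})

test_that("fit reproduces the reference mixed-model software exactly", {
  library(lmerTest)
  set.seed(42)
  items <- make_toy_items(8, 30)
  fit <- fit_control_hlm(items)
  m <- lmer(c ~ 0 + r + (0 + r | participant_id), data = items, REML = TRUE)
  s <- summary(m)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$gamma10, unname(lme4::fixef(m)["r"]), tolerance = 1e-6)
  expect_equal(fit$se_gamma10, s$coefficients[1, "Std. Error"],
               tolerance = 1e-5)
  expect_equal(fit$sigma2_eps, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-5)
  expect_equal(fit$sigma2_delta, vc$vcov[vc$grp == "participant_id"],
               tolerance = 1e-4)
  expect_equal(fit$df_satterthwaite, s$coefficients[1, "df"],
               tolerance = 1e-2)
  # BLUP slopes match the reference conditional modes
  blup_ref <- lme4::fixef(m)["r"] + lme4::ranef(m)$participant_id[, "r"]
  expect_equal(unname(fit$blup_slopes), blup_ref, tolerance = 1e-4)
})

test_that("REML and full-ML slope estimates agree within their standard errors", {
  set.seed(12)
  items <- make_toy_items(10, 40)
  reml <- fit_control_hlm(items, method = "REML")
  ml <- fit_control_hlm(items, method = "ML")
  expect_lt(abs(reml$gamma10 - ml$gamma10),
            min(reml$se_gamma10, ml$se_gamma10))
})

test_that("degenerate designs raise informative errors", {
  items <- data.frame(participant_id = rep(c("a", "b"), each = 3),
                      r = rep(0, 6), c = rnorm(6))
  expect_error(fit_control_hlm(items), "degenerate")
  one <- data.frame(participant_id = "a", r = rnorm(5), c = rnorm(5))
  expect_error(fit_control_hlm(one), "at least 2 participants")
  tiny <- data.frame(participant_id = c("a", "a", "b"),
                     r = c(-1, 1, 0.5), c = rnorm(3))
  expect_error(fit_control_hlm(tiny), ">= 2 items")
})

test_that("slope recovery on control simulations covers the closed-form value", {
  hits <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    items <- simulate_control_items(seed = 3000 + i, n_per_group = 27,
                                    n_items = 60)
    fit <- fit_control_hlm(items)
    if (abs(fit$gamma10 - (-0.374)) < 3 * fit$se_gamma10) hits <- hits + 1L
  }
  expect_gte(hits, 17L) # nominal coverage of the 3-SE band is ~99.7%
})

test_that("slope variance is unchanged by a shift only after re-centering", {
  set.seed(30)
  items <- make_toy_items(6, 25)
  fit0 <- fit_control_hlm(items)
  shifted <- items
  sel <- shifted$participant_id == "p01"
  shifted$c[sel] <- shifted$c[sel] + 0.5
  fit_shift <- fit_control_hlm(shifted)
  expect_false(isTRUE(all.equal(fit_shift$sigma2_delta, fit0$sigma2_delta,
                                tolerance = 1e-6)))
  recentered <- shifted
  recentered$c <- mean_center(recentered$c, recentered$participant_id)
  fit_rec <- fit_control_hlm(recentered)
  expect_equal(fit_rec$sigma2_delta, fit0$sigma2_delta, tolerance = 1e-6)
  expect_equal(fit_rec$gamma10, fit0$gamma10, tolerance = 1e-8)
})

test_that("RTM prediction is the slope times the centered rating", {
  expect_equal(predict_rtm_change(-0.374, 0), 0)
  expect_equal(predict_rtm_change(-0.374, 1.0), -0.374)
  expect_equal(predict_rtm_change(-0.374, -2.0), 0.748)
  set.seed(2)
  items <- make_toy_items(3, 10)
  fit <- fit_control_hlm(items)
  expect_equal(predict_rtm_change(fit, 1.5), fit$gamma10 * 1.5)
})

test_that("fit invariants hold: F = t^2, positive df, consistent lambda", {
  set.seed(55)
  items <- make_toy_items(5, 30)
  fit <- fit_control_hlm(items)
  expect_equal(fit$f_stat, (fit$gamma10 / fit$se_gamma10)^2)
  expect_gt(fit$df_satterthwaite, 0)
  expect_gte(fit$sigma2_delta, 0)
  expect_gt(fit$sigma2_eps, 0)
  expect_equal(fit$sigma2_delta, fit$lambda * fit$sigma2_eps)
  expect_output(print(fit), "gamma10")
})
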