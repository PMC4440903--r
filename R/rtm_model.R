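#' Fit the random-slope RTM model to control-group data
#'
#' Fits, by restricted maximum likelihood, the hierarchical linear model that
#' quantifies regression toward the mean in the control group: the item-level
#' rating change is `c_ik = beta_1k * r_ik + eps_ik` with
#' `eps_ik ~ N(0, sigma2_eps)`, and the participant-level slope is
#' `beta_1k = gamma10 + delta_1k` with `delta_1k ~ N(0, sigma2_delta)`.
#' Because both sessions are mean-centered within participant, the intercept
#' is identically zero and is hard-constrained, not estimated.
#'
#' Estimation profiles the criterion over the single variance ratio
#' `lambda = sigma2_delta / sigma2_eps`: for fixed lambda the GLS estimate of
#' `gamma10` and the residual variance have closed forms (the per-participant
#' covariance `sigma2_eps * (I + lambda r r')` is inverted with the rank-one
#' update identity), so the fit reduces to a bounded one-dimensional search
#' on `log(lambda)` over `[0, lambda_max]`. The boundary `lambda = 0` is a
#' legal solution and is reported as `sigma2_delta = 0`.
#'
#' The fixed slope is tested with `F = (gamma10 / SE)^2` on 1 and
#' Satterthwaite denominator degrees of freedom, computed from the variance
#' of the slope estimate as a function of the variance components (gradient
#' by central differences, relative step 1e-5) and their asymptotic
#' covariance (twice the inverse Hessian of the -2 restricted log-likelihood).
#' At the `lambda = 0` boundary the model collapses to through-origin least
#' squares and the residual degrees of freedom `N - 1` are exact.
#'
#' @param items Centered items restricted to one group (normally the control
#'   group): a data.frame with columns `participant_id`, `r` and `c`, as
#'   produced by [preprocess_trials()].
#' @param method `"REML"` (default) or `"ML"`.
#' @param lambda_max Upper bound of the variance-ratio search (default 1e3).
#' @return An object of class `rtm_hlm`: a list with elements `gamma10`,
#'   `se_gamma10`, `sigma2_eps`, `sigma2_delta`, `lambda`,
#'   `df_satterthwaite`, `f_stat`, `t_stat`, `p_value`, `blup_slopes` (named
#'   per-participant slope predictions), `method`, `criterion` (-2 log
#'   restricted likelihood, up to a constant), `n_obs`, `n_participants`.
#' @examples
#' cfg <- generator_config(n_per_group = 8, n_items = 60, discretize = FALSE,
#'                         seed = 42)
#' items <- preprocess_trials(generate_experiment(cfg))
#' fit <- fit_control_hlm(items[items$group == "control", ])
#' fit
#' @export
fit_control_hlm <- function(items, method = c("REML", "ML"), lambda_max = 1e3) {
  method <- match.arg(method)
  stopifnot(all(c("participant_id", "r", "c") %in% names(items)))

  by_k <- split(items[c("r", "c")], items$participant_id, drop = TRUE)
  K <- length(by_k)
  if (K < 2L) stop("need at least 2 participants", call. = FALSE)
  suff <- vapply(by_k, function(d) {
    c(S = sum(d$r^2), T = sum(d$r * d$c), U = sum(d$c^2), n = nrow(d))
  }, numeric(4))
  S <- suff["S", ]; Tt <- suff["T", ]; U <- suff["U", ]; n_k <- suff["n", ]
  if (any(n_k < 2L)) stop("every participant needs >= 2 items", call. = FALSE)
  if (any(S <= 0)) {
    stop("degenerate design: a participant has no variance in the centered ",
         "initial rating", call. = FALSE)
  }
  N <- sum(n_k)
  p_fix <- 1L # one fixed effect (the slope); no intercept by construction
  n_eff <- if (method == "REML") N - p_fix else N

  gls_gamma <- function(lambda) {
    sum(Tt / (1 + lambda * S)) / sum(S / (1 + lambda * S))
  }
  resid_q <- function(lambda, gamma) {
    # sum_k e' (I + lambda r r')^{-1} e for e = c - gamma r
    ee <- U - 2 * gamma * Tt + gamma^2 * S
    re <- Tt - gamma * S
    sum(ee - lambda * re^2 / (1 + lambda * S))
  }
  profile_dev <- function(lambda) {
    g <- gls_gamma(lambda)
    q <- max(resid_q(lambda, g), 1e-300) # exact fits leave a ~0 residual
    d <- n_eff * log(q / n_eff) + sum(log1p(lambda * S))
    if (method == "REML") d <- d + log(sum(S / (1 + lambda * S)))
    d
  }

  eps0 <- 1e-10
  if (lambda_max > 0) {
    opt <- stats::optimize(function(u) profile_dev(exp(u) - eps0),
                           interval = c(log(eps0), log(lambda_max + eps0)),
                           tol = 1e-12)
    lambda <- exp(opt$minimum) - eps0
    # the boundary (no slope heterogeneity) is legal; prefer it on ties
    if (profile_dev(0) <= opt$objective + 1e-10) lambda <- 0
    lambda <- max(lambda, 0)
  } else {
    lambda <- 0 # slope variance constrained off: pooled through-origin GLS
  }

  gamma10 <- gls_gamma(lambda)
  q <- resid_q(lambda, gamma10)
  sigma2_eps <- max(q / n_eff, 1e-30) # exact fits: keep the variance positive
  sigma2_delta <- lambda * sigma2_eps

  var_gamma <- function(theta) { # theta = (sigma2_eps, sigma2_delta)
    1 / sum(S / (theta[1] + theta[2] * S))
  }
  se_gamma10 <- sqrt(var_gamma(c(sigma2_eps, sigma2_delta)))
  t_stat <- gamma10 / se_gamma10
  f_stat <- t_stat^2

  df_sat <- if (lambda < 1e-8) {
    N - p_fix # through-origin least squares: residual df are exact
  } else {
    satterthwaite_df(c(sigma2_eps, sigma2_delta), S, Tt, U, n_k, N, method,
                     var_gamma, fallback = N - K)
  }
  p_value <- stats::pf(f_stat, 1, df_sat, lower.tail = FALSE)

  blup_delta <- lambda * (Tt - gamma10 * S) / (1 + lambda * S)
  blup <- gamma10 + blup_delta
  names(blup) <- names(by_k)

  structure(list(gamma10 = gamma10,
                 se_gamma10 = se_gamma10,
                 sigma2_eps = sigma2_eps,
                 sigma2_delta = sigma2_delta,
                 lambda = lambda,
                 df_satterthwaite = df_sat,
                 f_stat = f_stat,
                 t_stat = t_stat,
                 p_value = p_value,
                 blup_slopes = blup,
                 method = method,
                 criterion = profile_dev(lambda),
                 n_obs = N,
                 n_participants = K),
            class = "rtm_hlm")
}

# -2 log (restricted) likelihood as a function of the variance components,
# with the fixed slope profiled out by GLS; constants dropped.
m2_loglik_theta <- function(theta, S, Tt, U, n_k, method) {
  t1 <- theta[1]; t2 <- theta[2]
  if (t1 <= 0 || t2 < 0) return(Inf)
  a <- t1 + t2 * S # r' V r scale: r'V^{-1}r = S / a
  gamma <- sum(Tt / a) / sum(S / a)
  ee <- U - 2 * gamma * Tt + gamma^2 * S
  re <- Tt - gamma * S
  quad <- sum((ee - t2 * re^2 / a) / t1)
  d <- sum((n_k - 1) * log(t1) + log(a)) + quad
  if (method == "REML") d <- d + log(sum(S / a))
  d
}

satterthwaite_df <- function(theta, S, Tt, U, n_k, N, method, var_gamma,
                             fallback) {
  out <- tryCatch({
    g <- var_gamma(theta)
    # gradient of Var(gamma_hat) wrt the variance components
    grad <- vapply(1:2, function(i) {
      h <- 1e-5 * max(abs(theta[i]), 1e-8)
      up <- theta; up[i] <- up[i] + h
      dn <- theta; dn[i] <- max(dn[i] - h, 0)
      (var_gamma(up) - var_gamma(dn)) / (up[i] - dn[i])
    }, numeric(1))
    # Hessian of the -2 log-likelihood (numeric, central where possible)
    f <- function(th) m2_loglik_theta(th, S, Tt, U, n_k, method)
    hh <- pmax(1e-5 * abs(theta), 1e-9)
    hess <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      ei <- ej <- c(0, 0); ei[i] <- hh[i]; ej[j] <- hh[j]
      lo_ok <- all(theta - ei - ej >= c(1e-12, 0))
      if (i == j) {
        hess[i, j] <- if (lo_ok) {
          (f(theta + ei) - 2 * f(theta) + f(theta - ei)) / hh[i]^2
        } else {
          (f(theta + 2 * ei) - 2 * f(theta + ei) + f(theta)) / hh[i]^2
        }
      } else {
        if (lo_ok) {
          hess[i, j] <- (f(theta + ei + ej) - f(theta + ei - ej) -
                           f(theta - ei + ej) + f(theta - ei - ej)) /
            (4 * hh[i] * hh[j])
        } else {
          hess[i, j] <- (f(theta + ei + ej) - f(theta + ei) -
                           f(theta + ej) + f(theta)) / (hh[i] * hh[j])
        }
      }
    }
    vtheta <- 2 * solve(hess) # asymptotic covariance of the components
    denom <- drop(t(grad) %*% vtheta %*% grad)
    df <- 2 * g^2 / denom
    if (!is.finite(df) || df <= 0) stop("non-finite df")
    df
  }, error = function(e) fallback)
  out
}

#' Predict the RTM-induced rating change
#'
#' Expected rating change caused by regression toward the mean alone, for a
#' mean-centered initial rating `r`: `gamma10 * r`.
#'
#' @param fit An [fit_control_hlm()] result (or a single numeric slope).
#' @param r Mean-centered initial rating(s).
#' @return Numeric vector of expected RTM-induced changes.
#' @examples
#' predict_rtm_change(-0.374, r = c(-2, 0, 1))
#' @export
predict_rtm_change <- function(fit, r) {
  slope_of(fit) * r
}

slope_of <- function(fit) {
  slope <- if (inherits(fit, "rtm_hlm")) fit$gamma10 else fit
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope)) {
    stop("`fit` must be an rtm_hlm fit or a single finite slope",
         call. = FALSE)
  }
  slope
}

#' @export
print.rtm_hlm <- function(x, ...) {
  cat("Random-slope RTM model (intercept fixed at 0), ", x$method, " fit\n",
      sep = "")
  cat(sprintf("  gamma10 = %.3f, SE = %.3f, F(1, %.3f) = %.3f, p %s\n",
              x$gamma10, x$se_gamma10, x$df_satterthwaite, x$f_stat,
              format_p(x$p_value)))
  cat(sprintf("  sigma2_eps = %.3f, sigma2_delta = %.3f\n",
              x$sigma2_eps, x$sigma2_delta))
  cat(sprintf("  %d participants, %d items total\n",
              x$n_participants, x$n_obs))
  invisible(x)
}

format_p <- function(p) {
  if (p < 0.001) "< 0.001" else sprintf("= %.3f", p)
}
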