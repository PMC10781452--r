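# Causal-effect estimators for a harmonized instrument set: IVW (primary),
# MR-Egger, weighted median, weighted mode and maximum likelihood.

new_mr_estimate <- function(method, beta, se, pvalue, nsnp, extra = list()) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
                 pvalue = pvalue, nsnp = as.integer(nsnp), extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s, %d SNPs)\n", x$method, x$nsnp))
  cat(sprintf("  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  if (!is.null(x$extra$egger_intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$extra$egger_intercept, x$extra$egger_intercept_se,
                x$extra$egger_intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$nsnp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' Ratio `r_j = beta_out_j / beta_exp_j` with first-order standard error
#' `s_j = se_out_j / |beta_exp_j|` and inverse-variance weight
#' `w_j = 1 / s_j^2`.
#'
#' @param set A `harmonized_set`; every `beta_exp` must be nonzero.
#' @return Data frame with `variant_id`, `ratio`, `ratio_se`, `weight`.
#' @export
ratio_estimates <- function(set) {
  assert_harmonized(set, 1L, "ratio_estimates")
  zero <- set$beta_exp == 0
  if (any(zero)) {
    tm_error("zero_exposure_effect",
             sprintf("zero exposure effect for SNP(s): %s",
                     paste(set$variant_id[zero], collapse = ", ")),
             variants = set$variant_id[zero])
  }
  s <- set$se_out / abs(set$beta_exp)
  data.frame(variant_id = set$variant_id,
             ratio = set$beta_out / set$beta_exp,
             ratio_se = s, weight = 1 / s^2, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' The primary MR estimator: the inverse-variance weighted average of the
#' per-SNP Wald ratios, `beta = sum(w r) / sum(w)` with fixed-effect
#' `se = sqrt(1 / sum(w))`. Under the multiplicative random-effects model the
#' standard error is inflated by `max(1, sqrt(Q / (k - 2)))` (k >= 3) where
#' `Q` is Cochran's statistic; `"auto"` (default) uses random effects iff the
#' heterogeneity p-value is < 0.05. A single SNP degrades to the Wald ratio.
#'
#' @param set A `harmonized_set` with k >= 1 SNPs.
#' @param effects_model `"auto"`, `"fixed"` or `"multiplicative_random"`.
#' @return An `mr_estimate`; `extra` carries `Q`, `Q_p` and the model used.
#' @export
mr_ivw <- function(set, effects_model = c("auto", "fixed",
                                          "multiplicative_random")) {
  effects_model <- match.arg(effects_model)
  assert_harmonized(set, 1L, "mr_ivw")
  re <- ratio_estimates(set)
  k <- nrow(re)
  if (k == 1L) {
    beta <- re$ratio
    se <- re$ratio_se
    return(new_mr_estimate("wald_ratio", beta, se,
                           2 * pnorm(-abs(beta / se)), 1L,
                           extra = list(effects_model = "fixed")))
  }
  w <- re$weight
  beta <- sum(w * re$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum(w * (re$ratio - beta)^2)
  Q_p <- pchisq(Q, df = k - 1, lower.tail = FALSE)
  scale <- if (k >= 3) max(1, sqrt(Q / (k - 2))) else 1
  model <- switch(effects_model,
                  fixed = "fixed",
                  multiplicative_random = "multiplicative_random",
                  auto = if (Q_p < 0.05) "multiplicative_random" else "fixed")
  se <- if (model == "multiplicative_random") se_fixed * scale else se_fixed
  method <- if (model == "multiplicative_random") "ivw_random" else "ivw_fixed"
  new_mr_estimate(method, beta, se, 2 * pnorm(-abs(beta / se)), k,
                  extra = list(Q = Q, Q_df = k - 1, Q_p = Q_p,
                               effects_model = model))
}

# Weighted regression of beta_out on beta_exp after orienting beta_exp >= 0;
# shared by mr_egger() and the intercept test.
egger_fit <- function(set) {
  assert_harmonized(set, 3L, "mr_egger")
  flip <- set$beta_exp < 0
  bx <- ifelse(flip, -set$beta_exp, set$beta_exp)
  by <- ifelse(flip, -set$beta_out, set$beta_out)
  w <- 1 / set$se_out^2
  k <- length(bx)
  if (var(bx) == 0) {
    tm_error("collinearity",
             "all oriented exposure effects identical: Egger slope undefined")
  }
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  coefs <- drop(solve(XtWX, crossprod(X, w * by)))
  resid <- by - drop(X %*% coefs)
  rss_w <- sum(w * resid^2)
  sigma <- sqrt(rss_w / (k - 2))
  se <- sqrt(diag(solve(XtWX))) * max(1, sigma)
  tval <- coefs / se
  pval <- 2 * pt(-abs(tval), df = k - 2)
  list(coefs = coefs, se = se, pvalue = pval, k = k, df = k - 2)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects
#' (weights `1/se_out^2`) after orienting every SNP to a non-negative
#' exposure effect. The slope estimates the causal effect under the InSIDE
#' assumption; the intercept estimates average directional pleiotropy.
#' Standard errors are scaled by `max(1, sqrt(RSS_w / (k - 2)))` and p-values
#' use the t distribution with `k - 2` degrees of freedom.
#'
#' @param set A `harmonized_set` with k >= 3 SNPs.
#' @return An `mr_estimate`; `extra` carries `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p`.
#' @export
mr_egger <- function(set) {
  fit <- egger_fit(set)
  new_mr_estimate("egger", unname(fit$coefs["slope"]),
                  unname(fit$se["slope"]), unname(fit$pvalue["slope"]), fit$k,
                  extra = list(egger_intercept = unname(fit$coefs["intercept"]),
                               egger_intercept_se = unname(fit$se["intercept"]),
                               egger_intercept_p = unname(fit$pvalue["intercept"]),
                               df = fit$df))
}

weighted_median_point <- function(r, w) {
  ord <- order(r)
  rs <- r[ord]
  cw <- (cumsum(w[ord]) - w[ord] / 2) / sum(w)
  if (0.5 <= cw[1]) return(rs[1])
  if (0.5 >= cw[length(cw)]) return(rs[length(rs)])
  approx(cw, rs, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE for the median/mode point estimators: redraw each
# ratio from Normal(r_j, s_j) and re-apply the estimator with fixed weights.
# Ratios are oriented to a canonical global sign first so the SE is exactly
# invariant (same seed) under negation of all outcome effects.
boot_se <- function(r, s, w, n_boot, seed, estimator) {
  k <- length(r)
  sgn <- if (sum(w * r) < 0) -1 else 1
  r <- sgn * r
  with_seed(seed, {
    draws <- matrix(rnorm(n_boot * k, mean = rep(r, each = n_boot),
                          sd = rep(s, each = n_boot)),
                    nrow = n_boot)
    sd(apply(draws, 1L, estimator, w = w))
  })
}

#' Weighted-median estimator
#'
#' The median of the per-SNP Wald ratios on the inverse-variance weight
#' scale: ratios are sorted and the estimate is the linear interpolation of
#' ratio against normalized cumulative weight at 0.5. Consistent when at
#' least half the weight comes from valid instruments. The standard error is
#' the standard deviation of the estimate over `n_boot` parametric-bootstrap
#' redraws `r_j* ~ Normal(r_j, s_j)` (weights held fixed).
#'
#' @param set A `harmonized_set` with k >= 3 SNPs.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Mandatory bootstrap seed (recorded in `extra`).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed) {
  assert_harmonized(set, 3L, "mr_weighted_median")
  re <- ratio_estimates(set)
  beta <- weighted_median_point(re$ratio, re$weight)
  se <- boot_se(re$ratio, re$ratio_se, re$weight, n_boot, seed,
                weighted_median_point)
  new_mr_estimate("weighted_median", beta, se, 2 * pnorm(-abs(beta / se)),
                  nrow(re), extra = list(n_boot = n_boot, seed = seed))
}

mode_bandwidth <- function(r, phi) {
  k <- length(r)
  comp <- c(sd(r), mad(r))          # mad() already includes the 1.4826 factor
  comp <- comp[comp > 0]
  if (!length(comp)) return(0)
  phi * 0.9 * min(comp) * k^(-1 / 5)
}

weighted_mode_point <- function(r, w, phi = 1) {
  h <- mode_bandwidth(r, phi)
  if (h == 0) return(r[1])          # all ratios identical
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512L)
  dens <- colSums(w * exp(-0.5 * (outer(r, grid, "-") / h)^2))
  grid[which.max(dens)]             # which.max takes the lowest index on ties
}

#' Weighted-mode estimator
#'
#' Mode of the inverse-variance-weighted Gaussian kernel density of the
#' per-SNP Wald ratios, evaluated exactly on a 512-point grid spanning
#' `[min(r) - 3h, max(r) + 3h]`. The bandwidth is the modified Silverman rule
#' `h = phi * 0.9 * min(sd(r), mad(r)) * k^(-1/5)` (zero components dropped
#' from the min; an all-identical set returns the common ratio). Consistent
#' when the largest group of instruments sharing a causal estimate is valid
#' (ZEMPA). SE via the same parametric bootstrap as the weighted median.
#'
#' @param set A `harmonized_set` with k >= 3 SNPs.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Mandatory bootstrap seed.
#' @return An `mr_estimate`; `extra` carries the bandwidth.
#' @export
mr_weighted_mode <- function(set, phi = 1, n_boot = 1000L, seed) {
  assert_harmonized(set, 3L, "mr_weighted_mode")
  re <- ratio_estimates(set)
  beta <- weighted_mode_point(re$ratio, re$weight, phi)
  se <- boot_se(re$ratio, re$ratio_se, re$weight, n_boot, seed,
                function(r, w) weighted_mode_point(r, w, phi))
  new_mr_estimate("weighted_mode", beta, se, 2 * pnorm(-abs(beta / se)),
                  nrow(re),
                  extra = list(bandwidth = mode_bandwidth(re$ratio, phi),
                               phi = phi, n_boot = n_boot, seed = seed))
}

#' Maximum-likelihood estimator
#'
#' Maximizes the two-sample likelihood with independent components
#' `beta_exp_j ~ Normal(gamma_j, se_exp_j^2)` and
#' `beta_out_j ~ Normal(beta * gamma_j, se_out_j^2)` over
#' `(beta, gamma_1..gamma_k)` by alternating exact coordinate updates
#' (each step maximizes the likelihood in one block, so the ascent is
#' monotone), initialized at `gamma = beta_exp` and `beta` = fixed-effect
#' IVW. Convergence requires gradient norm < `tol`; the standard error comes
#' from the observed information at the optimum (Schur complement for beta).
#' When exposure effects are measured without error the estimate collapses to
#' fixed-effect IVW.
#'
#' @param set A `harmonized_set` with k >= 2 SNPs.
#' @param tol Gradient-norm convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 500) before a convergence error.
#' @return An `mr_estimate`; `extra` carries iterations and gradient norm.
#' @export
mr_max_likelihood <- function(set, tol = 1e-8, max_iter = 500L) {
  assert_harmonized(set, 2L, "mr_max_likelihood")
  bx <- set$beta_exp; by <- set$beta_out
  vx <- set$se_exp^2; vy <- set$se_out^2
  k <- length(bx)

  gamma <- bx
  beta <- mr_ivw(set, "fixed")$beta
  grad_norm <- function(beta, gamma) {
    g_gamma <- (bx - gamma) / vx + beta * (by - beta * gamma) / vy
    g_beta <- sum(gamma * (by - beta * gamma) / vy)
    sqrt(sum(g_gamma^2) + g_beta^2)
  }
  it <- 0L
  repeat {
    beta_old <- beta; gamma_old <- gamma
    gamma <- (bx / vx + beta * by / vy) / (1 / vx + beta^2 / vy)
    denom <- sum(gamma^2 / vy)
    if (denom == 0) tm_error("collinearity", "all fitted gamma are zero")
    beta <- sum(gamma * by / vy) / denom
    it <- it + 1L
    gn <- grad_norm(beta, gamma)
    if (gn < tol) break
    # floating-point fixpoint: when the iterates stop moving at machine
    # precision the gradient norm cannot shrink further (its scale is
    # amplified by 1/se^2), so accept the stationary point
    delta <- max(abs(beta - beta_old) / max(1, abs(beta)),
                 max(abs(gamma - gamma_old) / pmax(1, abs(gamma))))
    if (it > 1L && delta < 1e-14) break
    if (it >= max_iter) {
      tm_error("convergence",
               sprintf("no convergence in %d iterations (gradient norm %.3g)",
                       max_iter, gn),
               beta = beta, gamma = gamma, gradient_norm = gn)
    }
  }
  # observed information, beta block via Schur complement
  I_bb <- sum(gamma^2 / vy)
  I_bg <- -(by - 2 * beta * gamma) / vy
  I_gg <- 1 / vx + beta^2 / vy
  se <- sqrt(1 / (I_bb - sum(I_bg^2 / I_gg)))
  new_mr_estimate("max_likelihood", beta, se, 2 * pnorm(-abs(beta / se)), k,
                  extra = list(iterations = it,
                               gradient_norm = grad_norm(beta, gamma),
                               loglik = -0.5 * sum((bx - gamma)^2 / vx +
                                                     (by - beta * gamma)^2 / vy)))
}

# Log-likelihood at arbitrary (beta, gamma); used by optimality checks.
ml_loglik <- function(set, beta, gamma) {
  -0.5 * sum((set$beta_exp - gamma)^2 / set$se_exp^2 +
               (set$beta_out - beta * gamma)^2 / set$se_out^2)
}
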