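# Heterogeneity/pleiotropy diagnostics, leave-one-out, power, BH-FDR and
# fixed/random-effects meta-analysis.

#' Cochran Q heterogeneity test
#'
#' `Q = sum(w_j (r_j - beta_ivw_fixed)^2)` over the per-SNP Wald ratios, with
#' p from the upper tail of the chi-square distribution on `k - 1` degrees of
#' freedom. Q = 0 iff all ratios are equal.
#'
#' @param set A `harmonized_set` with k >= 2 SNPs.
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(set) {
  assert_harmonized(set, 2L, "cochran_q")
  est <- mr_ivw(set, "fixed")
  list(Q = est$extra$Q, df = est$extra$Q_df, p = est$extra$Q_p)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept of the MR-Egger regression with its standard error
#' and t-based p-value (`k - 2` df). An intercept away from zero indicates
#' average directional pleiotropy violating the exclusion restriction.
#'
#' @param set A `harmonized_set` with k >= 3 SNPs.
#' @return List with `intercept`, `se`, `p`.
#' @export
egger_intercept_test <- function(set) {
  fit <- egger_fit(set)
  list(intercept = unname(fit$coefs["intercept"]),
       se = unname(fit$se["intercept"]),
       p = unname(fit$pvalue["intercept"]))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW (auto effects model) causal effect omitting each SNP
#' in turn. A SNP is flagged influential when its omission flips the sign of
#' the estimate or moves the p-value across 0.05.
#'
#' @param set A `harmonized_set` with k >= 2 SNPs.
#' @return Data frame with one row per left-out SNP: `variant_id`, `beta`,
#'   `se`, `pvalue`, `influential`; the full-set estimate is stored in the
#'   `full` attribute.
#' @export
leave_one_out <- function(set) {
  assert_harmonized(set, 2L, "leave_one_out")
  full <- mr_ivw(set, "auto")
  k <- nrow(set)
  rows <- lapply(seq_len(k), function(j) {
    sub <- set[-j, , drop = FALSE]
    class(sub) <- class(set)
    e <- mr_ivw(sub, "auto")
    data.frame(variant_id = set$variant_id[j], beta = e$beta, se = e$se,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$influential <- sign(out$beta) != sign(full$beta) |
    ((out$pvalue < 0.05) != (full$pvalue < 0.05))
  attr(out, "full") <- full
  out
}

#' Statistical power of a two-sample MR analysis
#'
#' Normal approximation based on the non-centrality parameter: for a
#' continuous outcome `lambda = |beta| * sqrt(n * R2)`; for a binary outcome
#' `lambda = |beta| * sqrt(n * R2 * K * (1 - K))` with `beta` on the log-odds
#' scale and `K` the case fraction. Power is
#' `1 - Phi(z_{1-a/2} - lambda) + Phi(-z_{1-a/2} - lambda)`, which equals
#' `alpha` exactly when `beta_true = 0`.
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param r2_exposure Variance in the exposure explained by the instruments,
#'   in (0, 1).
#' @param beta_true Hypothesized causal effect (per exposure unit; log-odds
#'   for binary outcomes).
#' @param alpha Two-sided significance level (default 0.05).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param case_fraction Case fraction K in (0,1); required for binary.
#' @return Power in \[0, 1\].
#' @export
mr_power <- function(n_outcome, r2_exposure, beta_true, alpha = 0.05,
                     outcome_type = c("continuous", "binary"),
                     case_fraction = NULL) {
  outcome_type <- match.arg(outcome_type)
  tm_assert(r2_exposure > 0 && r2_exposure < 1, "domain",
            "r2_exposure must lie in (0,1)")
  tm_assert(n_outcome > 0, "domain", "n_outcome must be > 0")
  if (outcome_type == "binary") {
    if (is.null(case_fraction) || is.na(case_fraction) ||
        case_fraction <= 0 || case_fraction >= 1) {
      tm_error("domain", "binary outcomes need case_fraction in (0,1)")
    }
    lambda <- abs(beta_true) *
      sqrt(n_outcome * r2_exposure * case_fraction * (1 - case_fraction))
  } else {
    lambda <- abs(beta_true) * sqrt(n_outcome * r2_exposure)
  }
  z <- qnorm(1 - alpha / 2)
  1 - pnorm(z - lambda) + pnorm(-z - lambda)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: on the sorted scale
#' `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to input order.
#' Monotone in p and bounded by `[p, 1]`.
#'
#' @param pvalues Numeric vector with values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  tm_assert(length(pvalues) > 0, "empty_input", "no p-values supplied")
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    tm_error("domain", "p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Fixed/random-effects meta-analysis of MR estimates
#'
#' Pools estimates of the same quantity: fixed effects with weights `1/se^2`;
#' random effects with DerSimonian-Laird
#' `tau2 = max(0, (Q - (m-1)) / (sum(w) - sum(w^2)/sum(w)))` and weights
#' `1/(se^2 + tau2)`. `"auto"` uses random effects iff the heterogeneity
#' p-value is < 0.05. A single estimate is passed through with a message;
#' mixing effect scales (beta vs log-OR) is an error.
#'
#' @param estimates Data frame with columns `beta` and `se` (and optionally
#'   `scale`, all entries equal, to guard against pooling across scales).
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return List with `model`, `beta`, `se`, `ci_low`, `ci_high`, `p`, `tau2`,
#'   `Q`, `Q_p`, `m`.
#' @export
meta_combine <- function(estimates, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  tm_assert(is.data.frame(estimates) &&
              all(c("beta", "se") %in% names(estimates)),
            "schema", "estimates need columns beta and se")
  tm_assert(all(estimates$se > 0), "schema", "all se must be > 0")
  if ("scale" %in% names(estimates) &&
      length(unique(estimates$scale)) > 1) {
    tm_error("scale", "cannot pool estimates on different effect scales")
  }
  m <- nrow(estimates)
  if (m == 1L) {
    message("meta_combine: single estimate, passed through unchanged")
    b <- estimates$beta[1]; s <- estimates$se[1]
    return(list(model = "passthrough", beta = b, se = s,
                ci_low = b - Z975 * s, ci_high = b + Z975 * s,
                p = 2 * pnorm(-abs(b / s)), tau2 = 0,
                Q = 0, Q_p = 1, m = 1L))
  }
  w <- 1 / estimates$se^2
  beta_f <- sum(w * estimates$beta) / sum(w)
  Q <- sum(w * (estimates$beta - beta_f)^2)
  Q_p <- pchisq(Q, df = m - 1, lower.tail = FALSE)
  tau2 <- max(0, (Q - (m - 1)) / (sum(w) - sum(w^2) / sum(w)))
  use_random <- switch(model, fixed = FALSE, random = TRUE,
                       auto = Q_p < 0.05)
  if (use_random) {
    wr <- 1 / (estimates$se^2 + tau2)
    beta <- sum(wr * estimates$beta) / sum(wr)
    se <- sqrt(1 / sum(wr))
  } else {
    beta <- beta_f
    se <- sqrt(1 / sum(w))
    tau2 <- if (model == "fixed") 0 else tau2
  }
  list(model = if (use_random) "random" else "fixed", beta = beta, se = se,
       ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
       p = 2 * pnorm(-abs(beta / se)),
       tau2 = if (use_random) tau2 else 0, Q = Q, Q_p = Q_p, m = m)
}
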