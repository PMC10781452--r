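# Estimators: Wald ratios, IVW, MR-Egger, weighted median/mode, maximum
# likelihood, plus their scale/sign equivariances.

test_that("Wald ratios follow their definition and reject zero exposure effects", {
  hs <- make_hset(0.1, 0.01, 0.05, 0.02)
  re <- ratio_estimates(hs)
  expect_equal(re$ratio, 0.5)
  expect_equal(re$ratio_se, 0.2)
  expect_equal(re$weight, 25)

  hs_neg <- make_hset(-0.1, 0.01, 0.05, 0.02)
  re_neg <- ratio_estimates(hs_neg)
  expect_equal(re_neg$ratio, -0.5)
  expect_equal(re_neg$ratio_se, 0.2)

  hs0 <- make_hset(c(0.1, 0), c(0.01, 0.01), c(0.05, 0.05), c(0.02, 0.02))
  err <- tryCatch(ratio_estimates(hs0),
                  targetmr_zero_exposure_effect = function(e) e)
  expect_s3_class(err, "targetmr_zero_exposure_effect")
  expect_match(conditionMessage(err), "s02")
})

test_that("IVW equals the Wald ratio at k = 1 and the symmetric mean at equal weights", {
  one <- make_hset(0.1, 0.01, 0.05, 0.02)
  est <- mr_ivw(one)
  expect_equal(est$method, "wald_ratio")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)

  two <- make_hset(c(0.1, 0.1), c(0.01, 0.01), c(0.04, 0.06), c(0.02, 0.02))
  expect_equal(mr_ivw(two, "fixed")$beta, 0.5)
})

test_that("IVW fixed equals zero-intercept weighted least squares on random sets", {
  for (seed in 1:20) {
    hs <- random_hset(sample(3:10, 1), seed)
    est <- mr_ivw(hs, "fixed")
    w <- 1 / hs$se_out^2
    beta_wls <- sum(w * hs$beta_out * hs$beta_exp) / sum(w * hs$beta_exp^2)
    se_wls <- sqrt(1 / sum(w * hs$beta_exp^2))
    expect_equal(est$beta, beta_wls, tolerance = 1e-10)
    expect_equal(est$se, se_wls, tolerance = 1e-10)
  }
})

test_that("IVW auto switches to the multiplicative random-effects SE under heterogeneity", {
  het <- make_hset(rep(0.1, 5), rep(0.01, 5),
                   c(0.01, 0.03, 0.05, 0.20, 0.40), rep(0.002, 5))
  fixed <- mr_ivw(het, "fixed")
  auto <- mr_ivw(het, "auto")
  expect_true(fixed$extra$Q_p < 0.05)
  expect_equal(auto$method, "ivw_random")
  expect_equal(auto$se,
               fixed$se * sqrt(fixed$extra$Q / (nrow(het) - 2)),
               tolerance = 1e-12)
  hom <- make_hset(rep(0.1, 5), rep(0.01, 5), rep(0.05, 5) + 1e-5 * (1:5),
                   rep(0.01, 5))
  expect_equal(mr_ivw(hom, "auto")$method, "ivw_fixed")
})

test_that("Egger interpolates exact linear data and keeps finite SEs at k = 3", {
  bx <- c(0.05, 0.10, 0.15, 0.20)
  hs <- make_hset(bx, rep(0.005, 4), 0.02 + 0.3 * bx, rep(0.01, 4))
  est <- mr_egger(hs)
  expect_equal(est$beta, 0.3, tolerance = 1e-10)
  expect_equal(est$extra$egger_intercept, 0.02, tolerance = 1e-10)

  # orientation: SNPs with negative exposure effect contribute (-bx, -by)
  hs_flip <- hs
  hs_flip$beta_exp[2] <- -hs$beta_exp[2]
  hs_flip$beta_out[2] <- -hs$beta_out[2]
  est_flip <- mr_egger(hs_flip)
  expect_equal(est_flip$beta, est$beta, tolerance = 1e-12)
  expect_equal(est_flip$extra$egger_intercept, est$extra$egger_intercept,
               tolerance = 1e-12)

  min3 <- make_hset(c(0.05, 0.1, 0.2), rep(0.005, 3),
                    c(0.016, 0.029, 0.062), rep(0.01, 3))
  e3 <- mr_egger(min3)
  expect_true(is.finite(e3$se) && e3$se > 0)
  expect_equal(e3$extra$df, 1L)

  coll <- make_hset(rep(0.1, 3), rep(0.005, 3), c(0.01, 0.02, 0.03),
                    rep(0.01, 3))
  expect_error(mr_egger(coll), class = "targetmr_collinearity")
  expect_error(mr_egger(make_hset(c(0.1, 0.2), c(0.01, 0.01),
                                  c(0.01, 0.02), c(0.01, 0.01))),
               class = "targetmr_insufficient_instruments")
})

test_that("weighted median hits the exact median and resists a weak outlier", {
  hs <- make_hset(c(1, 1, 1), c(0.01, 0.01, 0.01), c(1, 2, 3),
                  c(1, 1, 1))                      # equal ratio weights
  est <- mr_weighted_median(hs, n_boot = 100, seed = 1)
  expect_equal(est$beta, 2)

  # 9 concordant ratios near 0.1 plus a low-weight wild outlier
  bx <- rep(0.1, 10)
  by <- c(0.1 * bx[1:9] + seq(-4e-4, 4e-4, length.out = 9), 0.9 * 0.1)
  sy <- c(rep(0.005, 9), 0.2)
  est_r <- mr_weighted_median(make_hset(bx, rep(0.005, 10), by, sy),
                              n_boot = 100, seed = 1)
  ratios <- by / bx
  expect_gte(est_r$beta, min(ratios[1:9]))
  expect_lte(est_r$beta, max(ratios[1:9]))
})

test_that("weighted mode finds the majority mode and matches a refined grid", {
  same <- make_hset(rep(0.1, 4), rep(0.01, 4), rep(0.07, 4), rep(0.01, 4))
  est <- mr_weighted_mode(same, n_boot = 50, seed = 2)
  expect_equal(est$beta, 0.7)

  maj <- make_hset(rep(1, 4), rep(0.01, 4), c(0.1, 0.1, 0.1, 0.9),
                   rep(0.05, 4))
  re <- ratio_estimates(maj)
  h <- targetmr:::mode_bandwidth(re$ratio, 1)
  est_m <- mr_weighted_mode(maj, n_boot = 50, seed = 2)
  expect_lt(abs(est_m$beta - 0.1), h)

  # 512-point grid argmax vs brute-force 50001-point argmax
  for (seed in 1:20) {
    hs <- random_hset(sample(5:12, 1), seed + 300)
    re <- ratio_estimates(hs)
    r <- re$ratio; w <- re$weight
    h <- targetmr:::mode_bandwidth(r, 1)
    coarse <- targetmr:::weighted_mode_point(r, w, 1)
    fine_grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 50001L)
    dens <- vapply(fine_grid, function(g) sum(w * dnorm((g - r) / h)),
                   numeric(1))
    fine <- fine_grid[which.max(dens)]
    step <- (diff(range(r)) + 6 * h) / 511
    expect_lte(abs(coarse - fine), step)
  }
})

test_that("maximum likelihood collapses to IVW with exact exposures and fits exact lines", {
  hs <- random_hset(8, 42)
  hs_exact <- hs; hs_exact$se_exp <- 1e-8
  ml <- mr_max_likelihood(hs_exact)
  ivw <- mr_ivw(hs_exact, "fixed")
  expect_equal(ml$beta, ivw$beta, tolerance = 1e-4)

  line <- make_hset(c(0.1, 0.2), c(1e-5, 1e-5), 0.3 * c(0.1, 0.2) + 1e-8,
                    c(1e-5, 1e-5))
  expect_equal(mr_max_likelihood(line)$beta, 0.3, tolerance = 1e-6)
})

test_that("the reported ML optimum dominates random perturbations of (beta, gamma)", {
  set.seed(99)
  for (i in 1:10) {
    hs <- random_hset(6, i + 500)
    ml <- mr_max_likelihood(hs)
    gamma_hat <- (hs$beta_exp / hs$se_exp^2 +
                    ml$beta * hs$beta_out / hs$se_out^2) /
      (1 / hs$se_exp^2 + ml$beta^2 / hs$se_out^2)
    ll_opt <- targetmr:::ml_loglik(hs, ml$beta, gamma_hat)
    for (j in 1:10) {
      beta_p <- ml$beta + rnorm(1, 0, 0.05)
      gamma_p <- gamma_hat + rnorm(length(gamma_hat), 0, 0.01)
      expect_lte(targetmr:::ml_loglik(hs, beta_p, gamma_p), ll_opt + 1e-9)
    }
  }
})

test_that("estimators are scale-equivariant in the exposure and sign-equivariant in the outcome", {
  hs <- random_hset(8, 7)
  c_scale <- 2.5
  hs_sc <- hs
  hs_sc$beta_exp <- hs$beta_exp * c_scale
  hs_sc$se_exp <- hs$se_exp * c_scale

  expect_equal(mr_ivw(hs_sc, "fixed")$beta, mr_ivw(hs, "fixed")$beta / c_scale,
               tolerance = 1e-12)
  expect_equal(mr_egger(hs_sc)$beta, mr_egger(hs)$beta / c_scale,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs_sc, 50, seed = 3)$beta,
               mr_weighted_median(hs, 50, seed = 3)$beta / c_scale,
               tolerance = 1e-12)
  # mode: within grid resolution
  re <- ratio_estimates(hs)
  h <- targetmr:::mode_bandwidth(re$ratio, 1)
  step <- (diff(range(re$ratio)) + 6 * h) / 511
  expect_lte(abs(mr_weighted_mode(hs_sc, 1, 50, seed = 3)$beta -
                   mr_weighted_mode(hs, 1, 50, seed = 3)$beta / c_scale),
             step / c_scale + 1e-12)

  hs_neg <- hs; hs_neg$beta_out <- -hs$beta_out
  for (fit in list(
    list(mr_ivw(hs, "fixed"), mr_ivw(hs_neg, "fixed")),
    list(mr_egger(hs), mr_egger(hs_neg)),
    list(mr_weighted_median(hs, 50, seed = 5),
         mr_weighted_median(hs_neg, 50, seed = 5)),
    list(mr_weighted_mode(hs, 1, 50, seed = 5),
         mr_weighted_mode(hs_neg, 1, 50, seed = 5)),
    list(mr_max_likelihood(hs), mr_max_likelihood(hs_neg)))) {
    expect_equal(fit[[2]]$beta, -fit[[1]]$beta, tolerance = 1e-8)
    expect_equal(fit[[2]]$se, fit[[1]]$se, tolerance = 1e-8)
  }
})

test_that("bootstrap estimators are reproducible given a seed and leave the RNG untouched", {
  hs <- random_hset(6, 11)
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  a <- mr_weighted_median(hs, 200, seed = 77)
  after <- rnorm(1)
  b <- mr_weighted_median(hs, 200, seed = 77)
  expect_identical(a$se, b$se)
  expect_identical(before, after)   # caller's RNG stream undisturbed
})
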