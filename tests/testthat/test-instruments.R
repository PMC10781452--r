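# Cis-selection, clumping, harmonization, Steiger filtering, F statistics.

region1 <- data.frame(gene = "G1", chrom = "1", start = 100000L,
                      end = 200000L, exposure_trait = "LDL_C",
                      flank_bp = 100000L, stringsAsFactors = FALSE)

cand3 <- function(p = c(1e-20, 1e-10, 1e-9)) {
  data.frame(variant_id = c("a", "b", "c"), chrom = "1",
             pos = c(110000L, 120000L, 150000L),
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta = 0.05, se = 0.005, pvalue = p, n = 170000,
             n_cases = NA_real_, stringsAsFactors = FALSE)
}

test_that("selection keeps in-window genome-wide-significant SNPs and clumps by LD", {
  ld0 <- diag(3); dimnames(ld0) <- list(c("a", "b", "c"), c("a", "b", "c"))

  one <- cand3(); one$pvalue <- c(1e-9, 0.5, 0.5)
  cfg1 <- instrument_config(min_snps = 1)
  expect_equal(select_cis_instruments(one, region1, ld0, cfg1)$variant_id, "a")

  ld <- ld0; ld["a", "b"] <- ld["b", "a"] <- 0.9
  kept <- select_cis_instruments(cand3(), region1, ld, cfg1)
  expect_equal(kept$variant_id, c("a", "c"))   # b clumped to a, c kept

  all5 <- data.frame(variant_id = paste0("v", 1:5), chrom = "1",
                     pos = seq(110000L, 150000L, by = 10000L),
                     effect_allele = "A", other_allele = "G", eaf = 0.3,
                     beta = 0.05, se = 0.005,
                     pvalue = 10^-(20:16), n = 170000, n_cases = NA_real_,
                     stringsAsFactors = FALSE)
  ld5 <- diag(5); dimnames(ld5) <- list(all5$variant_id, all5$variant_id)
  expect_equal(nrow(select_cis_instruments(all5, region1, ld5, cfg1)), 5L)

  # out-of-window or sub-threshold SNPs never enter
  far <- cand3(); far$pos <- c(110000L, 400000L, 150000L)
  keptf <- select_cis_instruments(far, region1, ld0, cfg1)
  expect_false("b" %in% keptf$variant_id)
})

test_that("too few surviving instruments raises a condition carrying the count", {
  cfg <- instrument_config(min_snps = 3)
  one <- cand3(); one$pvalue <- c(1e-9, 0.5, 0.5)
  err <- tryCatch(
    select_cis_instruments(one, region1, NULL, cfg),
    targetmr_insufficient_instruments = function(e) e)
  expect_s3_class(err, "targetmr_insufficient_instruments")
  expect_equal(err$count, 1L)
})

test_that("greedy clumping matches the independent reference on random instances", {
  cfg <- instrument_config(min_snps = 1, clump_window_bp = 200000L)
  for (seed in 1:40) {
    k <- sample(2:12, 1)
    cand <- random_candidates(k, seed)
    ld <- random_ld(cand$variant_id, seed + 1000)
    big <- data.frame(gene = "G", chrom = "1", start = 1L, end = 600000L,
                      exposure_trait = "LDL_C", flank_bp = 0L)
    kept <- select_cis_instruments(cand, big, ld, cfg)
    ref <- reference_clump(cand, ld, cfg$clump_r2, cfg$clump_window_bp)
    expect_equal(kept$variant_id, ref, info = paste("seed", seed))
    # no retained pair violates the clumping condition
    if (nrow(kept) > 1) {
      for (i in seq_len(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        violating <- ld[kept$variant_id[i], kept$variant_id[j]] >= cfg$clump_r2 &&
          abs(kept$pos[i] - kept$pos[j]) <= cfg$clump_window_bp
        expect_false(violating)
      }
    }
  }
})

test_that("missing LD entries are treated conservatively with a warning", {
  cfg <- instrument_config(min_snps = 1)
  expect_warning(kept <- select_cis_instruments(cand3(), region1, NULL, cfg),
                 "LD entries missing")
  expect_equal(kept$variant_id, "a")     # r2 = 1 imputed: everything clumps
  cfg0 <- instrument_config(min_snps = 1, missing_ld_r2 = 0)
  expect_warning(kept0 <- select_cis_instruments(cand3(), region1, NULL, cfg0))
  expect_equal(nrow(kept0), 3L)
})

make_records <- function(ids, ea, oa, beta, eaf = 0.3, se = 0.01,
                         n = 2e5) {
  data.frame(variant_id = ids, chrom = "1", pos = seq_along(ids) * 100L,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, pvalue = 2 * pnorm(-abs(beta / se)), n = n,
             n_cases = NA_real_, stringsAsFactors = FALSE)
}

test_that("harmonization aligns swapped alleles and excludes inconsistent ones", {
  expo <- make_records(c("rs1", "rs2", "rs3"), c("A", "A", "T"),
                       c("G", "G", "C"), c(0.10, 0.08, 0.05))
  outc <- make_records(c("rs1", "rs2", "rs3"), c("G", "A", "A"),
                       c("A", "C", "G"), c(-0.05, 0.02, 0.01))
  hs <- harmonize(expo, outc)
  # rs1: swapped alleles -> beta negated; rs2: A/G vs A/C -> excluded;
  # rs3: complement strand T/C vs A/G -> aligned without flip
  expect_equal(hs$variant_id, c("rs1", "rs3"))
  expect_equal(hs$beta_out[1], 0.05)
  expect_true(hs$flipped[1])
  expect_equal(hs$beta_out[2], 0.01)
  expect_false(hs$flipped[2])
  expect_equal(attr(hs, "exclusions")$reason, "inconsistent_alleles")
})

test_that("palindromic SNPs drop by default and need unambiguous frequencies to flip", {
  expo <- make_records(c("p1", "p2"), c("A", "G"), c("T", "C"),
                       c(0.1, 0.1), eaf = c(0.50, 0.10))
  outc <- make_records(c("p1", "p2"), c("A", "G"), c("T", "C"),
                       c(0.05, 0.05), eaf = c(0.50, 0.85))
  hs_drop <- harmonize(expo, outc)
  expect_equal(nrow(hs_drop), 0L)    # both palindromic, both dropped
  expect_equal(attr(hs_drop, "exclusions")$reason, rep("palindromic", 2))
  expect_error(harmonize(expo, make_records("zz", "A", "G", 0.1)),
               class = "targetmr_no_overlap")

  hs <- harmonize(expo, outc, policy = "infer_by_eaf")
  # p1 has eaf 0.5 -> ambiguous; p2 frequencies disagree in side -> strand flip
  expect_equal(hs$variant_id, "p2")
  expect_equal(hs$beta_out, -0.05)
  expect_equal(hs$palindromic_resolution, "eaf_flip")
  expect_equal(attr(hs, "exclusions")$reason["p1" == attr(hs, "exclusions")$variant_id],
               "palindromic_ambiguous_eaf")
})

test_that("harmonization is idempotent and invariant to outcome allele flips", {
  sim <- simulate_mr_study(sim_config(seed = 21, n_snps = 8))
  hs <- harmonize(sim$exposure, sim$outcome)

  # re-harmonizing the harmonized outcome representation changes nothing
  out2 <- sim$outcome
  out2$beta <- hs$beta_out[match(out2$variant_id, hs$variant_id)]
  hs2 <- harmonize(sim$exposure, out2)
  expect_equal(hs2$beta_out, hs$beta_out)
  expect_equal(hs2$flipped, hs$flipped)

  # flipping every outcome record's alleles and negating beta is a no-op
  out3 <- sim$outcome
  out3[, c("effect_allele", "other_allele")] <-
    out3[, c("other_allele", "effect_allele")]
  out3$beta <- -out3$beta
  out3$eaf <- 1 - out3$eaf
  hs3 <- harmonize(sim$exposure, out3)
  expect_equal(hs3$beta_out, hs$beta_out)
  expect_equal(hs3$beta_exp, hs$beta_exp)
})

test_that("Steiger filtering keeps forward SNPs, removes reverse and ties", {
  # strong exposure, weak outcome: retained
  hs <- make_hset(beta_exp = c(0.05, 0.001), se_exp = c(0.005, 0.001),
                  beta_out = c(0.001, 0.05), se_out = c(0.001, 0.005),
                  n_exp = 1e5, n_out = 1e5)
  st <- steiger_filter(hs)
  expect_equal(st$set$variant_id, "s01")
  expect_equal(st$steiger$direction, c("forward", "reverse"))
  expect_true(st$steiger$removed[2])

  # exact tie (same t, same n): removed in direction_only mode
  tie <- make_hset(0.05, 0.005, 0.05, 0.005, n_exp = 1e5, n_out = 1e5)
  expect_equal(nrow(steiger_filter(tie)$set), 0L)

  # significant mode keeps a non-forward SNP whose reversal is not significant
  near_tie <- make_hset(c(0.05, 0.0500001), c(0.005, 0.005),
                        c(0.06, 0.0500002), c(0.005, 0.005),
                        n_exp = 1e5, n_out = 1e5)
  cfg_sig <- instrument_config(steiger_mode = "significant")
  expect_equal(nrow(steiger_filter(near_tie, cfg_sig)$set), 2L)

  small_n <- make_hset(0.05, 0.005, 0.01, 0.005, n_exp = 3, n_out = 1e5)
  expect_error(steiger_filter(small_n), class = "targetmr_sample_size")
})

test_that("Steiger r2 is sign-invariant and monotone in |t|", {
  r2 <- targetmr:::r2_from_t
  expect_equal(r2(-4, 1000), r2(4, 1000))
  ts <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(r2(ts, 5000)) > 0))
})

test_that("planted reverse-causal variants are flagged reverse in simulation", {
  hits <- 0L
  for (seed in 1:60) {
    sim <- simulate_mr_study(sim_config(seed = seed, n_reverse = 2))
    st <- steiger_filter(sim_to_hset(sim))
    removed <- st$steiger$variant_id[st$steiger$removed]
    planted <- sim$truth$variant_id[sim$truth$reverse]
    if (all(planted %in% removed)) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.95)
})

test_that("F statistics follow the closed form and its monotonicities", {
  # R2 = 0.5, n = 102, k = 1 -> F = 100
  t_for_r2 <- function(r2, n) sqrt(r2 * (n - 2) / (1 - r2))
  n <- 102
  t1 <- t_for_r2(0.5, n)
  hs <- make_hset(0.1, 0.1 / t1, 0.01, 0.01, n_exp = n)
  fs <- compute_f_statistics(hs)
  expect_equal(fs$overall_R2, 0.5, tolerance = 1e-12)
  expect_equal(fs$overall_F, 100, tolerance = 1e-9)
  expect_false(fs$weak_flag)

  # R2 -> 0 gives F -> 0 and the weak flag
  hs0 <- make_hset(1e-9, 1, 0.01, 0.01, n_exp = 1000)
  fs0 <- compute_f_statistics(hs0)
  expect_lt(fs0$overall_F, 1e-12)
  expect_true(fs0$weak_flag)

  # R2 = 0.01 split over k = 10 SNPs at the lipid-GWAS scale n = 173082
  n <- 173082; k <- 10
  tk <- t_for_r2(0.001, n)
  hsk <- make_hset(rep(0.1, k), rep(0.1 / tk, k), rep(0.01, k),
                   rep(0.01, k), n_exp = n)
  fsk <- compute_f_statistics(hsk)
  expect_equal(fsk$overall_R2, 0.01, tolerance = 1e-10)
  expect_equal(fsk$overall_F, 0.01 * (n - 1 - k) / (0.99 * k),
               tolerance = 1e-9)
  expect_equal(fsk$overall_F, 174.8, tolerance = 1e-3)
  expect_false(fsk$weak_flag)

  # monotone in R2 for fixed (n, k); decreasing in k for fixed (R2, n)
  f_of <- function(R2, n, k) R2 * (n - 1 - k) / ((1 - R2) * k)
  r2s <- seq(0.01, 0.9, by = 0.01)
  expect_true(all(diff(f_of(r2s, 1000, 5)) > 0))
  expect_true(all(diff(f_of(0.1, 1000, 1:20)) < 0))

  expect_error(compute_f_statistics(make_hset(0.1, 0.01, 0.1, 0.01, n_exp = 2)),
               class = "targetmr_degenerate_design")
})
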