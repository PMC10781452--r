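# Shared fixtures and independent reference implementations used as oracles.

# Build a harmonized set directly from effect vectors.
make_hset <- function(beta_exp, se_exp, beta_out, se_out,
                      n_exp = 170000, n_out = 300000,
                      ids = sprintf("s%02d", seq_along(beta_exp))) {
  k <- length(beta_exp)
  structure(data.frame(
    variant_id = ids, chrom = "1", pos = seq_len(k) * 1000L,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp,
    pvalue_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
    n_exp = n_exp, eaf_exp = 0.3,
    beta_out = beta_out, se_out = se_out,
    pvalue_out = 2 * pnorm(-abs(beta_out / se_out)),
    n_out = n_out, eaf_out = 0.3,
    flipped = FALSE, palindromic_resolution = "not_palindromic",
    stringsAsFactors = FALSE),
    gene = "TEST", outcome = "TEST_OUT",
    class = c("harmonized_set", "data.frame"))
}

# Random harmonized set for property tests.
random_hset <- function(k, seed) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    bx <- rnorm(k, 0.05, 0.02)
    bx[abs(bx) < 0.01] <- 0.01
    make_hset(bx, abs(rnorm(k, 0.005, 0.001)) + 1e-4,
              rnorm(k, 0.1 * bx, 0.01), abs(rnorm(k, 0.01, 0.002)) + 1e-4)
  })
}

# Convert a simulated study directly into a harmonized set (alleles already
# aligned by construction) without the selection stage.
sim_to_hset <- function(sim) {
  harmonize(sim$exposure, sim$outcome, gene = sim$region$gene,
            outcome_name = "sim_outcome")
}

# Independent clumping reference: straightforward restart-scan formulation,
# structured differently from the package's single-pass implementation.
reference_clump <- function(cand, ld, r2_threshold, window_bp,
                            missing_r2 = 1) {
  cand <- cand[order(cand$pvalue, cand$pos, cand$variant_id), , drop = FALSE]
  kept <- character(0)
  pool <- cand
  while (nrow(pool) > 0) {
    top <- pool[1, ]
    kept <- c(kept, top$variant_id)
    drop <- logical(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      if (i == 1) { drop[i] <- TRUE; next }
      a <- top$variant_id; b <- pool$variant_id[i]
      r2 <- if (!is.null(ld) && a %in% rownames(ld) && b %in% colnames(ld)) {
        ld[a, b]
      } else missing_r2
      drop[i] <- r2 >= r2_threshold &&
        abs(pool$pos[i] - top$pos) <= window_bp
    }
    pool <- pool[!drop, , drop = FALSE]
  }
  kept
}

# Random symmetric LD matrix with unit diagonal.
random_ld <- function(ids, seed) {
  set.seed(seed)
  k <- length(ids)
  m <- matrix(runif(k * k), k, k)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

# Random candidate table on one chromosome.
random_candidates <- function(k, seed) {
  set.seed(seed)
  data.frame(
    variant_id = sprintf("v%02d", seq_len(k)),
    chrom = "1",
    pos = sort(sample.int(500000L, k)),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = rnorm(k, 0.05, 0.01), se = 0.005,
    pvalue = 10^-runif(k, 8, 30), n = 170000, n_cases = NA_real_,
    stringsAsFactors = FALSE)
}
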