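# Synthetic paired exposure/outcome GWAS summary statistics with known
# ground truth, emulating the two-sample drug-target MR data model and its
# controlled violations (horizontal pleiotropy, reverse causation).

#' Simulation configuration
#'
#' Parameters of the generating model. Per-SNP true exposure effects
#' `gamma_j` are drawn as `|Normal(0, gamma_sd^2)|` truncated at
#' `gamma_min` (each variant is oriented to its exposure-increasing allele,
#' as instrument tables conventionally are) and then the whole vector is
#' multiplied by one common factor so that the smallest expected exposure z
#' statistic is at least `z_min = 6`. A common rescale (rather than a
#' per-SNP floor) keeps every instrument genome-wide significant
#' (`p <= 5e-8`, i.e. `|z| >= 5.45`) when noise-free and ~98% of them
#' significant in noisy draws, while preserving the relative spread of
#' instrument strengths; a per-SNP floor would pile most effects onto the
#' floor, shrink the between-instrument variance in `b_X`, and induce
#' substantial regression-dilution bias in the MR-Egger slope.
#' Standard errors use
#' the standardized-trait approximation `1/sqrt(2 n MAF (1-MAF))`
#' (times `1/sqrt(K(1-K))` on the log-odds scale for binary outcomes).
#' Pleiotropic effects `alpha_j ~ Normal(pleiotropy_mean, pleiotropy_sd^2)`
#' are planted on the `ceiling(prop_invalid * k)` lowest-index SNPs;
#' `n_reverse` highest-index SNPs are reverse-causal (a large direct outcome
#' effect `delta_j` drawn like `gamma`, with
#' `beta_exp ~ Normal(beta_rev * delta_j, se_exp^2)` and `beta_rev = 0.05`).
#' The LD matrix is AR(1): `r^2(i,j) = ld_rho^(2|i-j|)`, SNPs 1 kb apart.
#'
#' @param seed Default seed used by [simulate_mr_study()].
#' @param n_snps Number of instruments k (default 20).
#' @param maf_range Minor-allele-frequency range (default \[0.05, 0.5\]).
#' @param beta_true True causal effect of exposure on outcome (default 0.1,
#'   per 1 SD higher exposure).
#' @param n_exp,n_out Exposure/outcome GWAS sample sizes (defaults 170000
#'   and 300000, the scale of the lipid and disease GWAS the design mirrors).
#' @param ld_rho AR(1) adjacent-SNP correlation in \[0, 0.99\] (default 0).
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-0 pleiotropy) or
#'   `"directional"` (mean `pleiotropy_mean`).
#' @param pleiotropy_sd SD of pleiotropic effects (default 0.01).
#' @param pleiotropy_mean Mean pleiotropic effect; default 0 for balanced,
#'   0.05 for directional.
#' @param prop_invalid Fraction of SNPs carrying pleiotropy when mode is not
#'   `"none"` (default 0.3).
#' @param n_reverse Number of planted reverse-causal SNPs (default 0).
#' @param outcome_type `"continuous"` or `"binary"` (log-odds outcome scale).
#' @param case_fraction Case fraction K for binary outcomes (default 0.1).
#' @param gamma_sd,gamma_min,z_min,beta_rev Generator internals (see above).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_snps = 20L, maf_range = c(0.05, 0.5),
                       beta_true = 0.1, n_exp = 170000, n_out = 300000,
                       ld_rho = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0.01, pleiotropy_mean = NULL,
                       prop_invalid = NULL, n_reverse = 0L,
                       outcome_type = c("continuous", "binary"),
                       case_fraction = 0.1,
                       gamma_sd = 0.02, gamma_min = 0.005, z_min = 6,
                       beta_rev = 0.05) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  if (is.null(pleiotropy_mean)) {
    pleiotropy_mean <- if (pleiotropy_mode == "directional") 0.05 else 0
  }
  if (is.null(prop_invalid)) {
    prop_invalid <- if (pleiotropy_mode == "none") 0 else 0.3
  }
  tm_assert(n_snps >= 1, "config", "n_snps must be >= 1")
  tm_assert(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5
            && maf_range[1] <= maf_range[2],
            "config", "maf_range must lie within (0, 0.5]")
  tm_assert(prop_invalid >= 0 && prop_invalid <= 1, "config",
            "prop_invalid must lie in [0,1]")
  tm_assert(ld_rho >= 0 && ld_rho <= 0.99, "config",
            "ld_rho must lie in [0, 0.99]")
  n_invalid <- if (pleiotropy_mode == "none") 0L
    else as.integer(ceiling(prop_invalid * n_snps))
  if (n_invalid + n_reverse > n_snps) {
    tm_error("config",
             sprintf("%d pleiotropic + %d reverse SNPs exceed k = %d",
                     n_invalid, n_reverse, n_snps))
  }
  structure(list(seed = as.integer(seed), n_snps = as.integer(n_snps),
                 maf_range = maf_range, beta_true = beta_true,
                 n_exp = n_exp, n_out = n_out, ld_rho = ld_rho,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 prop_invalid = prop_invalid, n_invalid = n_invalid,
                 n_reverse = as.integer(n_reverse),
                 outcome_type = outcome_type, case_fraction = case_fraction,
                 gamma_sd = gamma_sd, gamma_min = gamma_min, z_min = z_min,
                 beta_rev = beta_rev),
            class = "sim_config")
}

draw_true_effects <- function(k, cfg, se) {
  g <- abs(rnorm(k, 0, cfg$gamma_sd))
  g <- pmax(g, cfg$gamma_min)
  # common rescale to guaranteed discoverability, preserving relative spread
  g * max(1, cfg$z_min / min(g / se))
}

#' Simulate one paired exposure/outcome GWAS
#'
#' Generates summary statistics under the two-sample MR model: exposure
#' effects `b_X_j ~ Normal(gamma_j, se_X_j^2)` and, for valid forward SNPs,
#' outcome effects `b_Y_j ~ Normal(beta_true * gamma_j + alpha_j, se_Y_j^2)`
#' with independent noise in the two panels. Reverse-causal SNPs swap roles
#' (see [sim_config()]). Returns the two summary-statistic tables in the
#' exact form [read_summary_stats()] produces, an AR(1) LD matrix, a
#' synthetic gene region covering the SNPs, and the ground truth.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`); the output is a
#'   deterministic function of (config, seed).
#' @param gene Gene symbol for the synthetic region.
#' @return List with `exposure`, `outcome` (summary-stat data frames), `ld`
#'   (matrix), `region` (one-row data frame) and `truth` (per-SNP data frame
#'   with `gamma`, `alpha`, `reverse`, realized effects; `beta_true` and the
#'   config as attributes).
#' @export
simulate_mr_study <- function(config = sim_config(), seed = config$seed,
                              gene = "SYNTH1") {
  cfg <- config
  k <- cfg$n_snps
  with_seed(seed, {
    maf <- runif(k, cfg$maf_range[1], cfg$maf_range[2])
    se_x <- 1 / sqrt(2 * cfg$n_exp * maf * (1 - maf))
    se_y0 <- 1 / sqrt(2 * cfg$n_out * maf * (1 - maf))
    se_y <- if (cfg$outcome_type == "binary") {
      se_y0 / sqrt(cfg$case_fraction * (1 - cfg$case_fraction))
    } else se_y0

    gamma <- draw_true_effects(k, cfg, se_x)
    alpha <- numeric(k)
    if (cfg$n_invalid > 0) {
      alpha[seq_len(cfg$n_invalid)] <-
        rnorm(cfg$n_invalid, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    }
    reverse <- rep(FALSE, k)
    if (cfg$n_reverse > 0) {
      reverse[(k - cfg$n_reverse + 1L):k] <- TRUE
    }
    delta <- numeric(k)
    if (any(reverse)) {
      delta[reverse] <- draw_true_effects(sum(reverse), cfg, se_y[reverse])
      gamma[reverse] <- 0
      alpha[reverse] <- 0
    }

    b_x <- rnorm(k, gamma, se_x)
    b_y <- rnorm(k, cfg$beta_true * gamma + alpha, se_y)
    if (any(reverse)) {
      b_x[reverse] <- rnorm(sum(reverse), cfg$beta_rev * delta[reverse],
                            se_x[reverse])
      b_y[reverse] <- rnorm(sum(reverse), delta[reverse], se_y[reverse])
    }

    pos <- 1000000L + (seq_len(k) - 1L) * 1000L
    ids <- sprintf("snp_%03d", seq_len(k))
    exposure <- data.frame(
      variant_id = ids, chrom = "19", pos = pos,
      effect_allele = "A", other_allele = "G",
      eaf = maf, beta = b_x, se = se_x,
      pvalue = pmax(2 * pnorm(-abs(b_x / se_x)), 1e-300),
      n = cfg$n_exp, n_cases = NA_real_, stringsAsFactors = FALSE)
    outcome <- data.frame(
      variant_id = ids, chrom = "19", pos = pos,
      effect_allele = "A", other_allele = "G",
      eaf = maf, beta = b_y, se = se_y,
      pvalue = pmax(2 * pnorm(-abs(b_y / se_y)), 1e-300),
      n = cfg$n_out,
      n_cases = if (cfg$outcome_type == "binary")
        round(cfg$case_fraction * cfg$n_out) else NA_real_,
      stringsAsFactors = FALSE)

    ld <- cfg$ld_rho^(2 * abs(outer(seq_len(k), seq_len(k), "-")))
    dimnames(ld) <- list(ids, ids)

    region <- data.frame(gene = gene, chrom = "19",
                         start = pos[1], end = pos[k],
                         exposure_trait = "LDL_C", flank_bp = 100000L,
                         stringsAsFactors = FALSE)
    truth <- data.frame(variant_id = ids, maf = maf, gamma = gamma,
                        alpha = alpha, delta = delta, reverse = reverse,
                        b_x = b_x, se_x = se_x, b_y = b_y, se_y = se_y,
                        stringsAsFactors = FALSE)
    attr(truth, "beta_true") <- cfg$beta_true
    attr(truth, "config") <- cfg
    attr(truth, "seed") <- seed
    list(exposure = exposure, outcome = outcome, ld = ld, region = region,
         truth = truth)
  })
}

#' Simulate a target-by-outcome grid of paired GWAS
#'
#' One [simulate_mr_study()] per (target, outcome) cell, with per-cell seeds
#' derived deterministically from the master seed and the grid indices, so
#' any cell can be regenerated in isolation.
#'
#' @param base A [sim_config()] shared by all cells.
#' @param targets Character vector of target-gene names.
#' @param outcomes Character vector of outcome names.
#' @param seed Master seed.
#' @return List with `cells` (named `target.outcome`) and `manifest`
#'   (data frame target, outcome, seed).
#' @export
simulate_mr_grid <- function(base, targets, outcomes, seed) {
  tm_assert(length(targets) > 0 && length(outcomes) > 0, "config",
            "targets and outcomes must be non-empty")
  keys <- as.vector(outer(targets, outcomes, paste, sep = "."))
  if (anyDuplicated(keys)) {
    tm_error("config", "duplicate (target, outcome) keys in grid")
  }
  cells <- list()
  manifest <- data.frame(target = character(0), outcome = character(0),
                         seed = integer(0), stringsAsFactors = FALSE)
  for (ti in seq_along(targets)) {
    for (oi in seq_along(outcomes)) {
      s <- derive_seed(seed, ti, oi)
      key <- paste(targets[ti], outcomes[oi], sep = ".")
      cells[[key]] <- simulate_mr_study(base, seed = s, gene = targets[ti])
      manifest <- rbind(manifest,
                        data.frame(target = targets[ti],
                                   outcome = outcomes[oi], seed = s,
                                   stringsAsFactors = FALSE))
    }
  }
  list(cells = cells, manifest = manifest)
}

#' Write one simulated study to disk in the pipeline's input formats
#'
#' Serializes a [simulate_mr_study()] result as two summary-statistic TSVs, a
#' square LD TSV and a BED gene-region file, readable by the `read_*`
#' functions, so the whole pipeline can be exercised end-to-end from files.
#'
#' @param sim A [simulate_mr_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths.
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             region = file.path(dir, "region.bed"))
  fmt_ss <- function(df) {
    for (col in c("eaf", "beta", "se", "pvalue")) {
      df[[col]] <- sprintf("%.15g", df[[col]])
    }
    df
  }
  write.table(fmt_ss(sim$exposure), paths["exposure"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fmt_ss(sim$outcome), paths["outcome"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  ld_out <- data.frame(variant_id = rownames(sim$ld),
                       apply(sim$ld, 2, function(x) sprintf("%.15g", x)),
                       check.names = FALSE, stringsAsFactors = FALSE)
  write.table(ld_out, paths["ld"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  bed <- data.frame(chrom = sim$region$chrom, start = sim$region$start - 1L,
                    end = sim$region$end, gene = sim$region$gene,
                    trait = sim$region$exposure_trait)
  write.table(bed, paths["region"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths
}
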