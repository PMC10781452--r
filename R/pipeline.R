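# Config-driven orchestration over a drug-target-by-outcome grid:
# select -> harmonize -> Steiger -> estimate -> diagnose -> FDR,
# with skip reporting for genes lacking instruments.

ALL_METHODS <- c("ivw", "egger", "weighted_median", "weighted_mode",
                 "max_likelihood")

#' Analysis configuration for [run_analysis()]
#'
#' Collects all inputs and settings of a full drug-target MR run.
#'
#' @param exposures Named list mapping exposure trait (`LDL_C`, `TG`) to a
#'   summary-statistic data frame or file path.
#' @param outcomes Named list; each element is a list with `stats` (data
#'   frame or path), `type` (`"continuous"`/`"binary"`), `category`
#'   (`"longevity"`, `"cardiometabolic"`, `"cancer"`, `"positive_control"`),
#'   optional `n` and `case_fraction` (taken from the stats columns when
#'   absent).
#' @param gene_regions Gene-region data frame (see [read_gene_regions()] /
#'   [lipid_target_regions()]).
#' @param ld LD r-squared matrix or NULL.
#' @param instrument An [instrument_config()].
#' @param methods Estimators to run besides the primary IVW-or-Wald-ratio;
#'   subset of `ivw, egger, weighted_median, weighted_mode, max_likelihood`.
#' @param effects_model IVW effects model (`"auto"`, `"fixed"`,
#'   `"multiplicative_random"`).
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Master seed; per-cell bootstrap seeds are derived from it and
#'   logged.
#' @param phi Weighted-mode bandwidth multiplier.
#' @param fdr_scope `"per_category"` (default; BH within each outcome
#'   category) or `"global"`.
#' @param lower_exposure Report effects per 1 unit *lower* exposure
#'   (lipid-lowering convention): estimates and CIs are negated relative to
#'   the per-unit-increase regression. Default TRUE.
#' @param scale_factor Named per-trait multiplier applied to exposure effects
#'   and SEs before estimation (e.g. SD to mmol/L rescaling). Default 1.
#' @param palindrome_policy,eaf_tolerance Passed to [harmonize()].
#' @param diagnostics Compute Cochran Q / Egger intercept / power per cell.
#' @param loo Compute leave-one-out tables per cell.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(exposures, outcomes, gene_regions, ld = NULL,
                            instrument = instrument_config(),
                            methods = ALL_METHODS,
                            effects_model = "auto",
                            n_boot = 1000L, seed = 1L, phi = 1,
                            fdr_scope = c("per_category", "global"),
                            lower_exposure = TRUE,
                            scale_factor = c(LDL_C = 1, TG = 1),
                            palindrome_policy = "drop",
                            eaf_tolerance = 0.42,
                            diagnostics = TRUE, loo = TRUE) {
  fdr_scope <- match.arg(fdr_scope)
  tm_assert(length(names(outcomes)) == length(unique(names(outcomes))),
            "config", "outcome labels must be unique")
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  for (lab in names(outcomes)) {
    o <- outcomes[[lab]]
    tm_assert(o$type %in% c("continuous", "binary"), "config",
              sprintf("outcome '%s': unknown type '%s'", lab, o$type))
    if (o$type == "binary" && !is.null(o$case_fraction)) {
      tm_assert(o$case_fraction > 0 && o$case_fraction < 1, "config",
                sprintf("outcome '%s': case_fraction outside (0,1)", lab))
    }
  }
  structure(list(exposures = exposures, outcomes = outcomes,
                 gene_regions = gene_regions, ld = ld,
                 instrument = instrument, methods = methods,
                 effects_model = effects_model, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), phi = phi, fdr_scope = fdr_scope,
                 lower_exposure = isTRUE(lower_exposure),
                 scale_factor = scale_factor,
                 palindrome_policy = palindrome_policy,
                 eaf_tolerance = eaf_tolerance,
                 diagnostics = isTRUE(diagnostics), loo = isTRUE(loo)),
            class = "analysis_config")
}

load_stats <- function(x) {
  if (is.character(x)) read_summary_stats(x) else x
}

estimate_row <- function(est, gene, outcome_label, binary, lower_exposure) {
  beta <- est$beta; lo <- est$ci_low; hi <- est$ci_high
  if (lower_exposure) {
    beta <- -beta
    tmp <- lo; lo <- -hi; hi <- -tmp
  }
  data.frame(target_gene = gene, outcome = outcome_label,
             method = est$method, nsnp = est$nsnp,
             beta = beta, se = est$se, ci_low = lo, ci_high = hi,
             or_value = if (binary) exp(beta) else NA_real_,
             or_ci_low = if (binary) exp(lo) else NA_real_,
             or_ci_high = if (binary) exp(hi) else NA_real_,
             pvalue = est$pvalue, stringsAsFactors = FALSE)
}

#' Run the full drug-target MR analysis grid
#'
#' For every (gene, outcome) pair: select cis-instruments, harmonize outcome
#' effects, Steiger-filter, compute F statistics, run the configured
#' estimators, run diagnostics (Cochran Q, Egger intercept, leave-one-out)
#' and power, then adjust the primary (IVW) p-values by Benjamini-Hochberg
#' within `fdr_scope`. Genes or cells with too few instruments are reported
#' in the skip table rather than failing the run, mirroring how underpowered
#' targets are dropped from a drug-target MR study; if *no* cell yields
#' instruments the run fails with per-gene reasons.
#'
#' @param config An [analysis_config()].
#' @return List with `results` (the [write_results()] schema), `diagnostics`
#'   (per-cell Q, Egger intercept, F, power, stage SNP counts), `loo`,
#'   `steiger`, `skipped`, `counts` (per-cell stage reconciliation) and `log`
#'   (character vector, includes every derived seed).
#' @export
run_analysis <- function(config) {
  tm_assert(inherits(config, "analysis_config"), "config",
            "config must be created by analysis_config()")
  exposures <- lapply(config$exposures, load_stats)
  outcomes <- config$outcomes
  for (lab in names(outcomes)) outcomes[[lab]]$stats <-
    load_stats(outcomes[[lab]]$stats)

  regions <- config$gene_regions
  results <- list(); diagnostics <- list(); loo_tabs <- list()
  steiger_tabs <- list(); skipped <- list(); counts <- list()
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  for (gi in seq_len(nrow(regions))) {
    region <- regions[gi, , drop = FALSE]
    gene <- region$gene
    trait <- region$exposure_trait
    expo <- exposures[[trait]]
    if (is.null(expo)) {
      tm_error("config", sprintf("no exposure stats supplied for trait '%s'",
                                 trait))
    }
    sel <- tryCatch(
      select_cis_instruments(expo, region, config$ld, config$instrument),
      targetmr_insufficient_instruments = function(e) e)
    if (inherits(sel, "condition")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        target_gene = gene, outcome = NA_character_,
        stage = "selection", n_snps = sel$count,
        reason = conditionMessage(sel), stringsAsFactors = FALSE)
      note("gene %s skipped at selection: %d instruments", gene, sel$count)
      next
    }
    note("gene %s: %d instruments selected", gene, nrow(sel))

    for (oi in seq_along(outcomes)) {
      lab <- names(outcomes)[oi]
      oc <- outcomes[[oi]]
      binary <- oc$type == "binary"
      hs <- tryCatch(
        harmonize(sel, oc$stats, policy = config$palindrome_policy,
                  eaf_tolerance = config$eaf_tolerance,
                  gene = gene, outcome_name = lab),
        targetmr_no_overlap = function(e) e)
      if (inherits(hs, "condition")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          target_gene = gene, outcome = lab, stage = "harmonization",
          n_snps = 0L, reason = conditionMessage(hs), stringsAsFactors = FALSE)
        next
      }
      n_harm <- nrow(hs)
      n_excl <- nrow(attr(hs, "exclusions"))

      sf <- config$scale_factor[[trait]] %||% 1
      if (!is.na(sf) && sf != 1) {
        hs$beta_exp <- hs$beta_exp * sf
        hs$se_exp <- hs$se_exp * sf
      }

      if (config$instrument$steiger_enabled) {
        st <- steiger_filter(hs, config$instrument)
        hs <- st$set
        st$steiger$target_gene <- gene
        st$steiger$outcome <- lab
        steiger_tabs[[length(steiger_tabs) + 1L]] <- st$steiger
      }
      n_steiger <- nrow(hs)
      counts[[length(counts) + 1L]] <- data.frame(
        target_gene = gene, outcome = lab,
        instruments_selected = nrow(sel),
        kept_after_harmonization = n_harm, harmonization_drops = n_excl,
        kept_after_steiger = n_steiger, stringsAsFactors = FALSE)

      if (n_steiger < config$instrument$min_snps) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          target_gene = gene, outcome = lab, stage = "steiger",
          n_snps = n_steiger,
          reason = sprintf("%d instrument(s) after filtering (< %d)",
                           n_steiger, config$instrument$min_snps),
          stringsAsFactors = FALSE)
        next
      }

      k <- nrow(hs)
      cell_seed <- derive_seed(config$seed, gi, oi)
      note("cell %s/%s: k = %d, bootstrap seed %d", gene, lab, k, cell_seed)

      ests <- list()
      ests$ivw <- mr_ivw(hs, config$effects_model)  # primary, always run
      if ("egger" %in% config$methods && k >= 3) ests$egger <- mr_egger(hs)
      if ("weighted_median" %in% config$methods && k >= 3) {
        ests$weighted_median <- mr_weighted_median(hs, config$n_boot,
                                                   seed = cell_seed)
      }
      if ("weighted_mode" %in% config$methods && k >= 3) {
        ests$weighted_mode <- mr_weighted_mode(hs, config$phi, config$n_boot,
                                               seed = derive_seed(cell_seed, 1L))
      }
      if ("max_likelihood" %in% config$methods && k >= 2) {
        ests$max_likelihood <- mr_max_likelihood(hs)
      }

      rows <- do.call(rbind, lapply(ests, estimate_row, gene = gene,
                                    outcome_label = lab, binary = binary,
                                    lower_exposure = config$lower_exposure))
      rows$category <- oc$category %||% NA_character_

      Q <- Q_p <- eg_i <- eg_p <- mean_F <- pow <- NA_real_
      fs <- compute_f_statistics(hs)
      mean_F <- mean(fs$per_snp$f_stat)
      if (config$diagnostics) {
        if (k >= 2) {
          q <- cochran_q(hs); Q <- q$Q; Q_p <- q$p
        }
        if (k >= 3) {
          eg <- egger_intercept_test(hs); eg_i <- eg$intercept; eg_p <- eg$p
        }
        n_out_cell <- oc$n %||% suppressWarnings(min(hs$n_out, na.rm = TRUE))
        Kc <- oc$case_fraction %||%
          (if (binary && !all(is.na(oc$stats$n_cases)))
            max(oc$stats$n_cases, na.rm = TRUE) /
              max(oc$stats$n, na.rm = TRUE) else NULL)
        if (is.finite(n_out_cell) && fs$overall_R2 > 0 &&
            (!binary || !is.null(Kc))) {
          pow <- mr_power(n_out_cell, fs$overall_R2, ests$ivw$beta,
                          outcome_type = oc$type, case_fraction = Kc)
        }
        if (config$loo && k >= 2) {
          lt <- leave_one_out(hs)
          lt$target_gene <- gene; lt$outcome <- lab
          loo_tabs[[length(loo_tabs) + 1L]] <- lt
        }
      }
      rows$Q <- Q; rows$Q_p <- Q_p
      rows$egger_intercept <- eg_i; rows$egger_intercept_p <- eg_p
      rows$mean_F <- mean_F; rows$power <- pow
      results[[length(results) + 1L]] <- rows

      diagnostics[[length(diagnostics) + 1L]] <- data.frame(
        target_gene = gene, outcome = lab, nsnp = k, Q = Q, Q_p = Q_p,
        egger_intercept = eg_i, egger_intercept_p = eg_p,
        overall_R2 = fs$overall_R2, overall_F = fs$overall_F,
        mean_F = mean_F, weak_flag = fs$weak_flag, power = pow,
        stringsAsFactors = FALSE)
    }
  }

  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(target_gene = character(0), outcome = character(0),
               stage = character(0), n_snps = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  if (!length(results)) {
    tm_error("no_results", paste0(
      "no (gene, outcome) cell yielded instruments; reasons: ",
      paste(sprintf("%s: %s", skipped$target_gene, skipped$reason),
            collapse = "; ")))
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL

  primary <- results$method %in% c("ivw_fixed", "ivw_random", "wald_ratio")
  results$qvalue <- NA_real_
  if (config$fdr_scope == "global") {
    results$qvalue[primary] <- bh_fdr(results$pvalue[primary])
  } else {
    for (cat in unique(results$category[primary])) {
      idx <- primary & (results$category %in% cat)
      if (any(idx)) results$qvalue[idx] <- bh_fdr(results$pvalue[idx])
    }
  }

  list(results = results,
       diagnostics = do.call(rbind, diagnostics),
       loo = if (length(loo_tabs)) do.call(rbind, loo_tabs) else NULL,
       steiger = if (length(steiger_tabs)) do.call(rbind, steiger_tabs)
         else NULL,
       skipped = skipped,
       counts = do.call(rbind, counts),
       log = log)
}

#' Plot-ready forest and heatmap tables
#'
#' Builds the tables behind the standard drug-target MR figures: a forest
#' table with one row per (gene, outcome, method) carrying the effect (beta
#' for continuous outcomes, OR for binary), its CI, p and q; and a genes x
#' outcomes heatmap matrix of the primary (IVW) estimates with a parallel
#' significance mask (`q < 0.05`).
#'
#' @param results The `results` data frame from [run_analysis()].
#' @return List with `forest` (data frame), `heatmap` (numeric matrix),
#'   `significant` (logical matrix).
#' @export
make_plot_tables <- function(results) {
  tm_assert(is.data.frame(results) && nrow(results) > 0, "empty_input",
            "results table is empty")
  binary <- !is.na(results$or_value)
  forest <- data.frame(
    target_gene = results$target_gene, outcome = results$outcome,
    method = results$method, nsnp = results$nsnp,
    effect_type = ifelse(binary, "OR", "beta"),
    estimate = ifelse(binary, results$or_value, results$beta),
    ci_low = ifelse(binary, results$or_ci_low, results$ci_low),
    ci_high = ifelse(binary, results$or_ci_high, results$ci_high),
    pvalue = results$pvalue, qvalue = results$qvalue,
    stringsAsFactors = FALSE)

  primary <- results[results$method %in%
                       c("ivw_fixed", "ivw_random", "wald_ratio"), ,
                     drop = FALSE]
  genes <- unique(primary$target_gene)
  outs <- unique(primary$outcome)
  heat <- matrix(NA_real_, length(genes), length(outs),
                 dimnames = list(genes, outs))
  sig <- matrix(NA, length(genes), length(outs),
                dimnames = list(genes, outs))
  for (i in seq_len(nrow(primary))) {
    g <- primary$target_gene[i]; o <- primary$outcome[i]
    heat[g, o] <- if (!is.na(primary$or_value[i])) primary$or_value[i]
      else primary$beta[i]
    sig[g, o] <- !is.na(primary$qvalue[i]) && primary$qvalue[i] < 0.05
  }
  list(forest = forest, heatmap = heat, significant = sig)
}
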