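# Cis-instrument selection, allele harmonization, Steiger directionality
# filtering and instrument-strength statistics.

#' Instrument-selection configuration
#'
#' Thresholds for cis-instrument selection and filtering. Defaults follow the
#' conventional drug-target MR settings: genome-wide significance
#' `p <= 5e-8`, greedy LD clumping at `r^2 < 0.3` within a 100 kb window,
#' +/-100 kb gene flank, at least 3 instruments per gene, and
#' direction-only Steiger removal of reverse-causal variants.
#'
#' @param pvalue_threshold Exposure p-value ceiling for candidates.
#' @param clump_r2 r-squared at or above which two nearby SNPs are clumped.
#' @param clump_window_bp Maximum base-pair distance at which LD clumping
#'   applies (pairs further apart are never clumped).
#' @param flank_bp Gene-window flank used when the region carries none.
#' @param min_snps Minimum surviving instruments; fewer raises an
#'   insufficient-instruments condition so the caller can skip the gene.
#' @param steiger_enabled Run Steiger filtering in the pipeline.
#' @param steiger_alpha Significance gate, used only in `"significant"` mode.
#' @param steiger_mode `"direction_only"` removes every SNP whose outcome
#'   r-squared is >= its exposure r-squared; `"significant"` removes only
#'   those whose reverse direction is also significant at `steiger_alpha`.
#' @param missing_ld_r2 r-squared imputed for candidate pairs absent from the
#'   LD matrix; the conservative default 1 forces them to clump.
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(pvalue_threshold = 5e-8,
                              clump_r2 = 0.3,
                              clump_window_bp = 100000L,
                              flank_bp = 100000L,
                              min_snps = 3L,
                              steiger_enabled = TRUE,
                              steiger_alpha = 0.05,
                              steiger_mode = c("direction_only", "significant"),
                              missing_ld_r2 = 1) {
  steiger_mode <- match.arg(steiger_mode)
  tm_assert(pvalue_threshold > 0 && pvalue_threshold < 1, "config",
            "pvalue_threshold must lie in (0,1)")
  tm_assert(clump_r2 >= 0 && clump_r2 <= 1, "config",
            "clump_r2 must lie in [0,1]")
  tm_assert(clump_window_bp >= 0, "config", "clump_window_bp must be >= 0")
  tm_assert(min_snps >= 1, "config", "min_snps must be >= 1")
  structure(list(pvalue_threshold = pvalue_threshold, clump_r2 = clump_r2,
                 clump_window_bp = as.numeric(clump_window_bp),
                 flank_bp = as.numeric(flank_bp),
                 min_snps = as.integer(min_snps),
                 steiger_enabled = isTRUE(steiger_enabled),
                 steiger_alpha = steiger_alpha, steiger_mode = steiger_mode,
                 missing_ld_r2 = missing_ld_r2),
            class = "instrument_config")
}

ld_lookup <- function(ld, a, b, missing_r2) {
  if (is.null(ld)) return(rep(missing_r2, length(b)))
  out <- rep(missing_r2, length(b))
  if (a %in% rownames(ld)) {
    hit <- b %in% colnames(ld)
    out[hit] <- ld[a, b[hit]]
  }
  out
}

#' Select cis-instruments for one drug-target gene
#'
#' Keeps exposure SNPs on the region's chromosome within
#' `[start - flank, end + flank]` at `pvalue <= pvalue_threshold`, then
#' greedily LD-clumps: the lowest-p remaining SNP is kept and every remaining
#' SNP with `r^2 >= clump_r2` to it *and* within `clump_window_bp` base pairs
#' is discarded; p-value ties break deterministically by (pos, variant_id).
#'
#' @param exposure_stats Summary-statistic data frame (must carry
#'   `chrom`/`pos`).
#' @param region One gene region (single-row data frame or list with `gene`,
#'   `chrom`, `start`, `end`, optional `flank_bp`).
#' @param ld LD r-squared matrix with variant ids as dimnames, or NULL.
#'   Candidate pairs missing from the matrix get `missing_ld_r2`
#'   (default 1 — conservative) with a warning.
#' @param config An [instrument_config()].
#' @return Data frame of kept SNPs in ascending p order. Fewer than
#'   `min_snps` survivors raises a condition of class
#'   `targetmr_insufficient_instruments` carrying `count`.
#' @export
select_cis_instruments <- function(exposure_stats, region, ld = NULL,
                                   config = instrument_config()) {
  region <- as.list(region)
  flank <- region$flank_bp %||% config$flank_bp
  if (is.na(flank)) flank <- config$flank_bp
  tm_assert(!any(is.na(exposure_stats$pos)) && !any(is.na(exposure_stats$chrom)),
            "schema", "exposure records need chrom and pos for cis selection")

  cand <- exposure_stats[
    exposure_stats$chrom == as.character(region$chrom) &
      exposure_stats$pos >= region$start - flank &
      exposure_stats$pos <= region$end + flank &
      exposure_stats$pvalue <= config$pvalue_threshold, , drop = FALSE]

  if (nrow(cand) > 1) {
    cand <- cand[order(cand$pvalue, cand$pos, cand$variant_id), , drop = FALSE]
    missing_pairs <- !is.null(ld) && !all(cand$variant_id %in% rownames(ld))
    if (is.null(ld)) missing_pairs <- TRUE
    if (missing_pairs) {
      warning(sprintf(
        "LD entries missing for some candidate pairs; using r^2 = %g for them",
        config$missing_ld_r2), call. = FALSE)
    }
    keep <- logical(nrow(cand))
    alive <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!alive[i]) next
      keep[i] <- TRUE
      alive[i] <- FALSE
      rest <- which(alive)
      if (!length(rest)) break
      r2 <- ld_lookup(ld, cand$variant_id[i], cand$variant_id[rest],
                      config$missing_ld_r2)
      near <- abs(cand$pos[rest] - cand$pos[i]) <= config$clump_window_bp
      alive[rest[r2 >= config$clump_r2 & near]] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }

  if (nrow(cand) < config$min_snps) {
    tm_error("insufficient_instruments",
             sprintf("gene %s: %d instrument(s) survive selection (< %d)",
                     region$gene %||% "?", nrow(cand), config$min_snps),
             count = nrow(cand), gene = region$gene %||% NA_character_)
  }
  rownames(cand) <- NULL
  cand
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(COMPLEMENT[ch], collapse = ""),
         character(1))
}

is_palindromic <- function(ea, oa) ea == complement_allele(oa)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns each shared SNP so that `beta_exp` and `beta_out` refer to the same
#' effect allele: outcome records with swapped alleles have `beta_out`
#' negated (`flipped = TRUE`); records matching only after strand
#' complementation are aligned on the complemented strand; SNPs whose allele
#' sets differ even after complementation (e.g. A/G vs A/C) are excluded as
#' allele-inconsistent. Palindromic SNPs (A/T, G/C) cannot be strand-resolved
#' from alleles: under `policy = "drop"` (default) they are excluded; under
#' `"infer_by_eaf"` they are oriented by allele-frequency agreement and
#' excluded as ambiguous when either frequency falls in
#' `[eaf_tolerance, 1 - eaf_tolerance]` or is missing.
#'
#' @param exposure,outcome Summary-statistic data frames keyed by
#'   `variant_id`.
#' @param policy Palindrome policy, `"drop"` or `"infer_by_eaf"`.
#' @param eaf_tolerance Lower edge of the ambiguous frequency band
#'   (default 0.42, i.e. \[0.42, 0.58\] is ambiguous).
#' @param gene,outcome_name Optional labels stored on the returned set.
#' @return A `harmonized_set` data frame with per-SNP exposure/outcome
#'   effects, `flipped` and `palindromic_resolution` provenance flags, and an
#'   `exclusions` attribute listing removed SNPs and reasons.
#' @export
harmonize <- function(exposure, outcome, policy = c("drop", "infer_by_eaf"),
                      eaf_tolerance = 0.42,
                      gene = NA_character_, outcome_name = NA_character_) {
  policy <- match.arg(policy)
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (!length(shared)) {
    tm_error("no_overlap", "no variants shared between exposure and outcome")
  }
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  n <- length(shared)
  beta_out <- ou$beta
  eaf_out <- if ("eaf" %in% names(ou)) ou$eaf else rep(NA_real_, n)
  flipped <- rep(FALSE, n)
  pal_res <- rep("not_palindromic", n)
  reason <- rep(NA_character_, n)

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (pal[i]) {
      if (policy == "drop") { reason[i] <- "palindromic"; next }
      ambiguous <- function(f) is.na(f) ||
        (f >= eaf_tolerance && f <= 1 - eaf_tolerance)
      if (!(ea_y == ea_x && oa_y == oa_x) && !(ea_y == oa_x && oa_y == ea_x)) {
        reason[i] <- "inconsistent_alleles"; next
      }
      if (ea_y == oa_x) {            # nominal swap before eaf orientation
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        flipped[i] <- TRUE
      }
      f_x <- ex$eaf[i]; f_y <- eaf_out[i]
      if (ambiguous(f_x) || ambiguous(f_y)) {
        reason[i] <- "palindromic_ambiguous_eaf"; next
      }
      if ((f_x - 0.5) * (f_y - 0.5) < 0) {   # opposite strands: flip
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        flipped[i] <- !flipped[i]
        pal_res[i] <- "eaf_flip"
      } else {
        pal_res[i] <- "eaf_keep"
      }
      next
    }
    if (ea_y == ea_x && oa_y == oa_x) next
    if (ea_y == oa_x && oa_y == ea_x) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      flipped[i] <- TRUE
      next
    }
    cea <- complement_allele(ea_y); coa <- complement_allele(oa_y)
    if (cea == ea_x && coa == oa_x) next
    if (cea == oa_x && coa == ea_x) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      flipped[i] <- TRUE
      next
    }
    reason[i] <- "inconsistent_alleles"
  }

  keep <- is.na(reason)
  exclusions <- data.frame(variant_id = shared[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  hs <- data.frame(
    variant_id = shared[keep],
    chrom = if ("chrom" %in% names(ex)) ex$chrom[keep] else NA_character_,
    pos = if ("pos" %in% names(ex)) ex$pos[keep] else NA_integer_,
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exp = ex$beta[keep], se_exp = ex$se[keep],
    pvalue_exp = ex$pvalue[keep],
    n_exp = if ("n" %in% names(ex)) ex$n[keep] else NA_real_,
    eaf_exp = if ("eaf" %in% names(ex)) ex$eaf[keep] else NA_real_,
    beta_out = beta_out[keep], se_out = ou$se[keep],
    pvalue_out = if ("pvalue" %in% names(ou)) ou$pvalue[keep] else NA_real_,
    n_out = if ("n" %in% names(ou)) ou$n[keep] else NA_real_,
    eaf_out = eaf_out[keep],
    flipped = flipped[keep],
    palindromic_resolution = pal_res[keep],
    stringsAsFactors = FALSE)
  rownames(hs) <- NULL
  structure(hs, gene = gene, outcome = outcome_name, exclusions = exclusions,
            class = c("harmonized_set", "data.frame"))
}

assert_harmonized <- function(set, min_snps = 1L, op = "estimator") {
  tm_assert(is.data.frame(set) &&
              all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(set)),
            "schema", "expected a harmonized instrument set")
  if (nrow(set) < min_snps) {
    tm_error("insufficient_instruments",
             sprintf("%s needs >= %d SNPs, got %d", op, min_snps, nrow(set)),
             count = nrow(set))
  }
  tm_assert(all(set$se_exp > 0) && all(set$se_out > 0), "schema",
            "all standard errors must be > 0")
  invisible(set)
}

# variance explained by one SNP from its t statistic and sample size
r2_from_t <- function(t, n) t^2 / (t^2 + n - 2)

#' Steiger directionality filtering
#'
#' For each SNP computes the variance explained in exposure and outcome from
#' the t-statistic form `r^2 = t^2 / (t^2 + n - 2)`, calls the direction
#' "forward" iff `r^2_exp > r^2_out`, and tests the difference with the
#' Steiger z statistic
#' `z = (atanh(|r_exp|) - atanh(|r_out|)) / sqrt(1/(n_exp-3) + 1/(n_out-3))`.
#' In `direction_only` mode every non-forward SNP (ties included) is removed;
#' in `significant` mode only non-forward SNPs with Steiger `p <
#' steiger_alpha` are removed.
#'
#' @param set A `harmonized_set` with per-SNP `n_exp` and `n_out` (> 3).
#' @param config An [instrument_config()] (fields `steiger_mode`,
#'   `steiger_alpha`).
#' @return List with `set` (the filtered harmonized set) and `steiger`
#'   (per-SNP data frame: r-squareds, direction, z, p, removed flag).
#' @export
steiger_filter <- function(set, config = instrument_config()) {
  assert_harmonized(set, 1L, "steiger_filter")
  if (any(is.na(set$n_exp)) || any(is.na(set$n_out))) {
    tm_error("sample_size", "Steiger filtering needs n_exp and n_out per SNP")
  }
  if (any(set$n_exp <= 3) || any(set$n_out <= 3)) {
    bad <- set$variant_id[set$n_exp <= 3 | set$n_out <= 3]
    tm_error("sample_size",
             sprintf("sample size <= 3 for SNP(s): %s",
                     paste(bad, collapse = ", ")))
  }
  t_exp <- set$beta_exp / set$se_exp
  t_out <- set$beta_out / set$se_out
  r2_exp <- r2_from_t(t_exp, set$n_exp)
  r2_out <- r2_from_t(t_out, set$n_out)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (set$n_exp - 3) + 1 / (set$n_out - 3))
  p <- 2 * pnorm(-abs(z))
  forward <- r2_exp > r2_out
  removed <- if (config$steiger_mode == "direction_only") {
    !forward
  } else {
    !forward & p < config$steiger_alpha
  }
  report <- data.frame(variant_id = set$variant_id,
                       r2_exp = r2_exp, r2_out = r2_out,
                       direction = ifelse(forward, "forward", "reverse"),
                       steiger_z = z, steiger_p = p, removed = removed,
                       stringsAsFactors = FALSE)
  kept <- set[!removed, , drop = FALSE]
  rownames(kept) <- NULL
  for (a in c("gene", "outcome", "exclusions")) {
    attr(kept, a) <- attr(set, a)
  }
  class(kept) <- class(set)
  list(set = kept, steiger = report)
}

#' Instrument-strength F statistics
#'
#' Per-SNP variance explained uses the t-statistic form
#' `r^2 = t^2/(t^2 + n - 2)` by default (allele-frequency form
#' `2 beta^2 eaf (1-eaf)` available when `eaf` is present). The set-level F
#' statistic is `F = R^2 (n - 1 - k) / ((1 - R^2) k)` with `R^2` the sum of
#' per-SNP r-squareds (capped just below 1), `n` the minimum exposure sample
#' size and `k` the number of SNPs; per-SNP F uses `k = 1`. Sets with overall
#' `F <= 10` are flagged as weak.
#'
#' @param set A `harmonized_set` with `n_exp` per SNP.
#' @param r2_method `"tstat"` (default) or `"eaf"`.
#' @return List with `per_snp` (variant_id, r2_explained, f_stat), `k`, `n`,
#'   `overall_R2`, `overall_F`, `weak_flag`.
#' @export
compute_f_statistics <- function(set, r2_method = c("tstat", "eaf")) {
  r2_method <- match.arg(r2_method)
  assert_harmonized(set, 1L, "compute_f_statistics")
  tm_assert(!any(is.na(set$n_exp)), "sample_size",
            "F statistics need n_exp per SNP")
  k <- nrow(set)
  n <- min(set$n_exp)
  if (k >= n - 1) {
    tm_error("degenerate_design",
             sprintf("k = %d >= n - 1 = %g: F statistic undefined", k, n - 1))
  }
  r2 <- if (r2_method == "tstat") {
    r2_from_t(set$beta_exp / set$se_exp, set$n_exp)
  } else {
    tm_assert(!any(is.na(set$eaf_exp)), "schema",
              "r2_method = 'eaf' needs eaf_exp on every SNP")
    2 * set$beta_exp^2 * set$eaf_exp * (1 - set$eaf_exp)
  }
  f_snp <- r2 * (set$n_exp - 2) / (1 - r2)
  R2 <- min(sum(r2), 1 - 1e-12)
  overall_F <- R2 * (n - 1 - k) / ((1 - R2) * k)
  list(per_snp = data.frame(variant_id = set$variant_id, r2_explained = r2,
                            f_stat = f_snp, stringsAsFactors = FALSE),
       k = k, n = n, overall_R2 = R2, overall_F = overall_F,
       weak_flag = overall_F <= 10)
}
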