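# Reading/writing GWAS summary statistics, gene regions, LD matrices and
# result tables. All coordinates are 1-based inclusive GRCh37 internally;
# BED input (0-based half-open) is converted at the boundary.

SS_MANDATORY <- c("variant_id", "effect_allele", "other_allele",
                  "beta", "se", "pvalue")
SS_OPTIONAL <- c("chrom", "pos", "eaf", "n", "n_cases")

#' Default header aliases for GWAS summary-statistic files
#'
#' GWAS consortia name the same columns differently (e.g. `SNP`, `rsid`,
#' `MarkerName` for the variant identifier). This preset maps each canonical
#' field to the header spellings commonly seen in consortium downloads;
#' matching is case-insensitive. Pass a modified copy to
#' [read_summary_stats()] for unusual dialects.
#'
#' @return Named list: canonical field name -> character vector of accepted
#'   headers (the canonical name itself is always accepted).
#' @export
default_column_map <- function() {
  list(
    variant_id    = c("variant_id", "SNP", "rsid", "rsID", "MarkerName",
                      "ID", "variant", "snpid"),
    chrom         = c("chrom", "CHR", "chromosome", "chr_name"),
    pos           = c("pos", "BP", "position", "base_pair_location", "POS"),
    effect_allele = c("effect_allele", "A1", "ALT", "Allele1", "EA",
                      "ea", "alt"),
    other_allele  = c("other_allele", "A2", "REF", "Allele2", "OA", "NEA",
                      "non_effect_allele", "ref"),
    eaf           = c("eaf", "EAF", "Freq1", "effect_allele_frequency",
                      "af", "maf", "FRQ"),
    beta          = c("beta", "Effect", "b", "BETA", "Beta"),
    se            = c("se", "StdErr", "SE", "standard_error", "sebeta"),
    pvalue        = c("pvalue", "P", "p", "P-value", "pval", "p_value",
                      "P_value", "Pvalue"),
    n             = c("n", "N", "sample_size", "TotalSampleSize", "n_total"),
    n_cases       = c("n_cases", "Ncases", "N_case", "ncase", "n_case")
  )
}

resolve_columns <- function(headers, column_map) {
  out <- character(0)
  lower <- tolower(headers)
  for (canon in names(column_map)) {
    aliases <- tolower(unique(c(canon, column_map[[canon]])))
    hit <- which(lower %in% aliases)
    if (length(hit)) out[canon] <- headers[hit[1L]]
  }
  out
}

#' Read GWAS summary statistics
#'
#' Reads a tab- or comma-separated file with a header row, maps headers to the
#' canonical fields (`variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, `n_cases`), uppercases
#' alleles, and drops rows violating the record invariants (alleles in
#' `{A,C,G,T}+` and distinct, `se > 0`, `pvalue` in (0,1], `pos >= 1`, `eaf`
#' in (0,1) when present). Dropped rows are counted, never silently reordered.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param column_map Named list of header aliases; see [default_column_map()].
#' @param duplicates `"error"` (default) fails on duplicated `variant_id`;
#'   `"keep_lowest_p"` keeps the lowest-p row per variant.
#' @return A data frame of records in file order, with attributes
#'   `n_input`, `n_dropped` and `drop_log` (reasons per dropped row).
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               duplicates = c("error", "keep_lowest_p")) {
  duplicates <- match.arg(duplicates)
  tm_assert(file.exists(path), "io", sprintf("file not found: %s", path))
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, data.table = FALSE,
                      showProgress = FALSE),
    error = function(e) tm_error("empty_input",
                                 sprintf("cannot read '%s': %s",
                                         path, conditionMessage(e))))
  if (nrow(dt) == 0L) tm_error("empty_input", sprintf("no rows in '%s'", path))

  found <- resolve_columns(names(dt), column_map)
  missing <- setdiff(SS_MANDATORY, names(found))
  if (length(missing)) {
    tm_error("schema",
             sprintf("mandatory column(s) not resolvable via column_map: %s",
                     paste(missing, collapse = ", ")),
             columns = missing)
  }

  rec <- data.frame(variant_id = as.character(dt[[found["variant_id"]]]),
                    stringsAsFactors = FALSE)
  rec$chrom <- if ("chrom" %in% names(found))
    as.character(dt[[found["chrom"]]]) else NA_character_
  rec$pos <- if ("pos" %in% names(found))
    as.integer(dt[[found["pos"]]]) else NA_integer_
  rec$effect_allele <- toupper(as.character(dt[[found["effect_allele"]]]))
  rec$other_allele <- toupper(as.character(dt[[found["other_allele"]]]))
  rec$eaf <- if ("eaf" %in% names(found))
    as.numeric(dt[[found["eaf"]]]) else NA_real_
  rec$beta <- as.numeric(dt[[found["beta"]]])
  rec$se <- as.numeric(dt[[found["se"]]])
  rec$pvalue <- as.numeric(dt[[found["pvalue"]]])
  rec$n <- if ("n" %in% names(found)) as.numeric(dt[[found["n"]]]) else NA_real_
  rec$n_cases <- if ("n_cases" %in% names(found))
    as.numeric(dt[[found["n_cases"]]]) else NA_real_

  reason <- rep(NA_character_, nrow(rec))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  allele_ok <- grepl("^[ACGT]+$", rec$effect_allele) &
    grepl("^[ACGT]+$", rec$other_allele)
  bad(!nzchar(rec$variant_id) | is.na(rec$variant_id), "missing variant_id")
  bad(!allele_ok, "non-ACGT allele")
  bad(rec$effect_allele == rec$other_allele, "identical alleles")
  bad(!is.finite(rec$beta), "non-finite beta")
  bad(!is.finite(rec$se) | rec$se <= 0, "se not > 0")
  bad(!is.finite(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1,
      "pvalue outside (0,1]")
  bad(!is.na(rec$pos) & rec$pos < 1, "pos < 1")
  bad(!is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1), "eaf outside (0,1)")
  bad(!is.na(rec$n) & rec$n <= 0, "n not > 0")

  keep <- is.na(reason)
  drop_log <- data.frame(row = which(!keep),
                         variant_id = rec$variant_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- rec[keep, , drop = FALSE]

  if (anyDuplicated(out$variant_id)) {
    if (duplicates == "error") {
      dup <- unique(out$variant_id[duplicated(out$variant_id)])
      tm_error("duplicate_variant",
               sprintf("duplicated variant_id(s): %s%s",
                       paste(head(dup, 5), collapse = ", "),
                       if (length(dup) > 5) ", ..." else ""),
               variants = dup)
    }
    # keep-lowest-p: stable — retain original order of the surviving rows
    best <- tapply(seq_len(nrow(out)), out$variant_id,
                   function(i) i[which.min(out$pvalue[i])])
    out <- out[sort(unlist(best, use.names = FALSE)), , drop = FALSE]
  }

  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(dt)
  attr(out, "n_dropped") <- nrow(drop_log)
  attr(out, "drop_log") <- drop_log
  out
}

#' GRCh37 windows of the nine lipid drug-target genes
#'
#' Ensembl GRCh37 coordinates (1-based inclusive) of the genes encoding the
#' protein targets of the major LDL-C- and triglyceride-lowering drug
#' classes, with the lipid trait each target is instrumented through:
#' LDL-C for LDLR, HMGCR, PCSK9, NPC1L1, APOB and CETP; triglycerides for
#' LPL, ANGPTL3 and APOC3.
#'
#' @param flank_bp Flank in base pairs stored on each region (applied lazily
#'   by [select_cis_instruments()]); default 100000.
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`,
#'   `exposure_trait`, `flank_bp`.
#' @export
lipid_target_regions <- function(flank_bp = 100000L) {
  out <- data.frame(
    gene  = c("LDLR", "HMGCR", "PCSK9", "NPC1L1", "APOB", "CETP",
              "LPL", "ANGPTL3", "APOC3"),
    chrom = c("19", "5", "1", "7", "2", "16", "8", "1", "11"),
    start = c(11200038L, 74632154L, 55505221L, 44552134L, 21224301L,
              56995762L, 19759228L, 63063158L, 116700422L),
    end   = c(11244492L, 74657929L, 55530525L, 44580914L, 21266945L,
              57017757L, 19824769L, 63071830L, 116703788L),
    exposure_trait = c("LDL_C", "LDL_C", "LDL_C", "LDL_C", "LDL_C", "LDL_C",
                       "TG", "TG", "TG"),
    stringsAsFactors = FALSE)
  out$flank_bp <- as.integer(flank_bp)
  out
}

KNOWN_TRAITS <- c("LDL_C", "TG")

#' Read gene regions from a BED-like table
#'
#' Expects 4+ whitespace/tab-separated columns `chrom start end gene
#' [exposure_trait]` in BED convention (0-based half-open), converted to
#' 1-based inclusive coordinates. A row with `start == end` is accepted as
#' the single base `start + 1`. When the trait column is absent, known lipid
#' target genes get their conventional trait (see [lipid_target_regions()]);
#' other genes default to `LDL_C`.
#'
#' @param path Path to the BED-like file (no header).
#' @param flank_bp Flank stored on every region; default 100000.
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`,
#'   `exposure_trait`, `flank_bp` (1-based inclusive coordinates).
#' @export
read_gene_regions <- function(path, flank_bp = 100000L) {
  tm_assert(file.exists(path), "io", sprintf("file not found: %s", path))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, data.table = FALSE,
                      showProgress = FALSE),
    error = function(e) tm_error("empty_input",
                                 sprintf("cannot read '%s'", path)))
  if (nrow(dt) == 0L) tm_error("empty_input", sprintf("no rows in '%s'", path))
  tm_assert(ncol(dt) >= 4L, "schema",
            "gene-region file needs >= 4 columns: chrom start end gene")

  chrom <- as.character(dt[[1]])
  start0 <- as.numeric(dt[[2]])
  end0 <- as.numeric(dt[[3]])
  gene <- as.character(dt[[4]])

  if (any(start0 > end0)) {
    tm_error("coordinate",
             sprintf("start > end for gene(s): %s",
                     paste(gene[start0 > end0], collapse = ", ")))
  }
  if (anyDuplicated(gene)) {
    tm_error("duplicate_gene",
             sprintf("duplicate gene(s): %s",
                     paste(unique(gene[duplicated(gene)]), collapse = ", ")))
  }

  start1 <- as.integer(start0 + 1)
  end1 <- as.integer(pmax(end0, start0 + 1))

  if (ncol(dt) >= 5L && !all(is.na(dt[[5]]))) {
    trait <- toupper(as.character(dt[[5]]))
    trait <- sub("^LDL-?C$", "LDL_C", trait)
    unknown <- setdiff(unique(trait), KNOWN_TRAITS)
    if (length(unknown)) {
      tm_error("schema",
               sprintf("unknown exposure_trait token(s): %s",
                       paste(unknown, collapse = ", ")))
    }
  } else {
    builtin <- lipid_target_regions()
    trait <- builtin$exposure_trait[match(gene, builtin$gene)]
    trait[is.na(trait)] <- "LDL_C"
  }

  data.frame(gene = gene, chrom = chrom, start = start1, end = end1,
             exposure_trait = trait, flank_bp = as.integer(flank_bp),
             stringsAsFactors = FALSE)
}

#' Read a SNP-by-SNP LD r-squared matrix
#'
#' Expects a square numeric matrix in TSV form with variant identifiers both
#' as a header row and as the first column. Mild asymmetry (<= 1e-6) is
#' symmetrized as (M + t(M))/2; the diagonal is forced to 1; values must lie
#' in \[0, 1\] up to 1e-9 rounding.
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix of r-squared values with variant ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  tm_assert(file.exists(path), "io", sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  tm_assert(nrow(m) == ncol(m), "matrix", "LD matrix is not square")
  tm_assert(identical(ids, colnames(m)), "matrix",
            "LD row and column variant ids differ")
  dimnames(m) <- list(ids, ids)
  validate_ld_matrix(m)
}

# Shared validation for LD matrices built in memory or read from disk.
validate_ld_matrix <- function(m) {
  tm_assert(is.matrix(m) && nrow(m) == ncol(m), "matrix",
            "LD matrix is not square")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6) {
    tm_error("matrix", sprintf("LD matrix asymmetry %.3g exceeds 1e-6", asym))
  }
  m <- (m + t(m)) / 2
  if (any(m < -1e-9) || any(m > 1 + 1e-9)) {
    tm_error("range", "LD r-squared values outside [0, 1]")
  }
  m[m < 0] <- 0
  m[m > 1] <- 1
  diag(m) <- 1
  m
}

RESULT_COLUMNS <- c("target_gene", "outcome", "method", "nsnp", "beta", "se",
                    "ci_low", "ci_high", "or_value", "or_ci_low", "or_ci_high",
                    "pvalue", "qvalue", "Q", "Q_p", "egger_intercept",
                    "egger_intercept_p", "mean_F", "power")

#' Write the MR results table
#'
#' Writes a TSV with the fixed column order `target_gene, outcome, method,
#' nsnp, beta, se, ci_low, ci_high, or_value, or_ci_low, or_ci_high, pvalue,
#' qvalue, Q, Q_p, egger_intercept, egger_intercept_p, mean_F, power`.
#' Numerics are printed with 15 significant digits so a write/read round trip
#' is lossless well beyond 12 significant digits. Missing columns are filled
#' with NA.
#'
#' @param results Non-empty data frame of estimate/diagnostic rows.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_results <- function(results, path) {
  tm_assert(is.data.frame(results) && nrow(results) > 0, "empty_input",
            "results table is empty")
  for (col in setdiff(RESULT_COLUMNS, names(results))) results[[col]] <- NA
  out <- results[, RESULT_COLUMNS, drop = FALSE]
  fmt <- out
  for (col in names(fmt)) {
    if (is.numeric(fmt[[col]])) {
      fmt[[col]] <- ifelse(is.na(fmt[[col]]), "NA",
                           sprintf("%.15g", fmt[[col]]))
    }
  }
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return Data frame with the standard result columns.
#' @export
read_results <- function(path) {
  tm_assert(file.exists(path), "io", sprintf("file not found: %s", path))
  data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                    na.strings = "NA", showProgress = FALSE)
}
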