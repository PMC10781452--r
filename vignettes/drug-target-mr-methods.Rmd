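---
title: "Methods: drug-target Mendelian randomization in targetmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target Mendelian randomization in targetmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

# The scientific problem

Drug-target Mendelian randomization (MR) asks whether lowering a lipid
exposure *through a particular gene product* — the way a drug would —
changes downstream outcomes. Genetic variants inside or near the gene
encoding the drug target (cis-variants) that alter the exposure act as
lifelong, randomized "natural experiments": because alleles are assigned at
meiosis, their downstream associations are protected from the confounding
and reverse causation that plague observational pharmaco-epidemiology.

`targetmr` implements the full two-sample summary-statistics workflow:
instruments are chosen from an exposure GWAS (e.g. LDL cholesterol or
triglycerides), their outcome associations are looked up in an independent
outcome GWAS, and per-variant effect ratios are combined into a causal
estimate per (target gene, outcome) cell of an analysis grid.

# Model and assumptions

For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its exposure
association and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its outcome
association, estimated in non-overlapping samples. Under the instrumental
variable assumptions (association with the exposure; no association with
confounders; no effect on the outcome except through the exposure), each
valid variant identifies the causal effect $\beta$ through the Wald ratio

$$\hat r_j = \hat\beta_{Yj} / \hat\beta_{Xj}, \qquad
  \mathrm{se}(\hat r_j) \approx \sigma_{Yj}/|\hat\beta_{Xj}|,$$

the usual first-order approximation that ignores the (relatively small)
uncertainty in $\hat\beta_{Xj}$ for genome-wide significant instruments.
The package's estimators differ in how they pool the $\hat r_j$ and in
which assumption violations they tolerate:

* **IVW** (`mr_ivw()`): inverse-variance weighted mean of the ratios;
  exactly zero-intercept weighted least squares of $\hat\beta_Y$ on
  $\hat\beta_X$ with weights $1/\sigma_Y^2$. The default `"auto"` effects
  model uses the fixed-effect SE unless Cochran's Q is significant
  (p < 0.05), in which case the SE is inflated by the multiplicative
  random-effects factor $\max(1, \sqrt{Q/(k-2)})$. With a single
  instrument IVW degenerates to the Wald ratio.
* **MR-Egger** (`mr_egger()`): the same weighted regression with a free
  intercept, each variant oriented so $\hat\beta_X \ge 0$. The intercept
  estimates directional pleiotropy; the slope remains consistent under the
  InSIDE assumption. Inference uses a t distribution with $k-2$ df and a
  multiplicative overdispersion scale.
* **Weighted median** (`mr_weighted_median()`): the ratio at cumulative
  weight 1/2 (linear interpolation); consistent when valid instruments
  carry more than half the weight. SE by parametric bootstrap of the
  ratios.
* **Weighted mode** (`mr_weighted_mode()`): argmax of a weighted Gaussian
  kernel density of the ratios; consistent when the largest
  homogeneous-ratio cluster is valid (ZEMPA). Bandwidth is
  $\phi \cdot 0.9 \min(\mathrm{sd}, 1.4826\,\mathrm{mad})\, k^{-1/5}$.
* **Maximum likelihood** (`mr_max_likelihood()`): joint Gaussian likelihood
  $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
  $\hat\beta_{Yj} \sim N(\beta\gamma_j, \sigma_{Yj}^2)$, profiled by
  alternating exact coordinate updates; unlike IVW it models the exposure
  measurement error. SE from the observed information (Schur complement of
  the $\beta$ block).

Diagnostics follow the field's standard battery: Cochran's Q for
heterogeneity (`cochran_q()`), the Egger intercept test
(`egger_intercept_test()`), leave-one-out influence (`leave_one_out()`),
per-SNP and overall F statistics with the $F = R^2(n-1-k)/((1-R^2)k)$
convention and a weak-instrument flag at $F \le 10$
(`compute_f_statistics()`), and analytic power from the non-centrality
$\lambda = |\beta|\sqrt{nR^2}$ (times $\sqrt{K(1-K)}$ for binary outcomes)
(`mr_power()`).

# Instrument processing choices

* **Cis-window**: instruments must fall within a ±100 kb flank of the gene
  body and pass $p \le 5\times 10^{-8}$.
* **Clumping**: greedy, lowest-p-first with deterministic (position, id)
  tie-breaks, discarding SNPs with $r^2 \ge 0.3$ within 100 kb of a kept
  SNP. The greedy order is the field convention; the test suite pins it to
  an independent brute-force restart-scan reference. Missing LD entries
  default to $r^2 = 1$ (conservative: forces discard) with a warning;
  `missing_ld_r2 = 0` opts out.
* **Harmonization**: allele swaps negate the outcome beta; strand
  complements are resolved; palindromic (A/T, G/C) SNPs are dropped by
  default, with an opt-in `infer_by_eaf` policy that treats allele
  frequencies in the ambiguous band (0.42, 0.58) as unresolvable.
  Harmonization is idempotent and invariant to allele-label flips.
* **Steiger filtering**: per-SNP variance explained is approximated by
  $r^2 = t^2/(t^2 + n - 2)$; a SNP is removed when it explains at least as
  much outcome as exposure variance (`direction_only`, the default) or
  additionally only when the z-test on the Fisher-transformed correlations
  is significant (`significant` mode). The t-statistic form is used
  because allele frequency columns are often missing from source files;
  an eaf-based $r^2$ is available as an option.
* **Reporting convention**: estimates are reported per 1 unit *lower*
  exposure — the lipid-lowering, drug-mimicking direction — by negating
  the per-unit-increase regression estimate and its interval
  (`lower_exposure = TRUE`); `scale_factor` supports SD-to-mmol/L
  rescaling. Binary outcomes additionally report $\mathrm{OR} =
  e^{\hat\beta}$.

Genes whose surviving instrument count falls below `min_snps` (default 3)
are reported in a skip table rather than failing the run, mirroring how
underpowered targets are excluded from drug-target MR studies; a run in
which *no* cell survives is a hard error with per-gene reasons.
Multiplicity is controlled by Benjamini–Hochberg FDR over the primary
(IVW) p-values, by default within each outcome category (longevity,
cardiometabolic, cancer, positive control), since those panels answer
distinct scientific questions; `fdr_scope = "global"` pools them.

# The synthetic-data generator

Because real drug-target MR inputs are multi-gigabyte GWAS files, every
statistical claim in this package is validated against
`simulate_mr_study()`, a generator for paired exposure/outcome summary
statistics with known ground truth:

* MAF $\sim U(0.05, 0.5)$; standard errors use the standardized-trait
  approximation $1/\sqrt{2n\,\mathrm{MAF}(1-\mathrm{MAF})}$, divided by
  $\sqrt{K(1-K)}$ on the log-odds scale for binary outcomes.
* True effects $\gamma_j$ are half-normal ($|N(0, 0.02^2)|$, truncated at
  0.005) and then the whole vector is multiplied by one common factor so
  the smallest expected exposure z statistic is 6. The common rescale is a
  deliberate design point: it guarantees every instrument is genome-wide
  discoverable (noise-free $p \le 5\times10^{-8}$; ~98% of instruments
  pass in noisy draws, so winner's-curse truncation is negligible) while
  preserving the relative spread of instrument strengths. A per-SNP floor
  would satisfy the same discoverability bound but pile most effects onto
  the floor, and the resulting low between-instrument variance induces
  marked regression-dilution bias in the MR-Egger slope — an artifact of
  the generator, not of the estimator.
* Realized effects are $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$
  and $\hat\beta_{Yj} \sim N(\beta\gamma_j + \alpha_j, \sigma_{Yj}^2)$
  with *independent* noise streams for the two panels (two-sample design).
* Assumption violations are explicit knobs: horizontal pleiotropy
  $\alpha_j \sim N(\mu, 0.01^2)$ on the $\lceil 0.3k \rceil$ lowest-index
  SNPs ($\mu = 0$ balanced, $\mu = 0.05$ directional), and `n_reverse`
  reverse-causal SNPs whose large direct outcome effect leaks weakly back
  into the exposure ($\beta_{\mathrm{rev}} = 0.05$).
* LD is AR(1), $r^2(i,j) = \rho^{2|i-j|}$, with SNPs 1 kb apart, so
  clumping behaviour is analytically predictable.
* Defaults ($k = 20$, $\beta = 0.1$, $n_{\mathrm{exp}} = 170{,}000$,
  $n_{\mathrm{out}} = 300{,}000$) match the scale of contemporary lipid
  and disease GWAS.

`simulate_mr_grid()` builds a target-by-outcome grid with per-cell seeds
derived deterministically from the master seed, and
`write_simulated_study()` serializes a study in exactly the formats the
readers accept, so the entire pipeline can be exercised end to end from
files.

```{r example, eval = FALSE}
sim <- simulate_mr_study(sim_config(seed = 1))
cfg <- analysis_config(
  exposures = list(LDL_C = sim$exposure),
  outcomes = list(lifespan = list(stats = sim$outcome,
                                  type = "continuous",
                                  category = "longevity")),
  gene_regions = sim$region, ld = sim$ld, seed = 1)
res <- run_analysis(cfg)
res$results[, c("target_gene", "outcome", "method", "beta", "se",
                "pvalue", "qvalue")]
```

# Numerical design choices

* **Maximum likelihood convergence**: the alternating coordinate updates
  stop when the gradient norm falls below `tol = 1e-8` *or* when an
  iteration changes the parameters by less than 1e-14 in relative terms.
  The second exit matters in the near-exact-exposure limit
  ($\sigma_X \to 0$), where the gradient component $(\hat\beta_X -
  \gamma)/\sigma_X^2$ amplifies machine rounding so the absolute gradient
  tolerance is unattainable even at the fixpoint.
* **Bootstrap sign canonicalization**: the parametric bootstrap behind the
  median/mode SEs first orients the ratio vector to a canonical overall
  sign before drawing. This makes the reported SE exactly invariant under
  negation of the outcome (a symmetry the point estimates obey), instead
  of only approximately so.
* **Mode search**: the kernel density is maximized over an exact 512-point
  grid spanning $[\min r - 3h, \max r + 3h]$, ties broken toward the
  lowest grid index; tests pin the argmax to a 50,001-point brute-force
  grid within one coarse step. When `sd` or `mad` of the ratios is zero,
  the zero component is dropped from the bandwidth rule (and a degenerate
  set returns the common ratio directly).
* **Established numerics are reused, not reimplemented**: file IO via
  `data.table::fread`, BH adjustment via `stats::p.adjust` (pinned in
  tests to the literal step-up formula), and the DerSimonian–Laird
  meta-analysis cross-checked against `metafor` where available.
* **Determinism**: every stochastic step takes an explicit seed;
  `run_analysis()` derives and logs one seed per grid cell from the master
  seed, and all seed derivation stays below $2^{31}$. Seeded runs are
  byte-identical when re-serialized.

# Validation strategy, and what it does not show

The test suite validates three kinds of claims: exact oracles (closed-form
identities, independent reference implementations, refined-grid argmax),
distributional calibration (type-I error of IVW and the Egger intercept,
null distribution of Q, CI coverage, FDR control on an all-null 9×5 grid),
and robustness orderings (weighted median less biased than IVW under 30%
directional pleiotropy; Steiger removal of planted reverse-causal
variants). Typical problem sizes are modest by design — tens of SNPs per
gene, grids of ~10 targets × ~20 outcomes — so every property runs in
seconds to a few minutes on one core.

Passing these checks shows the *implementation* is faithful to the stated
model; it does not validate the substantive MR assumptions in real data.
In particular: residual LD below the clumping threshold ($r^2 < 0.3$) is
not modeled by the independence-assuming estimators; the generator's
Gaussian summary-statistic model ignores winner's curse, sample overlap
and population stratification; the standardized-trait SE approximation
sidesteps phenotype-variance bookkeeping; and cis-instruments for one
lipid trait can act through correlated lipid fractions (horizontal
pleiotropy that Steiger filtering and the Egger intercept only partially
probe). Conclusions about real drug targets additionally rest on the
quality and ancestry-match of the underlying GWAS.
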