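---
title: "Methods: two-sample MR, two-step mediation, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, two-step mediation, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Two-sample Mendelian randomization treats a set of SNPs as instrumental
variables for an exposure. For SNP $j$ we observe, from independent GWAS,
the exposure association $\hat\gamma_j$ with standard error
$\sigma_{\gamma j}$ and the outcome association $\hat\Gamma_j$ with
$\sigma_{\Gamma j}$. Under the instrumental-variable assumptions (relevance,
independence from confounders, and effect on the outcome only through the
exposure), each Wald ratio $\hat\Gamma_j/\hat\gamma_j$ estimates the same
causal effect $\beta$, and the estimators in `mr_fit()` are different ways
of pooling the ratios that trade efficiency against robustness to violations
of the third assumption (horizontal pleiotropy):

* **IVW** pools with weights $w_j = \hat\gamma_j^2/\sigma_{\Gamma j}^2$
  (equivalently weighted regression of $\hat\Gamma$ on $\hat\gamma$ through
  the origin). It is efficient but biased by any net pleiotropy.
* **MR-Egger** frees the intercept; under the InSIDE assumption
  (pleiotropic effects independent of instrument strengths) the slope is a
  pleiotropy-adjusted estimate and the intercept estimates the mean
  directional pleiotropic effect.
* **Weighted median** is consistent while instruments carrying at least
  half of the total weight are valid.
* **MR-PRESSO** and **radial MR** identify individual outlying instruments
  (gross violators) and re-estimate without them.

Two-step mediation composes three such analyses: the total effect $c$
(exposure→outcome), step 1 $a$ (exposure→mediator, with the exposure's
instruments), and step 2 $b$ (mediator→outcome, with the mediator's own
instruments). The indirect effect is the product $ab$, its standard error is
the Aroian form
$\sqrt{b^2\sigma_a^2 + a^2\sigma_b^2 + \sigma_a^2\sigma_b^2}$ (the Sobel SE
plus the second-order term, hence always at least as large), and the
mediated proportion is $ab/c$. Step 2 is univariable — the mediator's
instruments are not adjusted for the exposure — which is the standard
two-step design and a known limitation: it assumes the mediator's
instruments do not act on the outcome through the exposure.

# Instrument selection and its thresholds

`select_instruments()` applies, in order: exposure significance filter,
LD clumping, outcome-association exclusion, harmonization, F filter, and
radial pruning. All thresholds sit in `selection_config()` and all
inequalities are strict:

| parameter | default | meaning |
|---|---|---|
| `p_exposure` | 5e-8 | genome-wide significance for instruments |
| `clump_r2` | 0.01 | LD r² above which the weaker SNP is clumped away |
| `clump_window_kb` | 10 | distance fallback when r² is unavailable |
| `p_outcome_exclude` | 5e-8 | direct outcome association that disqualifies a SNP |
| `f_min` | 10 | minimum F = (β/SE)²; F exactly 10 is kept |
| `palindromic_maf_limit` | 0.42 | MAF above which allele frequency cannot resolve strand |

Choices that the conventions leave open, decided here once:

* **Palindromic SNPs** (A/T, C/G) cannot be strand-resolved from alleles.
  When both datasets report allele frequencies and both minor-allele
  frequencies are below 0.42, the orientation minimising
  $|\mathrm{EAF}_{exp} - \mathrm{EAF}_{out}|$ is used; otherwise the SNP is
  dropped. This is the common practice default; the 0.42 limit keeps
  frequencies informative about strand.
* **SNPs missing from the outcome table** pass the outcome-association
  exclusion (absence of evidence is not evidence of association) and are
  dropped later at harmonization, where outcome statistics are required.
* **Clumping ties** on equal p-values break lexicographically by SNP id,
  for reproducibility.
* **Stage order** places radial pruning last, per exposure–outcome pair,
  after the set is harmonized and strength-filtered; `max_iter` makes the
  batch-removal loop either single-pass or iterated-to-convergence.

# Numerical conventions in the estimators

* Wald-ratio SEs use the first-order delta method
  $\sigma_{\Gamma j}/|\hat\gamma_j|$, the summary-data standard; the
  second-order form is available (`wald_ratios(second_order = TRUE)`).
  Instruments with $\hat\gamma_j = 0$ have no defined ratio and are skipped
  with a warning.
* IVW defaults to **multiplicative random effects**: the fixed-effect SE is
  inflated by $\sqrt{\max(1, Q/(n-1))}$, so heterogeneity can widen but
  never narrow the interval. P-values are two-sided normal.
* MR-Egger first orients all instruments to positive $\hat\gamma$ (jointly
  negating both coordinates, which leaves every estimate invariant), fits
  weighted least squares with weights $1/\sigma_{\Gamma j}^2$, inflates SEs
  by $\sqrt{\max(1, Q_E/(n-2))}$, and uses t inference on $n-2$ df —
  material because published instrument sets can be as small as 4 SNPs.
* The weighted median interpolates the sorted ratios at cumulative
  standardized weight 0.5; its SE comes from a parametric bootstrap
  (default 1000 draws) resampling $(\hat\gamma_j, \hat\Gamma_j)$ from
  normal distributions at their observed values and SEs. A seed is
  mandatory, so results are exactly reproducible.
* MR-PRESSO simulates its null from leave-one-out predictions. The global
  test p uses the add-one convention $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$
  and so is never zero. The per-SNP outlier test uses the plain empirical
  proportion: with the add-one floor, 1000 simulations and 50 SNPs, an
  unambiguous outlier's Bonferroni-adjusted p would sit exactly at the 0.05
  boundary as an artifact of the convention rather than the data. Residuals
  are weighted by $1/\sigma_{\Gamma j}^2$, the consistent weight for
  outcome-scale residuals. The distortion null re-estimates after removing
  1000 random subsets of the same size as the outlier set. Note that the
  outlier test's resolution is $1/n_{sim}$: with few simulations the
  Bonferroni threshold $0.05/n$ drops below the achievable minimum and
  specificity degrades, which is why `n_sim` defaults to 1000.
* `pvalue_from_ci()` back-calculates $SE = (CI_{hi} - CI_{lo})/(2 \cdot 1.96)$
  and is intended for auditing published tables that print estimates with
  CIs but no SEs. Published mediated proportions do not always back-compute
  exactly from their rounded columns; full-precision internal propagation is
  treated as correct and comparisons are made within the rounding of the
  printed inputs.

# What the simulator emulates

`simulate_mediation_gwas()` draws per-SNP true effects
$\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$ for the exposure panel and
$\delta_k$ for a disjoint mediator panel, then builds the three summary
tables under the structural model: mediator associations $a\gamma_j$ (and
$\delta_k$), outcome associations $(c' + ab)\gamma_j + \alpha_j$ (and
$b\delta_k$), with sampling noise at
$SE = 1/\sqrt{2p(1-p)N}$ — the standardized-trait approximation, which gives
realistic instrument F statistics at biobank-scale $N$. Horizontal
pleiotropy $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ is applied in the
exposure-increasing-allele frame (it carries the sign of $\gamma_j$);
otherwise MR-Egger's orientation step would cancel any fixed mean shift and
directional pleiotropy would be unrecoverable by construction. Planted
outliers receive a fixed pleiotropic shift and are planted among strong,
non-palindromic instruments, because an outlier that never enters the
analyzed set cannot test outlier detection. Allele representations in the
mediator and outcome tables are randomly swapped (30%) or
strand-complemented (20%), and a configurable fraction of SNPs is
palindromic, so harmonization does real work on every simulated dataset.

**Default conditions.** The defaults are the package's study conditions:
50 exposure and 30 mediator instruments, $N = 200{,}000$ for all three GWAS,
`gamma_sd = 0.1` (mean F ≈ 800, strong-instrument regime), and
$a = b = c' = 0.05$, giving a total effect $c = 0.0525$ and a mediated
proportion of ≈4.8%, within the 1–12% range typical of cytokine-mediated
lifestyle effects on RA. The effect sizes are deliberately modest: with
strong instruments, larger structural effects would push instruments past
genome-wide significance on the *non-index* traits, and the pipeline's own
outcome-association exclusion would then truncate the panels — the
real-data regime is precisely the opposite (lifestyle SNPs do not reach
5×10⁻⁸ in cytokine or RA GWAS).

**What it does not emulate.** Estimates are drawn independently across SNPs
— the LD table declares within-block r² for clumping, but the noise is
uncorrelated; there is no individual-level genotype layer, no winner's
curse beyond what selection induces, no correlated (InSIDE-violating)
pleiotropy, no sample overlap between the three GWAS, and binary outcomes
are emulated directly on the log-odds scale rather than via a liability
model. Passing validation on this generator therefore demonstrates the
correctness and calibration of the inference machinery under its stated
assumptions, not robustness to the full messiness of real GWAS data.

# Validation design

The test suite validates three things, at sizes chosen to keep the full run
in tens of seconds:

* **Exact oracles**: IVW against `lm()` weighted regression through the
  origin, the weighted median against an explicit breakpoint walk, the
  screen ordering against all-pairs brute force, clumping against an
  independent greedy re-implementation, and the published-table arithmetic
  (odds ratios, mediated proportions, CI-derived p-values, pathway counts).
* **Calibration**: parameter recovery for $c$, $a$, $b$ and the mediated
  proportion within two Monte-Carlo SEs over 200 replicates; IVW CI
  coverage within [92%, 98%]; Egger intercept recovery over a
  $\mu_\alpha \in \{0, 0.02, 0.05\}$ grid and ≈5% rejection under balanced
  pleiotropy.
* **Robustness**: detection of planted outliers by PRESSO and radial
  filtering, with bias reduction of the corrected estimate, in ≥90% of
  replicates.

Two experiment-design points deserve explanation. First, the
recovery/coverage experiments run the selection cascade **without radial
pruning**: under a clean null, per-SNP deletion at $\alpha = 0.05$ removes
the most extreme valid instruments, deflates the empirical heterogeneity,
and mildly under-covers — the experiment isolates estimator calibration,
while radial behaviour is tested in the dedicated robustness experiment.
Second, the pleiotropy experiments (planted outliers, Egger calibration)
harmonize **without the outcome-association exclusion**: pleiotropy of any
useful magnitude makes instruments genome-wide significant on the outcome at
these sample sizes, so the exclusion filter would silently delete the very
signal under study. Both toggles are plain arguments
(`select_instruments(radial =)`, or composing the stage functions directly),
not special test hooks.

# Known limitations

* No Steiger directionality filtering, proxy-SNP lookup, multivariable MR,
  or network mediation decomposition.
* The mediated-proportion CI is not propagated (only the indirect effect
  carries an interval), matching the product-of-coefficients reporting
  convention.
* No multiple-testing adjustment across pathways by default;
  `pathway_table()` takes the per-pathway α and reports counts, leaving
  family-wise policy to the analyst.
* The fingerprint screen is intentionally fingerprint-agnostic; the bundled
  SMILES convenience path uses the OpenBabel FP2 path fingerprint
  (1024 bits) and molecular identity of ranking across fingerprint types is
  not guaranteed.
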