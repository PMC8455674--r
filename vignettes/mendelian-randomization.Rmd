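---
title: "Two-sample Mendelian randomization with mrkit: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

# The causal model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for an exposure. A variant $j$ is a valid instrument when it is
(a) associated with the exposure (*relevance*), (b) unrelated to
confounders of the exposure–outcome relationship (*independence*), and
(c) affects the outcome only through the exposure
(*exclusion restriction*). In the two-sample design the variant–exposure
associations $\hat\gamma_j$ (SE $\sigma_{Xj}$) and variant–outcome
associations $\hat\Gamma_j$ (SE $\sigma_{Yj}$) come from two independent
GWAS, so their sampling errors are uncorrelated. For binary traits both
sides are on the log odds-ratio scale and causal estimates are reported as
odds ratios per unit log-odds of the exposure; for continuous traits they
are mean differences.

Under the model $\Gamma_j = \beta\,\gamma_j + \alpha_j$, where $\beta$ is
the causal effect and $\alpha_j$ a direct (horizontally pleiotropic)
effect, the per-variant Wald ratio $\hat\beta_j =
\hat\Gamma_j/\hat\gamma_j$ estimates $\beta$ when $\alpha_j = 0$. The
package's estimators differ in what they assume about the $\alpha_j$:

* **IVW with multiplicative random effects** (the primary estimator)
  assumes balanced pleiotropy, $E[\alpha_j] = 0$. It is the weighted
  regression of $\hat\Gamma_j$ on $\hat\gamma_j$ through the origin with
  weights $\sigma_{Yj}^{-2}$:
  $\hat\beta = \sum_j \hat\gamma_j\hat\Gamma_j\sigma_{Yj}^{-2} \big/
  \sum_j \hat\gamma_j^2\sigma_{Yj}^{-2}$. Heterogeneity is summarised by
  Cochran's $Q = \sum_j w_j(\hat\beta_j - \hat\beta)^2$ with first-order
  weights $w_j = \hat\gamma_j^2/\sigma_{Yj}^2$, referred to
  $\chi^2_{J-1}$. The multiplicative random-effects variance scales the
  fixed-effect variance by $\hat\phi^2 = Q/(J-1)$, floored at 1 so the
  standard error never drops below the fixed-effect one. Confidence
  intervals and p-values use normal quantiles.
* **Weighted median** is consistent when at least half of the weight
  comes from valid instruments. The ordered Wald ratios are interpolated
  at cumulative-weight midpoint 0.5 with the same first-order weights; its
  standard error comes from a seeded parametric bootstrap that redraws
  $\hat\gamma_j^*$ and $\hat\Gamma_j^*$ from normals centred at the
  observed values.
* **MR-Egger** allows all instruments to be pleiotropic provided the
  InSIDE condition holds (pleiotropy uncorrelated with instrument
  strength). Each variant is oriented so $\hat\gamma_j \ge 0$ and
  $\hat\Gamma_j$ is regressed on $\hat\gamma_j$ with a free intercept and
  weights $\sigma_{Yj}^{-2}$; the slope estimates $\beta$, the intercept
  the average directional pleiotropy (intercept p < 0.05 flags its
  presence), with the same multiplicative overdispersion floor. The
  $I^2_{GX}$ statistic, $(Q_{GX} - (J-1))/Q_{GX}$ with
  $Q_{GX} = \sum_j (\hat\gamma_j - \bar\gamma_w)^2/\sigma_{Xj}^2$,
  quantifies relative measurement error in the exposure associations;
  values near 1 support the no-measurement-error (NOME) assumption that
  MR-Egger additionally needs. The raw value can be negative and is
  reported clipped at zero alongside the raw value.
* **MR-PRESSO** tests for pleiotropy through the residual sum of squares
  around leave-one-out IVW fits, locates per-variant outliers against a
  parametric simulated null, and re-estimates after removing them; a
  distortion test bootstraps the corrected-minus-raw difference under
  random reassignment of the outlier indices.

# Instrument processing

Variant-level rules, applied before any estimation: only biallelic
single-base variants (A/C/G/T, alleles distinct) with an rs-number
identifier are eligible. Instruments are variants below the significance
threshold (default $5\times10^{-8}$; $5\times10^{-6}$ is the conventional
relaxation for outcomes with few genome-wide hits), thinned by greedy LD
clumping: candidates are visited in ascending p-value order and kept only
if $r^2 < 0.001$ with everything already kept. Instruments absent from
the outcome GWAS may be replaced by a proxy with $r^2 \ge 0.8$, taking
the highest available $r^2$, ties broken by smaller outcome p-value then
lexicographic rsID. Proxy effect estimates are used as-is (no rescaling
by $r^2$), the convention in summary-data MR; the substitution is logged
so users can audit it.

Harmonization aligns every outcome effect onto the exposure's effect
allele: direct matches are kept, swapped labels negate the outcome beta
and complement its frequency, and strand-complement matches are resolved
the same way after complementing. Palindromic variants (A/T, C/G) carry
no strand information in their labels, so they are aligned by effect-allele
frequency; the concrete rule here — accept the label-based orientation
when both frequencies fall on the same side of 0.5, reverse it otherwise —
is one concretization of frequency alignment, standard in practice and
directly testable. Frequency alignment is only trusted when the
minor-allele frequency is at most 0.42; by default the gate is applied in
both samples (the conservative choice; `palindrome_maf_both = FALSE`
switches to exposure-only), and palindromes with a missing frequency in
either table are dropped because alignment is undefined without one.
Every input instrument appears exactly once in the audit trail with one
of: `kept`, `allele_flipped`, `proxy_substituted`, `dropped_palindrome`,
`dropped_missing`, `dropped_overlap` (the last from bi-directional
sensitivity re-runs).

Instrument strength is summarised by the mean per-variant approximate
F-statistic $(\hat\gamma_j/\sigma_{Xj})^2$; values above 10 conventionally
indicate low weak-instrument bias.

# Pipeline orchestration

`run_direction()` chains filter → select → clump → proxy → harmonize →
F-statistic → estimator battery (IVW, weighted median, MR-Egger,
MR-PRESSO), gating each estimator on its minimum instrument count
(1/3/3/4) and labelling any error with the stage that raised it.
`run_bidirectional()` runs both directions between two traits, flags
instruments identical to or in LD ($r^2 \ge 0.8$) with the reverse
direction's instruments, and re-runs a direction without them as a
sensitivity analysis. `confounder_screen()` applies the same battery to
candidate confounder traits (mean differences for continuous traits,
odds ratios for binary) to probe the independence assumption. Family-wise
control uses the Bonferroni threshold `alpha / n_tests`; the default
family of 16 corresponds to eight traits tested in two directions, and the
tier of each result (`bonferroni` / `nominal` / `null`) is a pure function
of the IVW p-value and the two thresholds.

Power for a binary outcome uses the standard two-sample approximation:
the test statistic has noncentrality
$z = |\ln \mathrm{OR}|\sqrt{N\,R^2_{GX}\,K(1-K)}$ with $N$ the outcome
GWAS size, $R^2_{GX}$ the variance in exposure explained by the
instruments and $K$ the case fraction, and
$\mathrm{power} = \Phi(z - z_{1-\alpha/2})$. This is the upper-tail term
of the two-sided test, the form used by the standard MR power
calculators; at $\mathrm{OR} = 1$ it returns $\alpha/2$ (the size
contributed by that tail), and it makes the inversion exact:
`min_detectable_or()` solves it by monotone root finding and returns the
root at full precision (printing at 3 significant figures is a display
convention), so the forward/inverse round trip and the $\sqrt2$ scaling
of $\ln\mathrm{OR}$ with information hold to numerical tolerance.

# The synthetic-data generator

`simulate_mr()` emulates the statistical structure of consortium GWAS
summary statistics without any download: $J$ independent instruments with
true effects $\gamma_j$ drawn uniform on `gamma_range` (default 0.01–0.15
on the log-OR scale, typical of the spread of genome-wide hits for a
common binary trait), outcome effects
$\Gamma_j = \beta\gamma_j + \alpha_j$, and observations with independent
normal noise in the two samples. True exposure effects are drawn positive,
i.e. effect alleles are oriented to the exposure-increasing allele; this
keeps the directional-pleiotropy regimes well defined (a directional mean
is only meaningful relative to a fixed orientation) and costs no
generality because the estimators re-orient internally. Pleiotropy
regimes: `none`; `balanced` (zero-mean draws — by default zero in
expectation, since forcing the sample mean to exactly zero induces
negative cross-variant correlation that makes the IVW test conservative;
`center_pleiotropy = TRUE` gives the exactly-centred variant);
`directional` (nonzero mean, independent of $\gamma_j$, so InSIDE holds);
`inside_violating` (pleiotropy correlated with $\gamma_j$, correlation
0.7). Planted outliers assign a fixed pleiotropic effect to chosen
indices.

Allele plumbing: a configurable fraction of variants is palindromic, with
effect-allele frequencies uniform on 0.05–0.95 so the 0.42 MAF rule is
exercised on both sides; a fraction of outcome records is relabelled on
the opposite strand, and a fraction reports the opposite effect allele
(labels swapped, beta negated, frequency complemented) as real GWAS with
different conventions do. Omitted instruments get one in-LD proxy each
($r^2$ uniform on 0.8–1) carrying the same allele pair and frequency —
i.e. proxies are assumed phase-resolved, which sidesteps proxy-allele
phasing that the package does not model.

When `target_mean_f` is set, the generator draws a per-variant
noncentrality $\lambda_j = (\gamma_j/\sigma_{Xj})^2$ uniform with mean
`target_mean_f - 1` (using $E[(\hat\gamma/\sigma)^2] = \lambda + 1$) and
bounded below at 34 so that, as in a real post-selection instrument set,
every instrument is individually genome-wide significant while the mean F
hits the target. The `valid_110` preset uses this with $J = 110$ and a
target of 89.3 — the instrument-set size and strength regime of a large
atrial-fibrillation GWAS — and lands in the high-$I^2_{GX}$ (> 0.95)
regime typical of such sets.

What the generator does **not** emulate: genotype-level sampling, real LD
panels beyond the one-proxy block structure, population stratification,
sample overlap between the two GWAS, winner's-curse bias in the exposure
effects, and allele-frequency differences between populations. Passing
tests therefore validate the estimators and plumbing under the stated
model, not robustness to those artefacts.

# Validation design and problem sizes

The test suite validates each estimator against an independent oracle
(origin-constrained weighted least squares for IVW; a brute-force
weighted-quantile scan for the weighted median; the intercept-constrained
fit reproducing IVW for MR-Egger) and then checks the statistical
properties on simulated conditions: parameter recovery at $J = 100$,
$\beta = 0.2$ over 500 replicates; type-I error of the random-effects IVW
under balanced pleiotropy over 1000 replicates (the rejection rate must
sit in [0.03, 0.07]); Egger intercept recovery of a directional-pleiotropy
mean of 0.05 over 500 replicates; MR-PRESSO detection of 5 planted
outliers (pleiotropy 10 times $\sigma_Y$) among 50 instruments over 100
replicates with 1000 simulations each.

The estimator-validation presets deliberately use strong instruments
(`se_x = 0.003`, mean F near 900). MR-Egger's slope is attenuated by
roughly $(1 - I^2_{GX})\beta$ when NOME fails, and the weighted median
inherits a bias of order $\beta/F$ from noise in its ratio weights, so
unbiasedness can only be observed in a regime where those assumptions
hold; at mean F near 900 both distortions are an order of magnitude below
the Monte-Carlo resolution of the recovery checks. The separate
`valid_110` preset keeps the realistic strength (mean F 89.3) for the
instrument-strength and end-to-end checks, where those biases are part of
the phenomenon rather than a nuisance.

# Numerical choices

* Overdispersion is multiplicative and floored at 1 for IVW and Egger:
  standard errors never shrink below their fixed-effect values.
* All Monte-Carlo p-values (PRESSO global, per-variant, distortion) use
  the add-one rule $(1 + \#\{\cdot\})/(n_{\mathrm{sim}} + 1)$, bounding
  them below by $1/(n_{\mathrm{sim}}+1)$ and avoiding exact zeros;
  per-variant outlier p-values are Bonferroni-corrected across the $J$
  instruments (capped at 1) before the 0.05 flag.
* Every stochastic routine takes a mandatory seed and scopes it with
  `withr::with_seed`, so results are bit-reproducible and the caller's
  RNG state is untouched.
* A reported p-value of exactly 0 is floored to the smallest positive
  double with a warning; duplicate rsIDs within one GWAS keep the record
  with the smallest p-value (logged) — the file's internal conflict
  resolution is otherwise undefined.
* Degenerate inputs: a single instrument degrades IVW to the Wald ratio
  with a warning; zero spread in the exposure associations is a
  collinearity error for Egger; estimators below their minimum $J$ are
  reported as not applicable by the battery rather than failing the run.
* Normal (not t) reference distributions throughout, including Egger's
  intercept test, with the overdispersion floor; this matches the usual
  summary-data implementations and is documented rather than configurable.

# Known limitations

No Steiger direction filtering, multivariable MR, correlated-instrument
IVW, or mode-based estimators. Binary exposures are analysed per unit
log-odds of liability, the standard caveat for binary-exposure MR; no
rescaling is attempted. LDLink-style remote proxy lookup is replaced by a
local LD table. The power calculation is validated by internal
consistency (round trip and scaling), not against any published
per-outcome table, because the $R^2_{GX}$ and case fractions behind such
tables are study-specific inputs.
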