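---
title: "Methods: longitudinal methylation dynamics and the multi-organ pace of aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal methylation dynamics and the multi-organ pace of aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`methylpace` implements a longitudinal epigenome-wide analysis for ageing
cohorts measured over repeated waves: per-CpG classification into
*age-associated* and *age-varying* sites via nested random-slope linear
mixed models, extraction of per-subject methylation change rates from
random-slope BLUPs, construction of phenotype-specific and organ-system
composite pace-of-aging scores, covariate-adjusted partial correlation of
the two, and the downstream enrichment machinery (Fisher-exact set
enrichment, hypergeometric over-representation, and similarity-based
redundancy reduction of enriched terms). A synthetic cohort generator with
ground-truth tables supports power and calibration studies; individual-level
cohort data of this kind are typically access-restricted, so the generator
is a first-class, tested component rather than a test fixture.

# The two-model classification

For each CpG $j$ with beta-value $m_{ijt}$ for subject $i$ at visit $t$, two
nested models are fitted by maximum likelihood:

* **Model 1 (random intercept):**
  $m_{ijt} = \beta_{0j} + \beta_{age,j}\,a_{it} + \gamma_j' x_{it} + b_{0ij} + \varepsilon_{ijt}$
* **Model 2 (random intercept + slope):** adds $b_{1ij}\,a_{it}$, with
  $(b_{0ij}, b_{1ij})$ bivariate normal with free covariance.

Here $a_{it}$ is age centred at the cohort mean baseline age and $x_{it}$
collects sex, smoking, drinking and five leukocyte subtype proportions.
Centring decorrelates random intercepts and slopes; slopes are always in
response units per year.

A CpG is called **age-varying** when model 2 beats model 1 on the
random-slope test, and **age-associated** when the fixed age effect of the
best model by AIC is significant; both calls use a Bonferroni split of the
family-wise $\alpha$ over the number of CpGs attempted (so the threshold is
reproducible regardless of convergence failures, which are flagged and
excluded from category counts). Sites passing both calls form the `both`
category; the intersection is reported rather than folded into either side.

## Design choices in the testing machinery

* **Null distribution of the slope test.** The null pins the slope variance
  (a boundary parameter) and the intercept–slope covariance, so
  $\Lambda = 2(\ell_2-\ell_1)$ is referred to the mixture
  $0.5\chi^2_1 + 0.5\chi^2_2$, not a plain $\chi^2_2$. An AIC-based
  alternative criterion (`criterion = "aic"`) is provided because model
  comparison by AIC is a common convention for this step; both $\Lambda$,
  its mixture p, and $\Delta$AIC are emitted so the choice is auditable.
* **ML, not REML.** Both models share fixed effects; ML likelihoods make the
  LRT and AIC comparisons coherent. A REML mode exists on `fit_lmm()` but is
  never used in comparisons.
* **Fixed-effect test.** Wald $z$ against the standard normal. With ~135
  subjects and 405 observations the large-sample reference is adequate (the
  null calibration of p-values is itself an acceptance test);
  small-sample degree-of-freedom corrections are out of scope.
* **Optimisation.** The fixed effects and residual variance are profiled
  out; the optimiser works on the 1 or 3 free elements of the
  Cholesky-parameterised relative covariance factor, with the diagonal
  bounded at zero so the no-slope-variance boundary is attainable exactly.
  Model 2 is always started from model 1's solution with the slope block at
  the boundary, which enforces $\ell_2 \ge \ell_1$ up to evaluation noise;
  a single perturbed restart handles the rare non-convergence, which is
  otherwise flagged. The per-evaluation cost is kept allocation-free in
  compiled code (Woodbury identity on the $2\times 2$ capacitance matrix),
  which is what makes genome-scale scans and the simulation-based
  calibration tests practical on one core.

# Change rates and the pace of aging

The model-2 random-slope BLUP $\hat b_{1ij}$ is the subject's methylation
change-rate deviation for CpG $j$. On the phenotype side the same
random-slope model is fitted per phenotype; $\hat b_{1ik}$ is the
phenotype-specific pace of aging. Composites average the direction-aligned
paces within each organ system:
$\text{pace}_{io} = \mathrm{mean}_{k \in o}\, d_k\, z(\hat b_{1ik})$,
where $d_k \in \{+1,-1\}$ encodes the phenotype's direction of change with
ageing.

Two decisions here were genuinely open:

* **Standardisation before averaging.** Phenotypes carry incommensurable
  units (mmHg/yr, mmol/L/yr, ...), so an unstandardised arithmetic mean is
  dominated by whichever phenotype is numerically largest. Paces are
  therefore z-scored across subjects before direction alignment and
  averaging; `standardize = FALSE` gives the raw aligned mean, and the mode
  in force is recorded in output metadata.
* **Imputation.** Multiple imputation by chained equations is replaced by a
  deterministic scheme (within-subject linear interpolation on age, then
  subject mean, then cohort mean; phenotypes missing in more than 20% of
  cells are dropped). This removes a stochastic dependency while preserving
  the pipeline contract, and makes end-to-end runs byte-reproducible.
* **Age as covariate vs time scale.** Age is the time scale of the model;
  the fixed effect of centred age carries the population trend and no
  separate baseline-age covariate is entered by default (subject-level
  baseline age is used when collapsing covariates for the subject-level
  partial correlations).

# Associating change rates with organ paces

Partial correlations are computed by two-sided residualisation: both the
CpG change rate and the organ pace are regressed on the subject-level
covariates, and the Pearson correlation of residuals is tested on
$n-2-k$ degrees of freedom. Time-varying covariates are collapsed to
subject level as baseline status (age, smoking, drinking) or within-subject
means (cell proportions); the collapse rule is recorded in metadata.
Raw $p < 0.05$ flags significance in the organ scan by default (a
Benjamini–Hochberg option exists but is off), matching the convention of
reporting raw-p association counts per organ in this literature.

# Enrichment machinery

* `fisher_exact_2x2()` computes the two-sided exact p by summing
  hypergeometric probabilities not exceeding the observed table's (with a
  $1+10^{-7}$ relative slack for floating-point ties). The odds ratio is
  the sample $ad/bc$ with Haldane–Anscombe correction (+0.5 per cell) for
  the OR and Wald CI only — the p-value is always exact on raw counts. The
  suite verifies the p against an independent enumeration for every table
  with total $\le 60$ and against `stats::fisher.test` on random tables.
* Clock enrichment intersects each clock list with the analysed universe
  first (so the universe is the set of CpGs that entered classification),
  tabulates clock × category membership with the inclusive category sets
  (the `both` overlap counts in each), and BH-adjusts across the clock ×
  category grid.
* The DHS contrast and the risk-factor contrast use the two exclusive
  categories (age-varying vs age-associated) since those form the 2×2 rows.
* The 2×8 genomic-feature table uses a Pearson chi-square test (expected
  counts are large; the choice of test for this table is a package
  decision).
* Over-representation is the one-sided hypergeometric tail with BH
  adjustment; probe-count bias weighting is not applied.
* Term redundancy: pairwise Wang similarity (is_a 0.8, part_of 0.6) for GO
  with a user-supplied DAG, Jaccard for other sources; edges strictly above
  0.5; communities by greedy (multilevel) modularity maximisation run under
  a fixed internal seed on lexicographically ordered vertices, so results
  are independent of input order; representatives minimise adjusted p with
  lexicographic tie-break; isolated terms represent themselves.

# The synthetic cohort

The generator emulates a three-wave, five-year longitudinal study of 135
older adults (baseline ages uniform on 70–81, follow-ups at +2.5 and +5
years, 61.5% female), with CpGs in four classes (null / age-associated /
age-varying / both) simulated directly on the beta scale with Gaussian
random effects and clamping to $[0,1]$ (the clamped fraction is reported
and stays below 1% under defaults because baseline levels are drawn away
from the boundaries; an unclamped M-value-like mode exists but is not the
default). Covariates include a six-part Dirichlet leukocyte simplex whose
dominant granulocyte fraction stays implicit — exactly as in deconvolution
practice — so the five emitted proportions are not collinear with the
intercept; cell proportions get small non-zero effects on methylation so
adjustment is exercised, while sex/smoking/drinking effects default to
zero so classification truth is driven by the random structure.

Organ phenotypes are generated from latent per-organ ageing rates: each
phenotype's true subject slope is a mixture
$d_k \tau (\rho u_{io} + \sqrt{1-\rho^2} e_{ik})$ so that the
direction-aligned slope correlates $\rho$ with the latent rate; per-subject
phenotype trajectories add an intercept, a population trend of
$0.1 d_k$ z-units/yr and Gaussian noise, then a per-phenotype unit scale
(1–100×) so unit-invariance of the composites is genuinely exercised.
Effect-size defaults ($\beta_{age} = 0.002$/yr, $\sigma_{b1} = 0.003$/yr,
$\sigma_{b0} = 0.02$, $\sigma_e = 0.005$, $\tau = 0.3$ z/yr, $\rho = 0.6$)
are calibration choices of the package — plausible for blood methylation
and clinical phenotypes in older adults — not estimates of any particular
cohort, and all are exposed in `cohort_config()`.

What the generator does **not** emulate: array-level artifacts (probe
bias, batch effects, detection failures), realistic phenotype marginal
distributions, non-Gaussian trajectory shapes, and dependence between
CpGs beyond the planted organ couplings. Passing recovery tests therefore
demonstrate correctness of the estimation machinery under the stated
model, not robustness to real-data pathologies.

# Numerical conventions and degenerate inputs

* Variance parameters live on the relative-Cholesky scale; profiled
  residual variance is floored at $10^{-12}$ so exactly-deterministic
  responses (e.g. a constant CpG) return boundary estimates instead of
  failing.
* Constant CpG rows are flagged degenerate and excluded from category
  counts; constant covariate columns raise an error naming the column.
* A partial correlation where one variable is fully explained by the
  covariates returns $r = 0$ with a warning (residual orthogonality); a
  constant input vector is an error.
* Fisher tables with an empty margin return $p = 1$ with the
  Haldane-corrected OR and an explicit flag.
* All significance flags use strict `p < alpha`, with `alpha >= 1`
  flagging everything (threshold-boundary convention).

# Problem sizes used in the tests

The shipped test-suite and the acceptance script run the calibration
studies at the study's own design scale — 135 subjects × 3 waves, with
2,000-CpG panels for the null-calibration and planted-recovery scans,
2,000 subjects for the large-sample convergence checks, and two full
pipeline runs at 135 × 2,000 for the determinism contract. These sizes
give the binomial/KS checks adequate resolution while keeping a full run
in the low minutes on a single core; all of them are plain function
arguments, so larger studies are a matter of changing the configuration.
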