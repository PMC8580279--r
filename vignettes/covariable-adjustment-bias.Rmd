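---
title: "Simulating covariable-adjustment bias in two-sample Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating covariable-adjustment bias in two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcovadj)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure X on an outcome Y by combining variant–exposure and
variant–outcome associations from two non-overlapping GWAS samples. Many
GWAS, however, publish associations *adjusted for a heritable covariable*
W (waist circumference adjusted for BMI, lung function adjusted for
smoking, and so on), usually to target "direct" genetic effects. When the
genetic instruments are marginally associated with W, such adjustment can
do two opposing things to a downstream MR analysis:

* **remove horizontal pleiotropy** that acts through W, when W has a
  direct effect on Y and no unmeasured confounding is present; or
* **introduce collider bias**, when W shares an unmeasured common cause
  with X or (especially) with Y — conditioning on W then opens a
  non-causal path between the instrument and the adjusted trait.

`mrcovadj` implements a structural-equation Monte-Carlo framework to
quantify these effects, together with the two-sample IVW estimation
pipeline itself so that the same estimator can be run on user-supplied
summary statistics.

## The data-generating model

Each scenario is a directed acyclic graph over the genetic variants Z,
the exposure X, the covariable W, the outcome Y, an optional shared
intermediate R, and up to three unmeasured confounders
$U_{XW}, U_{WY}, U_{XY}$. Six structures are crossed with five
confounding settings:

| Structure | Genetic architecture | Extra edges |
|-----------|----------------------------------|-------------|
| A | Z → W | W → X |
| B | Z → X, Z → W | — |
| C | Z → X | X → W |
| D | Z → R | R → X, R → W |
| E | Z → X, Z → W | W → Y (pleiotropy, InSIDE holds) |
| F | Z → R | R → X, R → W, W → Y (InSIDE violated) |

Confounding settings: 1 none, 2 adds $U_{XW}$, 3 adds $U_{WY}$, 4 adds
$U_{XY}$, 5 all three. In structures A–D the instruments are valid for
the X→Y effect; in E and F they are pleiotropic through W. X → Y is
always present, with a null or non-null coefficient.

**Effect scaling.** 40 independent biallelic variants are drawn under
Hardy–Weinberg equilibrium with allele frequencies uniform on
(0.1, 0.9) — the common-variant regime of GWAS. All variants with a
direct effect on a phenotype are combined into an unweighted additive
allele score, standardized to unit variance, which is given a coefficient
making it account for 10% of that phenotype's variance. Every phenotypic
or unmeasured direct cause receives a coefficient
$\sqrt{v}/\mathrm{sd}(\text{cause})$ with $v = 0.20$, so it nominally
accounts for 20% of the child's variance; the non-null X→Y effect falls
under the same rule, giving $\beta = \sqrt{0.2} \approx 0.447$ on the
standardized scale. All direct effects are positive. Residual Gaussian
noise tops each phenotype's variance up to 1: its variance is
$1 - \widehat{\mathrm{Var}}(\text{systematic part})$, recomputed
empirically per cohort and floored at 0.01.

Two consequences of this design are worth knowing. First, phenotypes are
standardized *empirically*, so variance fractions are realized exactly in
expectation but fluctuate with sampling error. Second, when several
causes of the same phenotype are positively correlated (heavily
confounded cells with a non-null effect, e.g. Y in F5), the systematic
variance can exceed 1; the floor then binds and the phenotype's total
variance exceeds 1 slightly. The configuration constructor rejects any
cell whose *nominal* fractions sum to ≥ 1, with a diagnostic listing the
contributing causes.

**Variant modes.** In *homogeneous* mode every variant has the single
causal role the structure dictates (A: effects on W only; B/E: on both X
and W; C: on X only; D/F: on R only). In *heterogeneous* mode the 40
variants split into four equal subgroups — effects on X only, on W only,
on both X and W, and on R only. The subgroup sizes are this package's
choice (equal split); in structures without R the fourth subgroup is
generated as null variants with no effects, which preserves the full
candidate count and exercises the instrument-strength filter
realistically.

## Estimation pipeline

Each replicate cohort of n individuals is split into two random halves:
the exposure half yields per-variant X associations, the outcome half Y
associations, each computed both unadjusted and adjusted for W by
per-variant least squares (the adjusted F is the partial F of the
genotype term — the squared Wald t — matching how instrument strength is
assessed in MR practice). Instruments are selected at F ≥ 10
(inclusive), re-selected per adjustment combination from the matching
exposure GWAS, and the causal effect is estimated by IVW with
multiplicative random effects:

$$\hat\beta = \frac{\sum_j \hat\beta_{Xj}\hat\beta_{Yj}/\sigma_{Yj}^2}
                   {\sum_j \hat\beta_{Xj}^2/\sigma_{Yj}^2},
\qquad
\mathrm{SE}(\hat\beta) = \phi \cdot
  \Big(\sum_j \hat\beta_{Xj}^2/\sigma_{Yj}^2\Big)^{-1/2},$$

where $\phi^2$ is the residual mean square of the zero-intercept weighted
fit, floored at 1 (underdispersion never shrinks the SE). Confidence
intervals use the normal approximation (±1.96 SE), the convention of
summary-data MR. The four combinations — neither side adjusted, exposure
only, outcome only, both — correspond to which published GWAS an analyst
might have access to.

For file-based inputs the same estimator runs behind a harmonization
step: records are joined on variant id; swapped or strand-complemented
alleles flip the outcome beta; palindromic variants are aligned by
allele frequency when both frequencies lie outside [0.42, 0.58] and are
dropped otherwise (the ambiguity zone is this package's explicit rule).
Instrument selection for file inputs uses genome-wide significance
(p < 5 × 10⁻⁸) by default, with an F-threshold alternative; LD
independence of the supplied variants is the caller's responsibility.
An optional sensitivity filter excludes instruments associated with the
covariable at p < 0.05 (retention is p ≥ 0.05).

## Monte-Carlo design and reproducibility

`run_grid()` aggregates replicates into per-cell summaries: mean bias
(mean estimate minus the realized true effect), empirical 95% CI
coverage, mean instrument count and F, and the fraction of
non-estimable replicates (zero instruments selected — e.g. the adjusted
exposure GWAS in homogeneous A1/A3/A4, where conditioning on W closes
every open Z–X path; such cells are flagged by
`summarize_bias_table()`). Bias and coverage are computed over estimable
replicates only.

Every replicate derives its own seed by hashing the master seed with the
scenario id, variant mode, null status and replicate index, so results
are bit-reproducible and independent of how replicates are scheduled
across workers.

**Problem sizes.** The package's reference conditions are 40 variants
and cohorts of 100 000 individuals with 5000 replicates per cell. The
shipped test and acceptance workloads scale this down: single-cohort
variance checks and the coverage cells run at the full n = 100 000
(coverage with 500 replicates rather than 5000), because CI calibration
is sensitive to instrument strength — mean F scales linearly with n, and
at reduced n weak-instrument attenuation (a shift of order $-\beta/F$ in
the estimate) measurably erodes nominal coverage even though the
instruments are valid; the directional-bias and instrument-count cells run 500
replicates at n = 20 000, where sign and ordering properties are already
unambiguous relative to Monte-Carlo error. At these sizes a full
directional suite runs in minutes on a single core.

One reduced-scale caveat the full-scale study does not share: with
n = 20 000 the per-variant F in the R-mediated structures (D, F,
homogeneous) is near the selection threshold, so winner's curse and
weak-instrument attenuation shrink estimates multiplicatively. Under a
non-null effect this attenuation partially offsets the positive
pleiotropy bias in the *unadjusted* E1/F1 analyses; the non-null-vs-null
bias ordering is therefore asserted in the covariable-adjustment-bias
cells (confounding setting 3, adjusted outcome associations), where both
mechanisms push the same way — which is also the setting the
qualitative claim is about.

## What the generator does and does not emulate

It emulates: independent common variants under Hardy–Weinberg
equilibrium, additive genetic effects, Gaussian phenotypes on a
standardized scale, non-overlapping two-sample GWAS, and
covariable-adjusted association estimates. It does not emulate: linkage
disequilibrium (instrument "independence" is by construction),
binary/skewed traits, sample overlap, population stratification,
genotype uncertainty, or variant-specific effect heterogeneity beyond
the four-subgroup heterogeneous mode. Passing tests therefore show the
estimator and the bias mechanisms behave as the causal structures
predict — not that real covariable-adjusted GWAS are free of additional
complications (clumping artefacts, winner's curse from discovery
selection, trait transformations).

## Numerical choices

* Per-variant OLS uses closed-form sufficient statistics
  (Frisch–Waugh–Lovell partialling-out for the adjusted case), exact to
  `lm()` within floating tolerance but without per-variant model objects.
* Constant genotype columns (possible at extreme frequencies in small
  samples) yield `NA` associations with a warning and are excluded from
  selection rather than failing the replicate.
* Threshold conventions: F selection is inclusive (≥ 10); the
  covariable-exclusion filter removes p < 0.05 and retains the boundary.
* With a single instrument the IVW estimate degenerates to the Wald
  ratio with dispersion 1; with zero instruments workflow drivers return
  a non-estimable marker instead of failing the remaining combinations.
* The non-null causal coefficient is `sqrt(0.2)` by the same
  variance-fraction rule as every other phenotypic direct effect; it is
  configurable through `direct_effect_variance_fraction`.

## Known limitations

* The variance-topping rule keeps every phenotype near unit variance
  only while the systematic variance stays below 1; in the most heavily
  confounded non-null cells Y's variance can exceed 1, so "20% of
  variance" is then nominal rather than realized.
* Heterogeneous-mode subgroup sizes are fixed at an equal split;
  real genetic architectures are not so tidy, and the relative bias of
  homogeneous vs heterogeneous instruments depends on this choice.
* The harmonization rule set is declared, not exhaustive: no proxy
  lookup, no multi-allelic variants, no indels.
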