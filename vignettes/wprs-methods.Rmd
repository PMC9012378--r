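---
title: "Weighted polygenic risk scores and tertile risk models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted polygenic risk scores and tertile risk models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wprskit)
```

## The model

A weighted polygenic risk score (wPRS) summarizes an individual's load
of risk alleles across a fixed variant panel under the additive genetic
model. With `g_ij` the number of copies (0, 1 or 2) of the risk allele
of variant `j` carried by individual `i`, and `beta_j` the variant's
log odds ratio from association studies,

    sum mode:      wprs_i = sum_j beta_j * g_ij
    average mode:  wprs_i = sum_j beta_j * g_ij / (2 * M_i)

where `M_i` is the number of panel variants with an observed genotype
for individual `i`. The two modes rank individuals identically when no
genotypes are missing; the average mode is robust to per-sample
missingness because an individual scored on fewer variants is not
mechanically pulled toward zero. **Average mode is the default**: it
matches the per-allele-average convention of the widely used PLINK
`--score` tool, and score ranges on a ~31-variant panel of modest
log-odds weights then land in the familiar 0-1.2 region rather than
growing with panel size. Both modes are first-class and the mode is
recorded in the score output.

Missing genotypes are mean-imputed before scoring: a missing cell at
variant `j` becomes `2 * p_hat_j`, the expected dosage under the
in-sample counted-allele frequency. Imputation uses sample frequencies
(not external reference frequencies), so scores are fully reproducible
from the input files alone. The denominator of the average mode counts
only variants observed *before* imputation, so with no missing data
average = sum / (2M) exactly.

Weights enter as signed `ln(OR)` values. Because a "summed risk
alleles" count is only meaningful when every counted allele is the
risk-increasing one, `orient_weights()` re-orients negatively weighted
variants (swap alleles, negate weight) before counting; scoring itself
is orientation-invariant by linearity.

### Assumptions

- Additivity on the log-odds scale, no dominance or interaction terms.
- The panel's weights were estimated elsewhere; the package applies,
  never re-estimates, them (refitting per-variant models is provided
  only for simulation validation).
- Biallelic SNPs. Multi-allelic records are rejected at VCF parse time.

## Harmonization

Dataset files may count either allele. `harmonize()` aligns every
shared variant so its dosage counts the weight table's effect allele:
matching pairs are kept, swapped pairs are flipped (`g -> 2 - g`),
irreconcilable pairs are dropped with a reason. Palindromic (A/T, C/G)
variants cannot be disambiguated across strands without external
frequency information, so the default policy drops them with a warning;
`keep` trusts the file strand. Joins are by variant identifier, not
position, because curated weight panels are typically rsID-keyed.

## Quality control

Defaults follow the conventional array-QC triple: call rate >= 95%,
MAF >= 1%, Hardy-Weinberg exact `p >= 1e-6`, with LD pruning at
`r^2 < 0.8`. Filters are checked in the order call rate, MAF, HWE, and
the report records the first failing rule per variant, so a variant
failing several rules is counted once.

The HWE test is the conditional exact test: with the observed allele
counts fixed, heterozygote counts are enumerated, each configuration's
probability is proportional to `multinomial(n; n_aa, n_ab, n_bb) *
2^n_ab`, and the two-sided p-value sums all configurations whose
probability does not exceed the observed one (with a `1 + 1e-12`
relative slack on the comparison, the standard guard against
floating-point misclassification of exactly tied configurations).
Computation is on the log scale and normalized over the support, so it
is stable for any counts. HWE is evaluated on all samples by default
with a controls-only switch, since HWE is only expected to hold in the
population controls represent; the default keeps the filter usable
before labels exist.

LD pruning is a greedy scan in genomic order: a variant is dropped if
its `r^2` (squared Pearson correlation of dosages over jointly observed
samples) with any previously kept variant on the same chromosome
exceeds the bound. Any kept set satisfying the pairwise bound would be
admissible; the greedy-in-order rule is fixed purely so results are
reproducible. A variant whose `r^2` against a kept variant is undefined
(monomorphic in the joint sample) is dropped with a warning — such a
variant carries no information the kept one does not.

Genotype principal components are computed on the study samples'
column-standardized, mean-imputed dosage matrix. The sign of each
component is fixed by making its largest-magnitude loading positive
(PCA signs are otherwise arbitrary and would break reproducibility).

## Tertile risk models

Scores of both case cohorts and the shared controls are pooled, and the
pooled vector is cut at its empirical 1/3 and 2/3 quantiles. Quantiles
use a **nearest-rank convention**: the boundaries are the order
statistics at ranks `floor(n/3) + 1` and `floor(2n/3) + 1`, assignment
is `score < lower -> T1`, `[lower, upper) -> T2`, `>= upper -> T3`, and
ties at a boundary all go to the upper group (deterministic and
order-independent). With 768 distinct pooled scores this yields exactly
256/256/256. No interpolation is used, so boundaries are always
observed score values.

Per-tertile odds ratios versus T1 come from a logistic model with T2/T3
indicators plus any adjustment covariates, fit by IRLS with Wald 95%
intervals `exp(b ± 1.96 se)`. High-risk tertiles in a strongly
discriminating score can approach quasi-complete separation (very few
controls in T3), where maximum-likelihood odds ratios diverge. The
package flags separation (non-convergence, absurd coefficients, or
standard errors above 10 on the log scale) and by default refits with a
Jeffreys-prior penalized (Firth-type bias-reduced) likelihood, which
always yields finite estimates; the policy is configurable and the
method used is recorded in the fit.

## Evaluation metrics

The AUROC is the tie-corrected Mann-Whitney statistic — the probability
a random case outscores a random control, half credit for ties —
computed via midranks. Confidence intervals use the DeLong
structural-components variance with a normal approximation, truncated
to [0, 1]. The same estimator applied to data grouped into K ordered
risk levels gives the ordinal AUROC of a tabulated risk model; this is
the statistic classical ROC-table routines report, and on a published
3-level count table it reproduces the printed three-decimal AUROCs
exactly. The DeLong interval is a documented package choice for the
ordinal case as well — grouped data are just heavily tied scores, for
which the estimator remains valid. Display rounding is three decimals,
half-up.

Threshold metrics at level `t` predict "case" iff level >= t:
sensitivity = cases at/above `t` / all cases, specificity = controls
below `t` / all controls, and accuracy obeys
`acc = (sens * n_cases + spec * n_controls) / n`.

## The synthetic cohort generator

`simulate_case_control()` emulates the structure the analysis assumes:

- a panel of 31 independent biallelic SNPs (29 tagged "gwas" with
  weights `|N(0.5, 0.2^2)|`, 2 tagged "reported" with weights
  `|N(0.2, 0.05^2)|` — shapes chosen to resemble a GWAS-top-hit panel,
  with no claim of matching any particular study's weights),
- minor allele frequencies uniform on [0.05, 0.5] and genotypes in
  Hardy-Weinberg proportions,
- two disease liabilities, additive on the log-odds scale with
  covariate effects (age, sex, four binary risk factors); disease B
  keeps a configurable fraction (default 0.7) of disease A's variant
  effects and zeroes the rest,
- cohort sizes 250 / 222 / 296 (two case groups, shared controls),
- uniform genotype missingness (default 1%).

Each cohort is rejection-sampled from its own independent population
draws — disease-A cases from `P(· | D_A = 1)`, disease-B cases from
`P(· | D_B = 1)`, controls from `P(· | D_A = 0, D_B = 0)`. Drawing the
three cohorts from one shared stream with exclusive assignment would
make B's cases systematically depleted for shared risk alleles (they
would be the `D_B` cases that escaped `D_A`), an artifact with no
analogue in a two-study design.

Intercepts are tuned by bisection so each disease's marginal
probability equals a configured **population prevalence** (default 5%
per disease, a realistic order for hospital-ascertained cerebrovascular
phenotypes). Tuning instead to the case-control sample fraction
(~0.45) would make "free of both diseases" a strong genetic screen:
controls would be visibly depleted of risk alleles and even a
genetically null comparison would show AUROC well above 0.5. At a few
percent prevalence this screening effect is negligible and the
generator satisfies the natural calibration checks (null panels give
AUROC ≈ 0.5; a fully shared panel discriminates both diseases equally
well; a disjoint architecture drops cross-disease AUROC to chance).

Under case-control sampling, logistic slope coefficients remain
consistent (only the intercept absorbs the sampling fraction), so
per-variant effects are recoverable by a joint adjusted refit. One
subtlety: this guarantee assumes selection depends only on the modeled
outcome. Because shared controls are screened free of *both* diseases,
a nonzero genetic effect on disease B adds a second genotype-dependent
selection channel and inflates disease-A effect estimates slightly
(~+0.05 mean log-OR at n = 20,000 under a fully shared panel). The
parameter-recovery experiments therefore run with
`shared_effect_fraction = 0`, where the classical result applies
cleanly.

### What the simulation does not emulate

Independent sites only — no LD structure, so LD pruning is exercised on
engineered duplicates rather than realistic haplotypes. No population
stratification (PCA separation tests construct two-subpopulation
fixtures directly). Covariates are drawn from simple marginals
(age ~ N(60, 13²) truncated at 18, binary flags with fixed rates) with
confounding arising only through the shared liability, not through
label-dependent sampling. Consequently, passing tests demonstrate
correctness of the estimators and the pipeline's bookkeeping, not
calibration on real array data — in particular, published
individual-level quantities (continuous-score AUROCs, adjusted odds
ratios, risk-allele count distributions) are only reproduced
qualitatively: discovery discrimination exceeding cross-disease
validation under partial sharing, and monotonically increasing tertile
odds ratios.

## Numerical choices and degenerate inputs

- Dosages always count `allele_b` (bim A1 / VCF ALT on read); writers
  invert the same convention, so PLINK and VCF round-trips are exact,
  including missing cells.
- All-identical scores make tertiles undefined: hard error.
- Monomorphic pairs make `r^2` undefined: error from `ld_r2`,
  drop-with-warning inside pruning.
- AUROC of 0 or 1 degenerates the DeLong variance: collapsed interval
  with a warning rather than a fabricated width.
- Fully missing variants cannot be imputed or frequency-typed: errors
  naming the variant.
- Logistic fits require both classes, full column rank and
  n > parameters: named errors.
- `glm` convergence tolerance is tightened to `1e-12` so saturated-model
  odds ratios match closed-form cross-product ratios to 1e-8.

## Problem sizes used by the test-suite experiments

Chosen as the package's own desk-scale defaults: oracle comparisons at
tens of samples; coverage simulations at 500-1000 replicates of
n = 300-768; Hardy-Weinberg enumeration exhaustive to total count 50;
parameter recovery at n = 20,000 with 31 variants. These keep the whole
suite within a couple of minutes on one CPU while leaving Monte-Carlo
noise well below the asserted tolerances.

## Known limitations

- No dosage (imputed, non-integer) genotype input; hard calls only.
- No clumping-and-thresholding or shrinkage-based PRS construction: the
  panel is fixed by design.
- Cross-validation of risk models is not built in; the tertile model is
  refit/evaluated on whatever cohort is supplied.
- The ordinal AUROC's DeLong interval treats the grouped counts as the
  data; it does not account for the estimation of the tertile
  boundaries themselves.
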