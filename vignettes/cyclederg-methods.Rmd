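---
title: "Methods: gene-set deregulation, survival and drug-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-set deregulation, survival and drug-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclederg)
```

This vignette is the package's own account of its models, its defaults
and the design choices that were genuinely open. Everything asserted
here is computed by the package's test suite or acceptance script;
nothing is quoted from elsewhere.

## The deregulation statistic

The question is whether a gene set (for example, the cell-cycle genes)
sits systematically above the rest of the transcriptome in a tumor
cohort. The statistic is deliberately simple and median-based:

1. For each gene, take the **median log2 expression across the
   cohort's samples**. Missing values are excluded from the median;
   genes with no observation are dropped and reported. Medians, not
   means, because expression distributions are heavy-tailed and a
   handful of outlier samples should not move the cohort summary.
2. The cohort's statistic is
   `log2FC = median(set-gene medians) − median(other-gene medians)`.
   On log2 data a difference of medians is a log2 fold change.

**Order of aggregation.** One could also pool all gene-by-sample
values of each group before taking the median. Both readings are
defensible; the per-gene-median order is the default because the
package's quantile reference (`quantile_reference()`, the grey
25/50/75% guide lines a set's genes are plotted against) is defined on
per-gene medians, and using the same substrate keeps the two displays
commensurable. The pooled reading is available via
`dereg_test(..., pooled = TRUE)`; on clean synthetic data the two
agree closely (tested).

**Significance, twice.**

* A two-sided **Wilcoxon rank-sum test** of set-gene medians against
  other-gene medians. The test is exact (enumeration) when both groups
  have fewer than 20 values and no ties, and otherwise uses midranks
  and the normal approximation with continuity correction. A rank test
  is the assumption-light choice for a median comparison; the exact
  distributional form of log2 expression never enters.
* An **empirical permutation null**: `M` times, relabel a random,
  equally sized gene set and recompute the statistic. The reported p
  is the add-one estimator `(1 + #{null ≥ observed})/(M + 1)`: it can
  never be zero (its floor is `1/(M+1)`, so `M = 10^4` — the default —
  reports at best `10^-4`), and ties count **against** significance,
  a deliberately conservative convention.

Cohorts are ranked by `log2FC` (rank 1 = largest); ties break first by
smaller rank-sum p, then lexicographically by label, so ranks are
always a permutation of 1..n.

**Matched pairs.** For tumor/normal pairs,
`matched_paired_test()` applies a two-sided Wilcoxon signed-rank test
per gene with midranks, dropping zero differences. With 12 or fewer
non-zero differences the p-value comes from full enumeration of all
2^n sign assignments — the textbook exact distribution is unavailable
under ties, and enumeration is both exact and cheap at that size;
larger genes use the normal approximation.

## Quartile-stratified survival

Patients are split at the **type-7** 25th and 75th percentiles of one
gene's expression; boundary samples are included in the extreme groups
(inclusive cut — the convention must be fixed somewhere, and inclusion
keeps both groups non-empty for heavily tied covariates). The middle
half is discarded. A covariate whose two boundaries coincide is a hard
error rather than a silent single group.

Each group's survival is the product-limit (Kaplan–Meier) estimate; at
tied times events are processed before censorings. The two groups are
compared with the standard log-rank test (hypergeometric mean and
variance at each distinct event time, chi-square on 1 df, no
continuity correction — the common default). Both are delegated to the
`survival` package and re-shaped into this package's containers; the
test suite checks them against hand product-limit computations and a
from-scratch log-rank implementation. No Cox model is fitted: the
analysis reports group curves and a test, not hazard ratios.

## Differential expression and over-representation

Per gene, `log2FC = mean(treated) − mean(control)` and a two-sided
**pooled-variance Student t-test** across replicates. Significance
calls use BH-adjusted p < 0.05 **and** |log2FC| > 1, both reproduced
exactly as threshold semantics.

**Why pooled Student rather than a separate-variance (Welch) test.**
At triplicate scale the Welch degrees of freedom can collapse toward
2 whenever one arm draws a small variance estimate, and its power
against even a 2-log2 shift falls below half; the pooled test keeps
df = n1 + n2 − 2 and matches the homoscedastic replicate noise that
array replicates exhibit. It is also the test named for all other
group comparisons in this kind of study. Moderated (empirical-Bayes)
statistics would add power by sharing variance across genes, but are
deliberately out of scope: the package's contribution here is the
threshold/overlap/enrichment logic, and a plain documented gene-wise
test keeps it transparent. Exact gene lists will therefore differ
from a moderated analysis.

Genes with zero variance in both arms are untestable when the means
are equal (p = 1); with unequal means they receive a variance floor
equal to the 10th percentile of all positive per-gene pooled variances
(flagged per gene), so degenerate fixtures yield finite statistics
instead of NaN.

Overlaps across treatment conditions are exact set algebra over every
exclusive Venn region (counts always partition the union).
Over-representation uses the upper-tail hypergeometric p with the
universe defaulting to all genes on the matrix; terms with no overlap
with the universe are excluded both from testing and from the
Bonferroni multiplier, which is the number of terms actually tested.

## Assay quantification

* **4PL dose-response**: `response = bottom + (top − bottom)/(1 +
  (dose/ec50)^hill)`, fitted by Levenberg–Marquardt least squares
  (`minpack.lm`), initialized at bottom = min response, top = max
  response, ec50 = dose nearest mid-response, hill = 1, with ec50
  bounded positive. An essentially flat response is flagged
  non-converged — no IC exists and none is reported. IC-x solves
  fitted response = (100 − x)% **of control** (the absolute scale MTT
  reporting uses) by monotone root finding over the observed dose
  range extended tenfold; the asymptote-relative definition is
  available via `relative = TRUE`. Confidence intervals are
  case-resampling percentile bootstrap (B = 1000 default; the method
  must be fixed somewhere and the percentile bootstrap makes no
  distributional assumption); if more than 20% of resamples fail to
  converge the intervals are withheld rather than reported from a
  biased remnant.
* **2^−ΔΔCT**: per replicate ΔCT = CT(target) − CT(reference); ΔΔCT is
  the difference of arm means of ΔCT; fold = 2^−ΔΔCT. Per-replicate
  folds are also emitted for spread. The fold is invariant to adding a
  constant to both target and reference CTs (tested).
* **Densitometry**: (band/loading) / (control band/control loading),
  invariant to rescaling all four intensities.
* **Phase fractions** must each lie in [0, 100] and sum to 95–105%
  (tolerance for debris and gating loss). The phase fold change is the
  raw ratio; conventional 1-decimal reporting is applied at print
  time, because rounding inside the function would break the exact
  reciprocal identity fold(A,B) = 1/fold(B,A).
* **Tumor metrics**: volume = a·b²·0.5 with a ≥ b enforced by
  reordering; area defaults to a·b (the plain caliper product), with
  the ellipse π/4·a·b behind a flag since reported mm² values rarely
  state their convention.
* **Two-group comparisons** are pooled-variance Student t-tests with
  means and SDs reported; zero pooled variance yields p = 1 (equal
  means) or p = 0 (separated constants) instead of an error.

## Synthetic data: what it emulates, what it does not

All generators are pure functions of (config, seed): identical seeds
give bit-identical output, the caller's RNG stream is never disturbed,
and the generating truth is returned with the data so recovery tests
are self-contained. A master seed expands into per-stage child seeds
via `child_seed()` — `(seed + 10007·stage_index) mod (2^31 − 1)` — so
any single stage can be reproduced alone.

* **Pan-cancer expression** is log2-normal: baseline Normal(8, 2) per
  gene and sample, with the designated set shifted up by a per-cohort
  delta. The default 24 cohorts carry deltas spanning 0.55–1.34 log2,
  the effect-size band over which a multi-cancer set-level screen
  operates; 2000 genes with a 200-gene set and 100 samples per cohort
  keep the estimator's sampling noise near ±0.03. Because every
  downstream statistic is median/rank-based, results are robust to the
  exact law; the normal is chosen for transparency.
* **Survival** draws exponential event times with hazard
  `h0·exp(β·covariate)` (proportional hazards, h0 = 1/1000 per day).
  Censoring is independent of the event time: with probability
  `censor_rate` a patient gets a Uniform(0, max follow-up) censoring
  time, so `censor_rate = 0` observes every event.
* **Treatment microarrays** follow the triplicate design (3 controls,
  3 replicates per concentration), with the target set shifted by a
  monotone non-increasing per-condition amount and i.i.d. Normal
  replicate noise (SD 0.25 by default).
* **Viability curves** are 4PL plus Normal noise; **qPCR tables**
  encode a gene's fold change f as a treated-arm CT shift of
  −log2(f).

None of the generators mimic batch structure, platform effects,
gene–gene correlation, or informative censoring. Passing recovery
tests therefore demonstrates correctness of the estimators under their
stated assumptions — not robustness to the artefacts of real cohorts.

## Numerical conventions and simulation sizes

Quantiles are type 7 (linear interpolation) throughout, stated because
quantile dialects differ. The permutation tail uses ≥; the empirical p
uses the add-one estimator. All Monte-Carlo procedures are
bit-reproducible under a fixed seed.

The test suite's calibration studies use 200 replicates for the
permutation-null and log-rank null rejection rates (checked against
the exact binomial 95% interval around the nominal 0.05), 200
replicates with B = 200 resamples for bootstrap EC50 coverage, 50
seeds for effect-recovery means, and 20 seeds for
differential-expression sensitivity — sizes at which the binomial
check is meaningful while the whole suite stays fast. The
exhaustive-enumeration oracles (permutation instances up to 8 genes,
hypergeometric universes up to 12, signed-rank up to 2^10 sign
vectors) are exact, not sampled.

## Known limitations

* The deregulation statistic treats genes as exchangeable under the
  permutation null; co-expressed sets violate this silently in real
  data (the null is then anti-conservative).
* The gene-wise Student t at triplicate scale has limited power:
  roughly a tenth of genuinely 2-log2-shifted genes draw an inflated
  variance estimate and miss the BH threshold, so sensitivity
  plateaus near 0.9 under the synthetic design. Variance moderation
  would raise it but is out of scope by design.
* Survival stratification discards the middle half of patients by
  construction; this matches the extreme-quartile display convention
  but is not an efficient estimator of the expression–hazard
  relationship.
* Gene identifiers are matched exactly and case-sensitively, with no
  alias resolution; the package is namespace-agnostic by design.
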