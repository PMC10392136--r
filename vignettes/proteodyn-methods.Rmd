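---
title: "Methods: models, parameters and design choices in proteodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in proteodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

proteodyn implements two workflows for DIA proteomic panels of breast
cancer cell lines: a **cohort workflow** (quality control,
protein-complex co-expression, TNBC differential expression, and
multi-omics elastic-net drug-response prediction) and a **perturbation
workflow** (drug time-course summarization, IC50-correlation screening,
fuzzy c-means clustering, opposite-dynamics selection, pathway
consistency, and persistently dysregulated protein detection). This
vignette records the statistical models, the tunable parameters, and the
design decisions that were genuinely open, so a maintainer can see why
each piece looks the way it does.

## Data model

All intensity layers are stored and processed in log2. Missing values
are a first-class feature: DIA matrices routinely run at ~35%
missingness and missingness is intensity-dependent, so no statistic in
the package ever encodes a missing value as a sentinel number, and all
correlations use pairwise-complete observations (listwise deletion would
discard most features at this missing rate). The mutation layer is
binary 0/1 with no missing values allowed.

Sample ids are opaque; the mapping to cell line, replicate group (1-3
biological, 4 = technical re-measurement of biological replicate 3, run
in a separate batch) and batch lives only in the sample annotation.
Both replicate-level (4 columns per line) and cell-line-averaged
matrices are supported by the same `omics_matrix` container.

## Quality control

* **Missing-rate filter**: features with missing fraction strictly
  greater than 0.9 are removed — the literal reading of "over 90%";
  a feature at exactly 0.9 is retained.
* **Outlier samples** are flagged by a robust z-score on the per-sample
  count of quantified proteins (median/MAD, default threshold 3).
  The underlying criterion is count-based; a PCA display is only a way
  of *seeing* such samples, so the rule is implemented directly on the
  counts and the threshold left configurable.
* **Replicate correlations** label same-line pairs with groups {3, 4}
  as technical and all other same-line pairs as biological. Group 4 is
  a re-measurement of biological replicate 3, so against replicates 1
  and 2 it behaves as a biological replicate; pairs are labeled purely
  by replicate group. Pairs with fewer than 3 co-observed features are
  skipped and counted.
* **Batch correction** is per-feature batch mean-centering (subtract
  the batch mean, add back the grand mean). This is a location-only
  adjustment: it preserves each feature's grand mean to numerical
  precision, leaves within-batch variance untouched, and never changes
  the missing pattern. A feature entirely missing within a batch is
  left unadjusted there.
* **CV by abundance**: per feature, the coefficient of variation of
  linear-scale intensities across a line's replicates, averaged over
  lines, then summarized as the median per abundance-quantile bin
  (default 3 bins).

## Protein-complex co-expression

Within-complex subunit pairs are enumerated against the measured
features; correlations use the cell-line-averaged matrix (cross-line
co-expression is the quantity of interest; replicate structure would
inflate r). Pairs need at least 3 co-observed lines — Pearson r is
degenerate below that; the threshold is configurable because the
original analysis is silent on it. The protein-level and
transcript-level correlation lists are compared with a two-tailed
unpaired equal-variance Student's t test on the raw r values (no Fisher
z). That choice is statistically debatable but mirrors the analysis the
package reproduces; fidelity wins over elegance here. Top pairs are
ranked by r with lexicographic tie-breaks so results are deterministic.

## Differential expression

Per feature, a two-tailed unpaired t test on log2 values —
equal-variance Student by default, with a Welch switch — with fold
change computed from the difference of log2 group means (the
geometric-mean ratio, consistent with volcano-plot conventions).
Benjamini-Hochberg adjustment runs across the tested features only;
features with fewer than two observations in either group are reported
untested and excluded from the family. A DEP requires adjusted p <
0.05 and fold change > 1.5 or < 0.67 (all configurable). The "most
significant" signature (default n = 38) is the smallest adjusted p
among DEPs, ties broken by larger |log2 FC| then feature id; the
original ranking rule is unstated, so the package fixes this
deterministic one. Signature quality is scored as the mean silhouette
width of the TNBC labels under correlation distance over complete-case
signature features — silhouette is a label-agnostic, bounded score, so
it serves as a clustering-free stand-in for "the heatmap separates the
groups".

## Elastic-net drug-response prediction

The estimator is a nested leave-one-out procedure over cell lines. For
each held-out line, on the remaining lines only:

1. **Tuning**: grid over the alpha mixing grid and a per-alpha
   geometric lambda path; CV MSE averaged over replicated k-fold
   partitions; ties broken toward larger lambda, then larger alpha
   (the sparser model).
2. **Bootstrap averaging**: the tuned model is refit on random 90%
   subsets drawn *without* replacement ("a random subset of 90% of the
   available lines" describes subsampling, not bootstrap resampling);
   coefficients are averaged elementwise and features ranked by
   absolute mean coefficient.
3. **Top-k selection**: OLS on the top-k ranked features, scored by
   10-fold CV; the smallest k within one standard error of the minimum
   is kept.
4. **Refit and predict**: OLS on the selected features predicts the
   held-out response.

Predictive power is the Pearson correlation of observed and LOO
predicted responses. The entire inner procedure re-runs per fold so no
information leaks; standardization parameters (mean/sd of intensity
features; mutation features stay binary) are always computed on the
training portion and applied to held-out data. A drug with fewer than
10 observed responses is marked invalid rather than fit.

Two presets share one code path: `"paper"` (alpha grid 0.1-1.0 step
0.1, 10x10-fold CV, 200 subsample fits) and `"fast"` (alpha grid
{0.2, 0.6, 1.0}, 3x5-fold CV, 50 fits, 30-point lambda path), the
desk-scale setting used by the tests. The lambda path length and fast
alpha grid are the package's own choices; the path is glmnet's default
geometric construction.

Numerical note: glmnet internally standardizes the response, which
rescales the ridge part of the penalty by sd(y). `fit_elastic_net`
remaps (alpha, lambda) so the solver minimizes exactly the stated
objective `(1/2n)||y - b0 - Xb||^2 + lambda(alpha||b||_1 +
(1-alpha)/2 ||b||_2^2)`; this is verified against the closed form on
centered orthonormal designs to machine precision.

**Known property**: the LOO Pearson correlation is a biased null
statistic. On data with no signal, the held-out prediction inherits the
training mean `mean(y[-i])`, which is negatively correlated with
`y[i]`; when the selected model is small this artifact can push the
null predictive r to noticeably negative values. Interpret weak
negative predictive powers as "no signal", not as anti-prediction.

## Perturbation dynamics

Time courses use six points {0, 4, 12, 24, 48, 72} h (baseline plus
five treatment durations). Profiles are replicate means per (protein,
line, drug, time); an entry is missing only when all replicates are.

* **IC50 screen**: per (drug, protein, time), Pearson r across lines
  against log10 IC50 (IC50 spans orders of magnitude, so the log scale
  is the meaningful one). A protein is eligible with at most 1
  non-computable time point; classification uses the mean r over
  computable points with threshold |mean r| > 0.7, the sign deciding
  resistance- vs sensitivity-association.
* **Fuzzy c-means** on z-scored mean profiles: standard alternating
  updates, memberships proportional to `d^(-2/(m-1))`, fuzzifier m = 2,
  c = 6 clusters by default (neither is stated by the analysis the
  package reproduces). Clustering is a grouping aid; the operative
  selection filters are the ANOVA/fold-change/opposition criteria, so
  the headline selection does not depend on c. Flat profiles cannot be
  z-scored and are excluded with a report. The objective is
  non-increasing by construction and memberships sum to one; as m
  approaches 1 the assignment hardens.
* **Trend calls** per (protein, line, drug): one-way ANOVA across the
  six time points (B-H adjusted across proteins within the line),
  last-vs-first fold change `2^(mean_72 - mean_0)`, and a
  monotone-consistency gate (Spearman |rho| of the mean profile against
  time >= 0.8) that operationalizes "consistently up- or
  down-regulated". A call requires adjusted p < 0.05, |FC| > 2 and the
  gate.
* **Opposite dynamics**: a protein is selected for a drug when one
  subtype group shows a *consistent* direction and the other group the
  opposite consistent direction. Consistency is a strict majority of
  the group's lines *with no contradictory call in the group*. The
  no-contradiction clause is deliberate: with 5+4 lines and strong
  per-line calls, a bare majority rule would keep "opposite" hits under
  random relabeling of the groups whenever the split is unbalanced,
  which contradicts what "consistently dysregulated" is meant to
  capture; requiring zero contradictions makes randomly relabeled
  groups collapse to near-zero retention while leaving genuine
  opposite-dynamics proteins untouched. Selection is per drug with
  union reporting by default; `dyn_intersect_drugs` switches to the
  strict "with every drug" reading.
* **Pathway consistency**: a pathway passes when at least ceil(3/5 of
  TNBC lines) and ceil(2/4 of non-TNBC lines) each carry a dysregulated
  selected member (thresholds inclusive).
* **PDPs**: per TNBC line, a 0 h vs 72 h DEP call (t test, B-H within
  line, the usual fold-change thresholds); a PDP must be a DEP in
  strictly more than 60% of usable TNBC lines ("over 60%"). The
  endpoint-vs-baseline definition is the narrowest reading of
  "persistent"; a multi-time-point persistence requirement is a
  possible stricter variant and deliberately out of scope.

## Synthetic data generator

The generator plants known structure so every stage is testable:

* **Cohort** (defaults = the study conditions): 76 lines, 39 TNBC,
  6000 proteins, 3 biological + 1 technical replicate (technical sd
  0.05 < biological sd 0.2, both log2), a +0.5 log2 batch offset on
  replicate group 4, intensity-dependent (logistic in log2 abundance,
  scale 1.5) missingness calibrated to 34.7%, per-feature protein-mRNA
  coupling calibrated to median r = 0.3, one latent factor per complex
  (the simplest mechanism giving higher within-complex than random-pair
  correlation; factor variance 0.35 of the line-level protein
  variance), log-normal abundance baselines (log2 mean 18, sd 2) to
  create the dynamic range the CV-by-abundance QC needs, and drug
  responses that are sparse linear functions of standardized protein
  features (5 planted predictors, effect 1, noise sd 0.5) on a log10
  IC50 scale.
* **Time course** (defaults): 9 lines (5 TNBC), 3 drugs, times
  {0, 4, 12, 24, 48, 72} h, 3 replicates, 1000 proteins. Planted sets
  are disjoint: monotone responders ramp log2-linearly to 4-fold at
  72 h; an opposite set ramps up in TNBC and down in non-TNBC lines
  under every drug; transient responders shift mid-course and return to
  baseline (they must *not* appear as PDPs); IC50-tracking proteins
  carry an offset proportional to the line's standardized log10 IC50 at
  every time point with per-(line, time) jitter calibrated to a target
  correlation of 0.8. Replicate noise sd is 0.2 (log2) and missingness
  is intensity-dependent with target 0.15 — the perturbation analyses
  operate downstream of the usual missing-rate filtering, so the
  analysis-ready density is higher than a raw matrix's.

What the generator does *not* emulate: peptide-level structure,
retention-time or acquisition artifacts, correlated (non-factor)
biological covariation between complexes, heteroscedastic noise by
abundance, and real mutation linkage disequilibrium. Passing tests
therefore demonstrate that the estimators recover the planted
mechanisms under realistic dimensions, noise and missingness — not that
they are robust to every pathology of real DIA data.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
the cohort generator is exercised at its full 76 x 6000 default where
the quantity under test is a cohort property (missingness, replicate
ordering, coupling), and at 12-60 lines x 60-500 features where the
quantity is an estimator property; the elastic-net recovery study uses
n = 60 lines, 500 features, 5 planted predictors, 20 seeds with the
fast preset. Every stochastic step is seeded: a single seed
reproduces generation, tuning partitions, bootstrap subsets and fold
assignments bit-for-bit, and each LOO fold derives its own seed so the
procedure parallelizes conceptually without changing results.

## Limitations

* The equal-variance Student t is the default to mirror the analysis
  reproduced here; Welch is one flag away and generally safer.
* The t test on raw correlation values (complex comparison) ignores
  the bounded support of r.
* The LOO-Pearson null bias discussed above.
* Batch centering is location-only; scale or feature-specific batch
  interactions are out of scope.
* The pathway-consistency filter treats a pathway as hit by *any*
  selected member; it does not weight by pathway size.
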