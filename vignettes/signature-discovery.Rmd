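---
title: "Age-associated tumor signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-associated tumor signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(votesig)
```

## The analysis this package implements

Hepatocellular carcinoma diagnosed in young adults (age 40 or below) behaves
differently from the elderly form: more vascular invasion, less underlying
cirrhosis, a more aggressive course. One productive way to interrogate that
difference is transcriptomic: compare tumor expression profiles between age
groups, extract a probe-set signature, show that it classifies independent
cohorts, and ask whether the signature reflects a biological program — here,
re-expression of embryonic-stem-cell (ESC) genes, i.e. tumor
dedifferentiation, quantified as transcriptome distance to reference ESC
profiles.

`votesig` implements that workflow end to end for log2-scale probe-by-sample
expression matrices: two-group differential testing with positive-FDR
q-values and a Venn intersection filter, a signal-to-noise weighted-voting
classifier with leave-one-out panel-size selection and a permutation null,
average-linkage distances of sample groups to reference profiles, classical
MDS and reference-axis PCA projection, and contingency comparisons of
clinical covariates. A synthetic cohort generator provides data with the
planted structure the analysis assumes, so every stage is testable without
any external download.

## Differential expression and the intersection filter

Per probe we use Welch's unequal-variance t statistic with
Welch–Satterthwaite degrees of freedom. The published analyses this mirrors
report only an FDR criterion, not the per-probe statistic; Welch is the
least-assumption default, and it is isolated behind `welch_t()` so a
moderated variant could be swapped in. Probes with zero spread in both
classes are assigned `t = 0, p = 1` rather than dropped, keeping the result
table aligned with the matrix.

Multiplicity is handled with the positive false discovery rate. We estimate
the null proportion with the single-point estimator
$\hat\pi_0 = \min\!\left(1, \frac{\#\{p_i > \lambda\}}{m(1-\lambda)}\right)$
at fixed $\lambda = 0.5$, then set
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j$, capped at 1. The
fixed-$\lambda$ estimator (rather than a spline over a $\lambda$ grid) is
deterministic and hand-checkable; with $\hat\pi_0$ forced to 1 it reduces
exactly to Benjamini–Hochberg, which the test suite exploits as an oracle.

A signature is every probe with $q \le$ threshold — ties at the threshold
included, so reported counts are reproducible — ordered by ascending q then
probe id. The default threshold is 0.05; stricter values (0.01, or 1e-4
for large reference designs) are arguments, not constants. The Venn-style
filter `intersect_signatures()` keeps probes differential in *both* the
age contrast (young vs elderly tumors) and the tumor contrast (tumor vs
non-tumor tissue of young patients), taking directions from the age
contrast. The tumor contrast is run unpaired: pairing is carried in the
annotations but the group-level comparison matches how such cohorts are
usually reported.

## The weighted-voting classifier

For classes 1 and 2, each probe gets a signal-to-noise weight and a decision
boundary

$$w = \frac{\mu_1 - \mu_2}{\sigma_1 + \sigma_2}, \qquad
  b = \frac{\mu_1 + \mu_2}{2},$$

with *population* (divide-by-n) standard deviations per class, the
convention of the original weighted-voting literature. A test sample $x$
casts the per-probe vote $v = w\,(x - b)$; positive vote mass $V_1$ backs
class 1, absolute negative mass $V_2$ backs class 2, the larger side wins,
and the margin is the prediction strength
$\mathrm{PS} = (V_\mathrm{win} - V_\mathrm{lose}) / (V_\mathrm{win} +
V_\mathrm{lose}) \in [0, 1]$. Exact vote ties (probability zero on
continuous data) leave a sample undecided and are counted as errors —
the conservative choice. Probes are ranked by $|w|$: a two-sided signature
contains both up- and down-regulated probes, so ranking by signed weight
would discard the down half. Ties in $|w|$ break by probe id, making panels
deterministic.

Panel size is chosen by leave-one-out cross-validation: for each held-out
sample the weights, the ranking **and** the top-k truncation are recomputed
on the remaining samples, so feature selection never sees the held-out
sample. (The optimistic variant that freezes a full-data ranking is
available as `refit_ranking = FALSE`, for comparison only; the unbiased
variant is the default because out-of-fold selection is the current
methodological standard.) `panel_scan()` evaluates a size grid in one pass
per fold and selects the **largest** size achieving the minimum error — the
largest panel with the best discrimination, which favors redundancy and
robustness over minimality.

Significance of the observed error uses a permutation null: labels are
permuted uniformly B times, the full LOOCV (including in-fold ranking) is
recomputed, and $p = (1 + \#\{e_b \le e_\mathrm{obs}\}) / (B + 1)$. The
default B = 1000 resolves p-values down to about 1/1000; because error
rates on n samples take only n + 1 values, null ties make the p-value
conservative, which the calibration test accounts for by checking the
binomial interval rather than exact uniformity.

A frozen panel can be applied to an external cohort with
`validate_panel()`, which never retrains; per-sample PS values are reported
without any "unpredicted" threshold — callers who want to abstain on weak
margins can filter on PS themselves.

## Stemness distances and ordination

The distance of a tumor group to the ESC reference is the average linkage:
the mean of all inter-group sample-pair distances, with
$\mathrm{SE} = \mathrm{sd}(\text{pair distances}) / \sqrt{n_\mathrm{pairs}}$.
Pairs sharing a sample are dependent, so this SE is approximate; a
bootstrap-over-samples SE (resampling within each group, seeded) is
available in `group_linkage_bootstrap_se()`. The default metric is
Euclidean distance on raw log2 values over the signature probes;
one-minus-Pearson and probe z-scoring are options because global
correlation-based variants are common and the choice is rarely stated in
publications. Under the generator's Gaussian model the expected squared
inter-group distance has the closed form $\sum_p \delta_p^2 + 2m\sigma^2$,
which the test suite checks directly.

Ordination uses classical (Torgerson) scaling — deterministic, exact on
Euclidean-embeddable distances, unlike stress-minimizing non-metric MDS —
and probe-centered PCA. For the differentiation axis, PCA is fitted on the
reference samples only (over probes separating ESC from day-20 hepatic
progeny) and tumor cohorts are *projected* into that fixed space, centering
with the fit cohort's means; group centroids along PC1 then order the
groups along the differentiation axis. Heat-map support is limited to
deterministic average-linkage leaf orders (items pre-sorted by id so
distance ties break reproducibly); styling is out of scope.

## Clinical comparisons

Categorical covariates are tested with Fisher's exact test, continuous ones
with the Mann–Whitney U (exact enumeration when both groups have at most 8
observations and no ties, otherwise the tie-corrected normal
approximation). The source tables that motivated this module report
medians with quartiles and do not name their tests; exact/rank tests are
the standard choice at these group sizes and are documented as assumptions.
Missing values are excluded per covariate, percentages use the
post-exclusion denominators, the denominators are always reported, and no
multiplicity correction is applied across covariates (the table is
descriptive). A zero-margin contingency table returns p = 1 with a warning
rather than an error.

`hcc_training_clinical()` ships a per-patient reconstruction of the
categorical covariates of a 23-young / 38-elderly HBV-positive surgical
training cohort, rebuilt from reported group-level counts (continuous
covariates cannot be reconstructed from summaries and are omitted). On it,
the headline rows reproduce exactly: macroscopic venous invasion 60.9% vs
10.5% and cirrhosis 17.4% vs 63.2%, both with Fisher p below 0.001.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws, on the log2 scale: per-probe baselines
$\mathcal N(7, 1.5^2)$ (typical microarray intensities), independent
Gaussian within-group noise (default sd 0.5), and a per-patient random
intercept (default sd 0.2) shared by a patient's tumor and non-tumor sample
to emulate pairing. Planted structure follows the Venn logic of the two
contrasts:

* *overlap* probes (default 30) are shifted in young tumors only — they are
  differential in both contrasts and form the target of the intersection
  filter;
* the remaining *age* probes (default 50 total age-differential) are
  shifted in all young samples — age contrast only;
* the remaining *tumor* probes (default 100 total tumor-differential) are
  shifted in all tumors — tumor contrast only.

Shift magnitude defaults to 2 log2 units with random sign per probe, so the
up/down split of a recovered signature is a testable proportion rather than
a constant. The default cohort — 20 + 20 tumor patients, 1000 probes, 50
age-differential probes at effect 2 and noise 0.5 — is the reference
condition for the package's recovery and classification properties.

Stemness is a planted differentiation axis: a disjoint set of probes
(default 300 at 2 log2 units) separates the ESC pole from the hepatic
day-20 pole, and each tumor group's mean is displaced toward ESC by its
stemness coordinate — young tumors at `stemness_gradient` (default 0.8),
elderly tumors at half that, non-tumor tissue at 0. The ESC profile
additionally carries the full age-differential pattern, reflecting the
biology being emulated (the age-associated genes of such signatures are
themselves stem-cell genes); this also gives the expected
young < elderly < non-tumor distance ordering comfortable margins under
the default design.

Structural randomness (baselines, probe assignments, signs) depends only on
the design seed; sampling randomness (patients, intercepts, noise) is
driven by a separate `cohort_seed`. Two cohorts simulated from one design
at different cohort seeds therefore behave like independent samples from
the same population on a shared platform — which is what makes frozen-panel
validation meaningful.

Deliberately **not** modeled: batch and cohort effects (cross-cohort
normalization is the caller's responsibility), probe–probe correlation
beyond the planted factors, heavy-tailed or intensity-dependent noise,
cross-hybridization, censored outcomes. Passing tests on this generator
demonstrate that the machinery recovers the structure it assumes; they do
not certify performance on data violating those assumptions, most notably
un-harmonized multi-cohort designs.

## Numerical and interface choices

* Missing expression values are a load error, never imputed: S2N weights
  and linkage distances silently bias under imputation, so the package
  fails loudly instead.
* Probe sets are the unit of analysis throughout; nothing collapses rows to
  genes.
* All selection rules are deterministic: q-ties included at thresholds,
  |w|-ties broken by probe id, the largest error-minimizing panel, items
  sorted by id before clustering.
* MDS truncates (with a warning) when fewer positive eigenvalues exist than
  requested dimensions; all-zero distance matrices embed at the origin.
* The pipeline's reference-axis threshold defaults to q < 0.01 rather than
  the stricter 1e-4 sometimes used with cohort-scale reference panels:
  with a handful of reference replicates per class the attainable Welch
  p-value floor is far above 1e-4, and a default that always selects
  nothing would be a trap. It is a config field
  (`q_reference_axis`), not a constant.
* `run_pipeline()` derives every stage seed from the master seed with fixed
  offsets (validation cohort at seed + 1, permutations at seed + 2), so a
  rerun is bit-identical and stages can be reproduced in isolation.
* The pipeline surface is the R API plus `scripts/acceptance.R`; the
  subcommand-shaped operations (`simulate`, `de`, `intersect`, `classify`,
  `distance`, `ordinate`, `clinical`, `run`) each correspond to one
  exported function.

## Problem sizes used by the test suite

The suite exercises the package at sizes chosen to make Monte-Carlo
properties stable while keeping a default `testthat` run around a minute:
the default 20 + 20 design for recovery and stemness properties (10 and 20
seeds respectively), 100 null cohorts of 12 + 12 samples by 200 probes with
99 permutations each for p-value calibration, 1000 random instances for the
vote-summation oracle, and 1000 random p-vectors for the
Benjamini–Hochberg equivalence. These are the package's own choices of
simulation size; the properties they check are scale-free.

## Known limitations

Exact reproduction of any published probe-set counts requires the original
deposited cohorts and their (unstated) preprocessing; the package instead
commits to property-based guarantees on data whose ground truth it
controls. The naive linkage SE underestimates uncertainty when groups are
small and pair distances strongly dependent (use the bootstrap variant).
The weighted-voting model is two-class only, by design. Fisher's exact test
is conservative at small counts, and the permutation p-value is discrete;
both are reported as-is rather than continuity-corrected.
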