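---
title: "Locus-specific HERV-H expression analysis: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-specific HERV-H expression analysis: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervloci)
library(dplyr)
```

This vignette is the package's own account of the science it implements:
the quantification model, the statistical procedures, the synthetic-data
generator that stands in for unpublished clinical data, and the design
decisions taken where the underlying methodology leaves room. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. Relative quantification from amplification curves

### The SDM Ct and why it is computed from a model fit

SYBR-green qPCR instruments report fluorescence per cycle. The
second-derivative-maximum (SDM) method defines the crossing cycle Ct as
the position where the curve's second derivative peaks — the point of
fastest acceleration at the start of the exponential phase. It needs no
arbitrary fluorescence threshold, which matters when many primer systems
with different plateau heights are compared.

`sdm_ct()` fits a four-parameter logistic

$$F(c) = B + \frac{A}{1 + e^{-(c-m)/s}}$$

to all 45 cycles (Levenberg–Marquardt least squares) and evaluates the SDM
in closed form: the third derivative of the logistic vanishes at
$c^\* = m - s\,\ln(2+\sqrt3)$. We deliberately chose the model fit over a
purely discrete estimate (smoothing + central second differences +
quadratic peak interpolation, still available as `method = "discrete"`).
The discrete route carries an intrinsic bias of up to ~0.3 cycles at
1-cycle sampling, because the second-derivative peak of a logistic is
asymmetric and a cubic interpolant's second derivative is piecewise linear
(its maximum snaps to integer cycles). The fit has no such bias: on
noise-free curves the recovery error is at numerical precision, and with
noise at 2% of the plateau amplitude ≥95% of curves are recovered within
0.3 cycles (both properties asserted in the acceptance suite). Fitting the
full 45-cycle trace is also what "relying on all 45 cycles to ensure
optimal curve fitting" means operationally.

A curve whose smoothed peak-to-baseline amplitude falls below
`min_amplitude` (default 0.1 fluorescence units, matched to the
generator's unit plateau) is called **censored** (`NA`); the fallback
discrete estimate is used when the fit fails on a non-flat trace.

### Amplification efficiency

The per-cycle amplification factor Eff enters the expression model
directly, so a biased Eff propagates into every RE value. The logistic
slope parameter ties the two together: during the exponential phase,
baseline-subtracted fluorescence grows as $e^{c/s}$, i.e.
$\mathrm{Eff} = e^{1/s}$. `estimate_efficiency()` therefore reuses the
same fit. A model-free alternative (`method = "expfit"`: log-linear
regression over an adaptive window at 0.5–5% of amplitude) exists for
non-logistic traces but is usable only at low noise; a naive log-linear
fit over the cycles immediately preceding the SDM is *not* offered,
because at those cycles the curve is already ~10% below pure exponential
growth, which biases Eff = 2.0 down to ≈1.84. Estimates are truncated to
the plausible range (1, 2.2]; failures return a configurable default
(2.0) with a warning. Per system, `ct_from_curves()` takes the median
across reactions — robust to occasional poor fits.

### RE, ceilings, normalization, scaling

`relative_expression()` implements $\mathrm{RE} =
\mathrm{Eff}^{\,\mathrm{Ct_{min}} - \mathrm{Ct}}$ with the series minimum
taken **per assay system over the analyzed batch** (the full input table;
restrict the table to change the batch). Conventions, in pipeline order:

* **Ceilings** (`apply_ct_ceiling()`): Ct strictly greater than the
  cohort's ceiling (defaults 33 and 32 cycles for the two cohorts) is set
  *to* the ceiling and flagged censored; a value exactly at the ceiling is
  not censored. Censored reactions keep their ceiling-derived RE instead
  of being dropped — they form the floor of the dynamic range, which
  avoids over-interpreting trace signals while keeping every sample in
  every comparison. The operation is idempotent.
* **Normalization** (`normalize_housekeeping()`): each sample's REs are
  divided by the geometric mean of its three housekeeping REs (G6PD,
  GAPDH, HPRT). A censored or non-positive housekeeping value makes the
  sample un-normalizable; it is excluded with a message and recorded in
  the `excluded_samples` attribute.
* **Scaling** (`scale_to_min()`): per system, all normalized values are
  divided by the series' smallest positive value, so the least-expressed
  sample sits exactly at 1. Idempotent; an all-zero series is an error.

The whole chain is algebraically transparent: the acceptance suite checks
that `quantify_expression()` equals a direct one-line evaluation of
$\mathrm{Eff}^{\Delta \mathrm{Ct}} / \mathrm{geomean(hk)}$, rescaled, to a
relative error of 1e-9 on 1,000 random tables.

## 2. Positivity calling

`compute_thresholds()` implements the data-driven rule: a system's
threshold is the mean + 3 SD of the scaled RE of **normal-tissue** samples
(adjacent normal colon only — not adenoma or metastasis-adjacent tissue),
and `call_positivity()` applies a strict `>` ("values greater than").
Decisions the rule itself leaves open:

* **SD convention**: sample SD (n−1). Configurable
  (`sd_type = "population"`).
* **Pooling**: thresholds are computed over all cohorts jointly, matching
  the joint scale-to-min batch; restrict the input to recompute per
  cohort.
* **Zero-variance normals** (all at the censoring floor): the threshold
  becomes mean + 1e-9, so floor-valued tumors are not called positive
  through exact floating-point ties; a message is emitted.

Under a Gaussian null, the rule's false-positive rate is the 3-sigma tail
P(Z > 3) ≈ 0.135%; the acceptance suite verifies this by fitting
thresholds on 5,000 simulated normals and applying them to 50,000
independent ones.

## 3. Cohort statistics

`compare_groups()` runs per-system two-sample t-tests: tumor vs normal,
MSI vs MSS tumors, and node-positive (N1∪N2) vs N0 tumors (the
dichotomization used for the headline nodal contrast; descriptive
three-group means are attached as an attribute). Choices:

* **Welch by default** (unequal variances); pooled Student via
  `var_equal = TRUE`. Group-wise rather than paired by default, mirroring
  how such dot-plot comparisons are usually reported; `paired = TRUE`
  exploits the tumor/normal pairing.
* **`log2(1 + x)` transform by default.** Scaled RE spans orders of
  magnitude with a point mass at the censoring floor. Null-calibration
  simulations at this package's default cohort (MSI ≈ 25 vs MSS ≈ 110)
  showed raw-scale Welch tests rejecting a true null at roughly twice the
  nominal 5%, while the log scale stays close to nominal (the acceptance
  suite measures the null rate over 200 replicate cohorts at
  Monte-Carlo resolution). Raw-scale tests remain available
  (`transform = "identity"`).
* **No multiple-testing correction by default** — the per-system stars
  (`*`, `**`, `***` at p < 0.05/0.01/0.001, strict boundaries) are
  reported the way such screens conventionally present them;
  `adjust = "BH"` adds Benjamini–Hochberg-adjusted p-values.

`combined_herv_value()` collapses the target loci to one value per sample
for family-level comparisons. No standard combination rule exists for
"all loci combined" dot plots; `max` (default), `mean` and `sum` are
offered and the rule used is recorded in the output.

## 4. Marker panels

`evaluate_panel()` implements the any-positive (OR) rule — a sample is
panel-positive when at least one member locus is called — against explicit
case and control classes (the control set behind published panel
percentages is rarely fully specified, so it is a parameter, defaulting to
adjacent normal tissue). Confusion-matrix counts come with Wilson 95%
intervals, chosen over Wald for their small-sample behaviour in strata
like the ~20-sample adenoma group. `select_top_expressed()` ranks target
systems by positivity frequency in a class; ties break by higher mean
scaled RE, then name, and the ranking table is attached. Only the OR rule
is implemented; AND/k-of-n rules and ROC analysis over continuous scores
are out of scope (the evaluated performance is apparent performance, no
cross-validation).

## 5. Insertion dating from primate orthology

A provirus present in the genomes of human and another primate must
predate their divergence, so `assign_age()` dates each locus by the split
age of the **most distant** species carrying it. Supporting conventions:

* `species_age_table()` ships round-figure divergence ages for the
  12-primate panel (chimp 6.6 My … bushbaby 63.7 My). These are external
  constants transcribed from the primate phylogenetics literature, not
  results of this package; supply your own via `read_species_ages()` or an
  ultrametric Newick tree (`species_ages_from_tree()`). Same-clade species
  share a split age, so the table is validated as non-decreasing rather
  than strictly increasing.
* `presence_from_coverage()` calls a locus present at ≥ 50% aligned
  coverage by default — a documented convention, since published
  extraction pipelines rarely state their exact criterion.
* `flank_orthology_check()` guards against paralogous alignments:
  ungapped identity over 500 aligned flanking positions must reach 0.7
  (positions with gaps or N excluded from both numerator and
  denominator). Both cutoffs are parameters.
* Non-monophyletic presence rows (a closer species missing the locus —
  lineage-specific deletion or alignment dropout) are still dated by the
  most-distant rule but flagged with a presence-gap warning.

`rank_sum_test()` compares age distributions: exact enumeration of the
Mann–Whitney null when both groups have ≤ 8 tie-free observations,
otherwise the normal approximation with tie and continuity correction
(fully tied data return p = 1 by convention — no ordering information).
`compare_category_ages()` runs the four contrasts of interest
(CRC-specific vs silent, vs constitutive, vs both pooled, and silent vs
constitutive), skipping empty categories with a message.

## 6. Chromatin overlap scoring

`interval_overlap()` counts the bases an LTR shares with the union of a
peak set (BED conventions: 0-based, half-open, strand-agnostic; merged
first so no base is double-counted). "Overlap score" is ambiguous between
peak-signal averaging and coverage; `mean_mark_overlap()` uses the
**LTR-coverage fraction** (overlap bases / LTR length, in [0, 1]) because
it is reproducible without peak signal values, then averages across the
cell lines with data for each mark (marks without data are dropped with a
warning). `mark_class_enrichment()` summarizes each locus by its mean
score over the activating marks — `H2az, H3k4me1/2/3, H3k9ac, H3k27ac` by
default — and separately over the repressive marks (`H3k9me3, H3k27me3`),
then contrasts CRC-specific loci against silent + constitutive loci with
the rank-sum test above. The mark partition is configuration, not
hard-coded; DNase or TFBS interval sets can be scored through the same
functions.

## 7. The synthetic cohort generator

No per-sample clinical data are publicly available for studies of this
kind, so `simulate_cohort()` generates the full input bundle with recorded
ground truth. What it emulates:

* **Design**: two biobank cohorts (70 + 69 tumor/normal pairs by default)
  with different Ct ceilings (33 vs 32 cycles); optional unpaired adenoma
  and liver-metastasis samples; 12 assay systems — 5 HERV-H target loci,
  a colon-tissue positive and a negative HERV-H control, tumor markers
  MMP7 and OPN, housekeeping G6PD/GAPDH/HPRT.
* **Positivity model**: marginal tumor positivity per target locus of
  0.50, 0.33, 0.27, 0.22, 0.17 — the frequency ordering such screens
  report. MSI status (22% of tumors) and nodal status (N0/N1/N2 =
  45/35/20%) modulate expression as odds ratios on the tumor probability;
  the baseline logit is solved numerically so the configured marginal is
  preserved exactly. Defaults: a strong MSI odds ratio (8) for the three
  MSI-representative loci, an opposite mild trend (0.6) for the
  chromosome 5 locus, nodal odds ratio 4 for the chromosome 5 and 20
  loci. Directions mirror the reported associations; magnitudes are
  simulation conventions chosen once (power analysis at design time: the
  boosted loci are detectable at the default cohort size, which is what
  the replicate-level acceptance check asserts). Normal tissue is never
  expressed at the target loci by default — with the mean + 3 SD rule the
  occasional normal positive still arises from floor-value variation, as
  in real screens.
* **Values**: expressed reactions draw Ct uniformly from 22–30 cycles;
  housekeeping Ct is N(20, 1); non-expressed reactions sit exactly at
  their cohort ceiling, flagged censored. These distributions are simple,
  controllable conventions — *not* estimates of the unpublished clinical
  distributions.
* **Curves**: `simulate_amplification_curve()` produces logistic traces
  whose SDM lands exactly on the requested Ct and whose slope encodes the
  requested efficiency, plus optional Gaussian noise.
* **Evolution**: `simulate_presence_matrix()` samples an insertion node
  per locus from category-specific distributions (CRC-specific loci
  young — chimp/gorilla nodes; silent and constitutive loci old — gibbon
  and beyond; gonads-restricted in between) and derives phylogenetically
  consistent presence patterns; a noisy mode flips presences to exercise
  the presence-gap path.
* **Chromatin**: `simulate_peak_sets()` emits peaks overlapping
  CRC-specific 5′ LTRs with probability `enrichment` for activating marks
  and `background` otherwise, over three cell lines, plus non-overlapping
  decoy peaks.

What it does **not** emulate: plate effects, primer-specific melting
behaviour, RNA-quality covariates, inter-run calibration, correlated
expression between loci of the same sample beyond the shared strata, and
real Ct value distributions. Passing tests therefore demonstrate that the
*pipeline arithmetic and inference machinery* behave as specified under
known ground truth — not that any particular clinical effect size is
reproduced.

## 8. Problem sizes and determinism

Every generator accepts a `seed` and is exactly reproducible. The test
suite uses cohorts of the default size (139 pairs) where cohort structure
matters, 200 replicate cohorts for the null-calibration check, 1,000
random tables for the quantification identity, 500 curves per noise level
for Ct recovery, 1,000 loci for age recovery and 10,000 random instances
for the interval-arithmetic oracle — sizes chosen so each property is
measured at meaningful Monte-Carlo resolution while the suite stays quick
to run. `scripts/acceptance.R` re-computes the headline quantities from
scratch at the same cohort size under a caller-supplied seed.

## 9. Known limitations

* The SDM and efficiency estimators assume a roughly sigmoidal trace;
  curves with drifting baselines or bi-phasic amplification will fall back
  to the discrete estimate or the default efficiency.
* Censored-at-ceiling values make the expression scale left-censored;
  group tests treat them as ordinary (floor) values rather than modelling
  the censoring explicitly.
* The mean + 3 SD rule's specificity guarantee is distributional; with
  strongly expressed normal outliers the threshold inflates and
  sensitivity drops — visible in the simulated tumor markers (MMP7/OPN),
  whose normals do express.
* Insertion dating is bounded by the species panel: a locus present in
  all 12 primates is at least as old as the bushbaby split, not exactly
  that age, and same-clade ties make the defining species non-unique (the
  age is still unique).
* Panel performance is apparent (resubstitution) performance.
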