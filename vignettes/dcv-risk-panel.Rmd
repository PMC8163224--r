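---
title: "Predicting delayed cerebral vasospasm risk from a biofluid miRNA panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting delayed cerebral vasospasm risk from a biofluid miRNA panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcvmir)
```

## The problem and the model

About one third of aneurysmal subarachnoid hemorrhage (aSAH) patients
develop delayed cerebral vasospasm (DCV) 3–10 days after rupture. The
clinical question this package addresses computationally is whether the
miRNA content of cerebrospinal fluid (CSF) sampled at post-bleed day 3
(PBD3) — before DCV onset — carries enough signal to call DCV risk per
patient.

The measurement model is a custom TaqMan low-density RT-qPCR array of
brain- and vasculature-injury-related miRNAs (packaged as `dcv_panel()`;
one rodent-specific assay control is flagged non-analyzable and the
array's mandatory U6 control is excluded outright). Each well yields a
relative threshold cycle (Crt): lower Crt means higher abundance, one
cycle is a twofold change on the raw scale.

Three processing rules define the analyzable data:

* **Censoring**: Crt ≥ 35 cycles, or a failed instrument QC flag, is
  *undetectable*. The limit is a property of the chemistry and is fixed.
* **Detectability**: a miRNA is retained in a fluid only if detectable in
  at least ⌈2/3 · n⌉ of that fluid's specimens, pooled over days and
  groups. (The complementary phrasing — removed when undetected in one
  third — is the same rule.)
* **Normalization**: the panel is too condition-focused to contain a
  stable endogenous normalizer, so each sample is normalized against its
  own global mean: ΔCrt = Crt_target − Crt_geomean, the location being
  the geometric mean of the sample's detectable, retained Crt values.
  Heatmap-style displays use −ΔCrt so that up is more abundant.

The geometric/arithmetic ambiguity deserves a note: classical global-mean
normalization averages expression on the linear scale, which corresponds
to the arithmetic mean of the cycle values; the formula stated with the
Crt method uses the geometric mean *of the cycles* instead. The two
differ by less than 0.1 cycle for typical spreads (the geometric mean of
values 28 ± 2 lies about `r round(28 - exp(mean(log(c(26, 28, 30)))), 3)`
cycles below the arithmetic mean). We implement both behind
`normalize_global_mean(variant =)`, defaulting to `"geometric"` to follow
the stated formula verbatim. The arithmetic variant is exactly zero-sum
per sample and exactly shift-invariant; the geometric variant is neither,
which the test suite documents rather than hides.

## From screening to a classifier

**Differential screening.** Each retained miRNA is compared by two-tailed
Student's (pooled-variance) t-tests over six comparisons per fluid: DCV+
vs DCV− at PBD3 (I) and PBD7 (II), and each patient group/day against
healthy controls (III–VI). Welch's form is available behind a flag but is
not the default, matching the named test. No multiple-testing correction
is applied by default — the screen mirrors the per-miRNA testing
convention of the field; a Benjamini–Hochberg option exists as a clearly
labelled extension. Star codes follow the usual legend with intervals
closed on the smaller-p side (\*\*\*\*: p < 1e-4; \*\*\*: [1e-4, 1e-3);
\*\*: [1e-3, 0.01); \*: [0.01, 0.05); ns otherwise), so the mapping is
total and non-overlapping; undetermined results (removed miRNA, or fewer
than two observations in a group) are coded `UD`.

**ROC discrimination.** The empirical AUC is computed by tie-corrected
pairwise counting, `[#(pos > neg) + 0.5·#ties] / (n_pos · n_neg)`, after
per-miRNA orientation (a miRNA votes DCV+ on the side of its own DCV+
group mean; ties orient to "higher is DCV"). The ROC curve enumerates
thresholds at every distinct score; its trapezoidal area equals the
pairwise statistic identically, which is asserted on random instances.
AUC = 1 is equivalent to disjoint oriented supports, and those *perfect
separators* are the panel's strongest assets.

**Classifiers.** Model building is restricted to the complete-data
candidate pool (`complete_candidates()`): miRNAs with no missing ΔCrt in
the training stratum. Each perfect separator becomes a single-miRNA
threshold predictor with the cutoff at the midpoint of the empty interval
between the training groups — the unique symmetric choice; since the
derivation of published cutoffs is not specified, the cutoff is exposed
as an overridable parameter so external values can be injected verbatim.
Votes use a strict inequality, so a value exactly at the cutoff votes
DCV−. The remaining candidates feed a CART decision tree written from
scratch: Gini impurity, thresholds at midpoints between consecutive
distinct values, greedy minimization of the weighted child impurity, and
deterministic tie-breaks (lowest impurity, then earliest variable in
column order, then smallest threshold). The stopping defaults
(`min_split = 2`, `min_leaf = 1`, `max_depth = 5`, zero impurity
penalty) are chosen so that an 18-subject training cohort *can* be fit
perfectly — the shipped defaults of general-purpose CART implementations
(minimum node size 20) could never split such a cohort. There are no
surrogate splits: a missing value at prediction time makes the predictor
abstain, recorded distinctly.

**Consensus.** The eight predictors vote; the panel calls DCV+ (or DCV−)
when at least five votes agree, and is indeterminate otherwise.
Abstentions count for neither side, and indeterminate calls are scored as
incorrect — the conservative choice. Accuracies are reported as
nearest-integer percentages (13/15 → 87, 14/15 → 93, 11/15 → 73).

## What the synthetic cohorts emulate — and what they do not

Patient-level data are not printed in any public table, so every
cohort-level claim is exercised on synthetic cohorts with planted
structure (`synthetic_config()`, `generate_cohort()`):

* Group sizes 8 DCV+ / 10 DCV− / 8 HC; patients sampled in both fluids at
  PBD3 and PBD7, controls once per fluid.
* Crt is normal per (miRNA, group, fluid, day) around a baseline of 28
  cycles with SD 1 — normality is exactly the assumption the t-test
  screen makes, and Crt ≈ 28 is a typical mid-dynamic-range value for
  biofluid miRNA assays.
* Six *low-expression* miRNAs per fluid (the sets named in the removal
  lists) are centred so that a draw exceeds the detection limit with
  probability 0.8 — comfortably beyond the one-third removal threshold —
  so the detectability filter removes exactly the planted sets.
* Seven planted separators at (CSF, PBD3) shift 8 SD towards higher
  abundance in DCV+, and their group ranges are additionally guaranteed
  disjoint by at least 4 SD by post-draw shifting (shifting, not
  rejection sampling, so feasibility holds at any seed).
* 37 of the 40 retained CSF miRNAs and 29 of the 40 retained plasma
  miRNAs carry a ±2.5 SD DCV+/DCV− shift at PBD3; PBD7 carries none,
  mirroring the attenuation of the signal by day 7. Healthy controls sit
  halfway between the patient groups.
* Missingness is completely at random at rate 0.03 (no mechanism is
  described for the real data, so the neutral choice is MCAR).

Two design details matter for reproducibility of the *counts*:

* **Sign balancing.** Global-mean normalization subtracts a per-sample
  location, so planted shifts leak into every other miRNA's ΔCrt at rate
  1/40. The planted signs are therefore chosen so the *log-scale* sum of
  the shifts (the scale the geometric mean averages) is as close to zero
  as possible; unshifted miRNAs then really are null on the ΔCrt scale,
  and the t-test's size on them stays nominal.
* **Anti-separation.** "Exactly seven separators" is only reproducible if
  non-separator miRNAs never come out disjoint by luck. After drawing,
  any accidentally separated non-separator at (CSF, PBD3) is nudged back
  into overlap (one DCV+ value moved 1.25 SD inside the DCV− ΔCrt range),
  iterating against the actual normalizer until the separator set equals
  the planted set. Separator cells at (CSF, PBD3) are likewise exempt
  from random missingness so they always satisfy the complete-data
  candidate rule.

`generate_pattern_cohort()` constructs test cohorts realizing an exact
per-predictor correctness pattern: threshold votes are placed 0.5 cycles
on the requested side of each cutoff, tree votes are routed down a leaf
path of the requested class with 0.3 cycles of clearance at every split,
and the remaining miRNAs balance each sample to zero mean shift so the
targeted ΔCrt values survive normalization to within a few hundredths of
a cycle. An infeasible pattern (no reachable leaf of the requested class
consistent with the threshold assignments) is an error naming the
conflict, not a silent approximation.

What passing these tests does **not** show about real data: the generator
draws independent normal values per cell, so it cannot speak to
heavy-tailed qPCR noise, plate effects, correlated miRNA co-regulation,
informative missingness, or the clinical heterogeneity behind the two
mispredicted cases of the published test cohort. It validates the
*machinery* — filtering, normalization arithmetic, screening calibration,
separator recovery, classifier construction, vote bookkeeping — not the
biology.

## Numerical choices and degenerate inputs

* Detection uses a strict `Crt < limit`; a value exactly at the limit is
  undetectable.
* A sample with fewer than two detectable values cannot support a
  location and is excluded with a warning; an empty fluid yields an empty
  removal set with a warning.
* t-tests fall back to an undetermined (`UD`) result, not an error, when
  a group has fewer than two observations; Fisher's exact test returns
  p = 1 with a warning on a zero margin.
* AUC ties contribute 0.5 per pair (midrank convention).
* CART leaf ties go to DCV− (the conservative call for a risk panel); a
  constant feature matrix yields a single majority-class leaf.
* Tree routing sends values strictly below the threshold left; thresholds
  are midpoints of observed values, so training data never sit on a
  boundary.
* All randomness flows from one integer seed; cohort generation saves and
  restores the caller's RNG state.

## Problem sizes used by the test suite

The suite runs the full planted cohort (46 panel miRNAs × 88 samples) for
the headline checks; calibration properties use 200 replicate null
cohorts for the t-test's size, 200 random instances for the
ROC-equivalence property, 100 random small datasets for the CART
root-split oracle, 12 seeds for planted-effect recovery and 20 for
censoring calibration — sizes chosen to make the binomial bounds
informative while keeping the default run in the minutes range.

Recovery of the planted significance *counts* is stochastic by design:
a planted 2.5 SD effect is missed occasionally and a null miRNA rejects
at the nominal 5%, so counts are checked within the design's stochastic
tolerance rather than as exact equalities, and the null false-positive
count is checked against central 99% binomial bounds (an "at least 95%
specificity" reading would sit exactly on the expected value and flip a
fair coin).

## Known limitations

* The packaged panel table carries the 46 analyzable human miRNAs
  recoverable from the published panel listing.
* The decision tree is intentionally minimal CART: no surrogate splits,
  no cost-complexity pruning, no cross-validation — the training cohorts
  are far too small for any of those to be meaningful, and the published
  model used none.
* Cutoff derivation for threshold predictors is the gap midpoint; other
  conventions (Youden-optimal, group-mean midpoint) would differ on real
  data but are indistinguishable on disjoint training groups.
* `INDETERMINATE` consensus calls are scored incorrect; an application
  wanting a "refer for closer monitoring" third class would score them
  differently.
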