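---
title: "Quantitative CT emphysema metrics and lobar phenotyping: methods"
author: "qctemph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT emphysema metrics and lobar phenotyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctemph)
```

# The problem

In alpha-1-antitrypsin deficiency (AATD), loss of antiprotease protection
leads to early panlobular emphysema. Quantitative CT (QCT) scores this
destruction from the attenuation histogram of the segmented lung: healthy
inflated parenchyma sits around −789 HU (roughly −750 to −850 HU), while
emphysematous voxels, being mostly air, drop below −950 HU. `qctemph`
implements the voxel-level metrics, a lobe-wise distribution phenotype, and
the cohort statistics layer that links that phenotype to clinical
covariates. Lung and lobe segmentation are upstream inputs: the package
consumes a CT volume plus a co-registered mask with labels 1–6 for RUL,
RML, RLL, LUL, LLi, LLL (in that fixed reporting order) and 0 for non-lung.

# Density metrics

For a region $R$ (one lobe, one lung, or the whole lung):

* **MLD** is the arithmetic mean attenuation over $R$.
* **EI** is $100\,|\{v \in R: \mathrm{HU}_v < -950\}| / |R|$. The
  comparison is *strict*: a voxel at exactly −950 HU is parenchyma. The
  threshold is a config key (`thresholdHU`), −950 HU by default.
* **PD15** is the 15th percentile of the attenuation distribution of $R$,
  computed by linear interpolation between order statistics (the inclusive
  convention, `stats::quantile` type 7). The convention matters only at the
  third decimal on realistic region sizes, but it is pinned by a
  brute-force sort-and-interpolate oracle in the tests so the choice is
  explicit. PD15 falls as emphysema adds mass to the left tail.
* **Volume** is the voxel count times the physical voxel volume
  (spacing is carried in mm; output in cm³).

Whole-lung EI is exactly the voxel-count-weighted mean of the lobar EIs;
the test suite asserts this identity on every phantom.

# Emphysema-type indices

The three morphology indices characterise *how* the emphysema voxels are
arranged, not just how many there are. The voxel-set definitions need
operative choices that clinical descriptions leave open; each choice is a
config key and every report embeds the effective configuration.

* **ET1** $= 10\,|\mathrm{inner}|/|\mathrm{border}|$. A border voxel has at
  least one face-adjacent (6-neighbourhood) voxel that is not emphysema;
  non-lung and out-of-grid neighbours count as not-emphysema, so clusters
  touching the image boundary keep a border. A single voxel scores 0; solid
  balls score higher with radius (a monotonicity the tests check by
  exhaustive neighbour scans). Cluster *labelling* uses 26-connectivity;
  the 26/6 pairing for foreground/boundary avoids the topological
  paradoxes of matching connectivities.
* **ET2** $= 100\,|\mathrm{peripheral}|/|\mathrm{emphysema}|$. Peripheral
  voxels lie within `rimMm` (default 2.0 mm) of the nearest non-lung
  voxel, by an exact anisotropic Euclidean distance transform
  (Felzenszwalb–Huttenlocher separable parabola method, implemented in
  C++). Distances are voxel-centre to voxel-centre. 2 mm captures the
  subpleural layer at typical reconstruction spacings without swallowing
  deep parenchyma. Distance is always measured against the *whole-lung*
  surface, also for per-lobe ET2: interlobar fissures are pleural surface,
  but a lobe's deep voxels should not become "peripheral" merely because a
  different lobe is nearby in a per-lobe crop.
* **ET3** $= 100\,|\mathrm{panlobular}|/|\mathrm{emphysema}|$. The lung is
  partitioned into axis-aligned cubes of edge `lobuleMm` (default 15 mm,
  the scale of a secondary pulmonary lobule) clipped to the lung; a
  pseudo-lobule with within-lobule emphysema fraction ≥ `destroyFrac`
  (default 0.8) counts as destroyed, and ET3 is the share of emphysema
  voxels inside destroyed pseudo-lobules. The index stays near 0 for
  scattered centrilobular disease and approaches 100 only when essentially
  whole lobules are gone — the panlobular pattern. The cubic partition is
  a deliberate simplification: real secondary lobules are irregular
  polyhedra, and no segmentation of them is attempted.

With zero emphysema voxels, ET1–ET3 are reported as 0 together with a
`degenerate` flag rather than failing, so cohort tables stay rectangular.

# Distribution phenotype

Lobar EIs are aggregated into three zones — upper (RUL, LUL), mid (RML,
lingula) and lower (RLL, LLL) — as the *unweighted* mean of the two lobes'
EIs. An unweighted mean is the simplest reading of a "regional average
EI" and reproduces the expected classification of the worked examples in
the test suite; a volume-weighted variant sits behind
`qctConfig(zoneWeighting = "volume")` for sensitivity analyses.

A case is **heterogeneous** when the zone spread (max − min) is *strictly*
greater than `heterogeneityPts` (default 15 percentage points); a spread
of exactly 15 is homogeneous. For heterogeneous cases the predominant type
is the argmax zone. Exact argmax ties are measure-zero on real data but
possible on constructed input; they resolve deterministically upper > mid
> lower and carry a `tie` flag — silent nondeterminism would be worse than
an arbitrary documented order.

# Cohort statistics

**Serum groups.** Severity is defined on serum AAT: severe ≤ 40 mg/dl,
moderate (40, 70], reduced-to-normal > 70. A stated "41–70" band leaves
the open interval (40, 41) unassigned; it goes to moderate, since severe
is explicitly "≤ 40". Eligibility in the reduced-to-normal band requires a
deficiency allele and is reported as a flag, not a group change.

**Group comparisons.** Categorical variables use Pearson's chi-square on
the group × level table without continuity correction (a warning flag is
raised when an expected cell is below 1). Continuous variables use
Student's t-test for two groups; for three or more, one-way ANOVA as the
k-group extension of the two-sample test, with Kruskal–Wallis behind
`rankBased = TRUE` as the rank-based alternative. Which test produced a
given p-value is always part of the output, since "as appropriate" choices
are otherwise unauditable.

**Stepwise logistic regression.** The mid-predominant outcome is modelled
with forward selection and backward pruning on likelihood-ratio p-values:
entry when the best add-one p < `alphaEnter` (default 0.05), removal when
a selected term's drop-one p > `alphaRemove` (default 0.10). These
defaults mirror the common stepwise defaults of commercial statistics
suites. The final model is refit with selected terms plus any forced
adjustment covariates (conventionally sex and BMI), and reported with
odds ratios $\mathrm{OR} = e^B$ and Wald 95% CIs
$e^{B \pm 1.96\,\mathrm{SE}}$. Note the exponentiated coefficient of a
logistic model is an odds ratio; this package never labels it a hazard
ratio. Rows with missing model inputs are dropped and counted
(`n_dropped`). Quasi-complete separation is detected from runaway
coefficients and raised as an error naming the separating term. A zero
deviance change makes the LRT p-value undefined; such candidates are
treated as p = 1 (nothing to add, or removable), which keeps degenerate
null-simulation replicates well-defined.

# Synthetic data

The generators are first-class, tested code: they define the conditions
under which everything else is verified.

**Phantoms.** Two ellipsoidal "lungs" on a soft-tissue background, each
split into three lobes by axial planes at the 40%/60% z-quantiles of its
voxels (axis 3 is superior–inferior). Each lobe is trimmed to a voxel
count divisible by 100, so any integer-percent EI target is hit *exactly*
by assigning exactly $k = n\,t/100$ voxels to emphysema. Attenuation is
drawn from normals truncated at the −950 HU boundary (parenchyma −789 ± 25
HU on [−950, −600]; emphysema −980 ± 15 HU below −950), so noise can never
move a voxel across the threshold and the EI ground truth stays exact at
any noise level. Placement modes: `mixed` (compact clusters with
geometric-ish sizes around `clusterVoxels`), `subpleural` / `core`
(nearest to / farthest from the pleural surface first, giving ET2 = 100
and 0 by construction), and `whole-lobule` (only pseudo-lobules wholly
contained in one lobe are destroyed, giving ET3 = 100 by construction; the
achieved EI, recorded in the truth, is the closest whole-lobule sum not
exceeding the target — and can be 0 for the thin mid-zone slab, which is
often too thin to contain a complete 15 mm pseudo-lobule). The default
grid is 96³ at 1 mm isotropic — under two seconds to generate, large
enough for rim and lobule geometry; the test suite mostly uses 48³ for
speed.

What the phantoms do *not* emulate: anatomical lobe shapes, airways and
vessels, scanner noise texture and reconstruction kernels, or attenuation
drift with inspiration depth. Passing tests therefore demonstrate metric
correctness against controlled geometry, not robustness to
segmentation error or acquisition artifacts on clinical data.

**Cohorts.** Three serum-defined groups with defaults typical of a
monocentric AATD referral cohort — sizes 13/16/46 and serum means 88.5,
57.9 and 16.7 mg/dl — with serum drawn from truncated normals confined to
each group's band, covariates (age, sex, BMI, pack-years, FEV1 %pred, RV)
from group-specific truncated normals, and genotype labels from
group-typical frequencies. The mid-predominant outcome follows a planted
logistic model, log-odds $= \beta_0 + \beta_{age}\,age +
\beta_{serum}\,serum$, defaults $(-2.2, +0.06, -0.05)$; the intercept is
set so the marginal outcome rate is near 30% at the cohort's covariate
means, matching a plausible phenotype prevalence. Truncation shifts group
means slightly towards the band interior (most visibly for the severe
band, truncated at 0); tests allow for this.

Both generators restore the caller's RNG state and are bit-reproducible
for a given spec and seed.

# Numerical and interface choices

* Reported summaries round half *away from zero* to one decimal, matching
  how clinical tables are conventionally printed; full precision is kept
  internally and in JSON outputs.
* Structural errors (shape mismatches, unknown columns) and domain errors
  (empty regions, degenerate outcomes) are distinct condition classes;
  the file-based entry points map them to status codes 3 and 4, with 2
  for QC failure and 0 for success.
* QC checks cover slice thickness (z spacing ≤ 1.25 mm), lung HU range,
  the mask label set, and lobe presence; a missing lobe is a warning (its
  metrics are reported missing, not zero), a thick reconstruction is a
  failure that `overrideQc = TRUE` can bypass.
* Every JSON output embeds the effective configuration and package
  version; reruns on identical input are byte-identical.

# Problem sizes

The test suite runs phantoms at 48³–64³ (one 96³ default in the README
example), 200 randomized morphology-oracle grids up to 20³, and the
stepwise simulation study at n = 300 with 200 effect replicates and 400
null replicates; the whole suite completes in about a minute on one CPU.
These sizes were chosen as the smallest at which the geometric features
under test (2 mm rims, 15 mm lobules, three z-zones) are comfortably
resolved.

# Limitations

* The ET2/ET3 voxel-set definitions are explicit operative stand-ins
  (2 mm rim; 15 mm cubic pseudo-lobules at 80% destruction); other QCT
  implementations use different, sometimes undocumented, definitions, so
  absolute ET2/ET3 values are comparable only within one parameterisation.
* Whether production QCT software treats a voxel at exactly −950 HU as
  emphysema is generally unstated; this package is strict, and the choice
  moves EI only by the measure of exact ties.
* The three-zone classifier ignores within-zone asymmetry (a purely
  unilateral process can still be "upper-predominant").
* No lung/lobe segmentation, airway analysis, vessel volume, or DICOM
  ingestion: masks and HU volumes are inputs.
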