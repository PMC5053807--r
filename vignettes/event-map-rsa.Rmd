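---
title: "Measuring spatio-temporal event maps with pattern-similarity change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatio-temporal event maps with pattern-similarity change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventmapr)
```

## The scientific question and the measurement model

When people learn where and when a series of events happened — here, objects
encountered along a fixed route through a virtual city — the memory system is
thought to organize them into a relational *event map*: a representation in
which events that are close in space or in time are also close neurally.
`eventmapr` implements a complete analysis pipeline for testing this idea
with multivoxel fMRI pattern similarity, together with a synthetic-data
generator that reproduces the structure of such an experiment end to end.

The design the generator emulates has five ingredients:

1. **A route with teleporters.** Sixteen objects sit at 2D positions along a
   one-way route. Spatial distance between two objects is Euclidean;
   temporal distance is the summed traversal time of the route segments
   between them. Three teleporter segments traverse a large spatial span in
   a fixed ~2 s, which decorrelates the two distance structures.
   `generate_route()` resamples layouts until the pair-level correlation
   between z-scored spatial and temporal distances is below 0.1 in
   magnitude and all four cells of the high/low × high/low median-split
   factorial are occupied.
2. **Distance-judgment behavior.** For each of the 120 object pairs,
   subjects rate spatial and temporal distance on a bounded slider.
   `generate_behavior()` models a rating as a logistic squash of
   `own_weight · z(own distance) + cross_weight · z(other distance) + noise`.
   The default weights (0.50/0.17 for spatial ratings, 0.65/0.16 for
   temporal ratings) and noise levels reproduce the group-level accuracy
   correlations (~0.49 spatial, ~0.64 temporal) reported for this kind of
   task; the cross-domain terms create the characteristic leakage that the
   error-bias analysis detects.
3. **A picture-viewing task (PVT) shown twice.** Each of 17 object pictures
   (16 learned plus a target) appears once per block in 12 blocks — 204
   trials, with stimulus-onset asynchronies of 2 or 3 TRs balanced 50/50
   and drawn at random. `generate_pvt_recipe()` rejects candidate trial
   lists in which a one-way ANOVA of trial position by object is
   significant at α = 0.05, so no object is systematically early or late;
   the accepted recipe is reused verbatim for the pre- and post-learning
   session, which removes all timing differences between sessions.
4. **Pre/post 4D volume series.** `generate_volumes()` writes each trial's
   object pattern into the volume two after the onset volume and fills
   everything with Gaussian noise. There is deliberately no hemodynamic
   model: the analysis selects exactly that volume (the third after onset,
   4.54–6.81 s post-stimulus at TR 2.27 s), so convolving with an HRF would
   only re-derive the selection rule; the acceptance surface of the package
   is the RSA statistics, not HRF modeling.
5. **A ground-truth effect.** Inside a designated effect region the
   post-session object patterns are drawn with a target correlation
   structure whose pairwise increments mix a rank transform of a distance
   model with an orthogonal random profile, weighted `α : sqrt(1 − α²)` with
   `α = |effect_size|`. The *expected* pattern-similarity change therefore
   has Spearman correlation ≈ `effect_size` (negative: remembered-close
   pairs gain the most similarity) with the model. The realized per-subject
   correlation is attenuated by pattern-estimation noise — finitely many
   voxels and repetitions — exactly as in real data; with the default
   27-voxel regions and trial noise 0.3 a subject typically shows
   ρ ≈ −0.25, which the first-level z translates into strong evidence.

## The analysis pipeline

**First level.** Motion parameters are regressed out of every voxel's time
series (`regress_motion()`); the third volume after each onset is extracted
over the analysis mask and target trials are dropped
(`select_trial_volumes()`). Every trial's voxel pattern is Pearson-correlated
with every other trial's, excluding same-block combinations — slow noise
shared within a block would otherwise inflate similarity — and correlations
are averaged per object pair (`crosscorr_matrix()`; with 12 blocks each
cross-object cell averages 132 combinations and each same-object cell 66).
Subtracting the pre-learning from the post-learning matrix gives the
pattern-similarity change PS′ (`ps_change()`), whose 120 off-diagonal pair
values are compared with a distance model by Spearman correlation
(`model_correlation()`). Five models are standard: remembered spatial,
remembered temporal, their product (`combined_model()`, low = close in both
dimensions), and each domain after the other has been removed from PS′ by
OLS residualization (`residualize()`). The observed ρ is standardized
against correlations of randomly shuffled pairings
(`subject_shuffle_z()`, default 10,000 shuffles), yielding a per-subject z.

**Second level.** Subject z values are tested against zero with a sign-flip
test (`signflip_group_test()`, default 10,000 flips, exhaustive enumeration
engaged automatically when `2^n ≤ 2^20`), one-tailed in the negative
direction because the hypothesis is directional (closer remembered ⇒ larger
similarity gain). P values are Benjamini–Hochberg corrected over the full
ROI × model family (`fdr_adjust()`): 15 tests for the remembered-distance
analysis (3 ROIs × 5 models), 9 for the objective-distance analysis. The
objective distances additionally support a 2 × 2 within-subject ANOVA of
PS′ averaged in the high/low space × time cells
(`objective_2x2_anova()`), computed through exact paired-contrast t
equivalence (F(1, n−1) = t²) rather than a general mixed-model fit.

**Searchlight.** `build_spheres()` forms a sphere (default radius 9 mm,
6 voxels at 1.5 mm isotropic; spheres keeping fewer than 30 grey voxels are
dropped) around every mask voxel; `searchlight_map()` replays the ROI
computation inside each sphere and writes ρ at the center. Group inference
(`group_searchlight()`) uses a per-voxel one-sample T with family-wise
correction by the sign-flip max-statistic distribution, optionally
restricted to a small-volume mask. Max-statistic correction was chosen over
threshold-free cluster enhancement because it gives exact, assumption-light
FWER control that can be verified against enumeration; TFCE is an extension
point, not implemented.

## Numerical and design choices

* **Pair order.** All pair vectors use the row-major upper triangle
  ((1,2), (1,3), …); `pair_indices()` is the single source of truth.
* **Correlation types.** Trial-pattern similarity is Pearson (the RSA
  default); model fits are Spearman with average-rank ties. Cell means
  average raw coefficients; a Fisher-z averaging option exists.
* **Shuffle scheme.** The first-level null permutes the 120 pair entries
  freely. Pair-level shuffles ignore the dependence structure of a distance
  matrix; the null calibration suite shows that for these statistics the
  subject z is nevertheless well calibrated (pooled sd within [0.9, 1.1]).
* **Degenerate inputs.** Constant vectors yield flagged `NA`s or errors,
  never silent `NaN`; Fisher z of |r| = 1 is capped at r = 0.9999 and
  flagged; zero-variance trial patterns are excluded from cell means with
  counts reported; a zero-spread sign-flip input is an error.
* **Volume indexing.** Onsets are 0-based and locked to volume starts;
  "third volume after onset" is onset + 2. R's 1-based indexing adds one
  at the extraction site only.
* **Seeds.** Every stochastic stage takes an explicit seed;
  `derive_seed()` mixes a master seed with a stage index so a whole run is
  a pure function of one integer. Regenerating any artifact with the same
  seed is byte-identical (NIfTI is written uncompressed for this reason).
* **Free recall.** The generator draws recall sequences with an adjacency
  bias toward route order (weight `exp(−0.8 · position gap)`), giving
  recall-order/temporal-distance correlations around 0.5 with spatial
  correlations near zero; the analysis measures order distance as the
  absolute rank difference within the recalled subsequence.
* **Map test.** Responses are true positions plus isotropic jitter
  (sd 0.17 of the map side), clamped to the map; the expected mean
  displacement ratio is ≈ 0.19.
* **Problem sizes.** The calibration and power suites run 26-subject
  cohorts on 6³ grids with 27-voxel regions and 1000 shuffles/flips. Only
  mask and ROI voxel counts enter the statistics, so small grids change
  nothing but attenuation, which the power analysis accounts for.

## What passing tests do and do not show

The generator produces pre-aligned, artifact-free data: no motion beyond
the optional sinusoidal nuisance, no physiological noise, no spatial
autocorrelation, no HRF variability, and noise that is Gaussian and
homoscedastic. Calibration and power results therefore demonstrate the
correctness of the statistical machinery under its own assumptions — they
do not guarantee the same power on real data, where preprocessing quality,
temporal autocorrelation within blocks (mitigated here by block exclusion)
and between-subject registration all bite. The block-exclusion rule, the
pre/post recipe identity and the second-level sign-flip test are exactly
the defenses a real study uses against those artifacts, and they are
exercised here in the regime they were designed for.

## A worked example

```{r example, eval = FALSE}
route <- generate_route(seed = 1)
subject <- simulate_subject(route, seed = 2)
rois <- list(effect = subject$effect_roi, control = subject$control_roi)
cohort <- lapply(1:8, function(s) simulate_subject(route, seed = s))
res <- roi_pipeline(cohort, rois, n_shuffles = 1000, n_flips = 1000,
                    seed = 99)
res$table
```

The `report.txt` and `summary.json` written by `run_analysis()` contain the
same table together with all seeds and parameters; `run_simulate()` /
`run_analysis()` (or the `inst/cli/eventmap.R` script) chain the whole
pipeline from one YAML configuration.
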