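---
title: "Methods: perfusion quantification and the distributed deviating voxels statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfusion quantification and the distributed deviating voxels statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Diffuse disease processes — type 2 diabetes is the motivating example — can
lower cerebral perfusion at scattered, subject-specific locations. The two
standard analysis families are poorly matched to this situation: region-of-
interest (ROI) averages dilute a handful of abnormal voxels into a large
normal background, and voxelwise parametric mapping requires the abnormality
to overlap anatomically across subjects. `devoxel` implements a third
approach: score every voxel of every subject against a normative reference
cohort, count each subject's own *deviating voxels*, and compare those
counts between groups. A subject's burden of scattered hypoperfusion
contributes to the statistic no matter where in the brain it sits.

The package covers the full quantitative chain needed to use the statistic
on arterial spin labeling (ASL) data: CBF quantification from raw
control/label series, carotid inflow from phase-contrast cine images,
normative z-maps with leave-one-out handling, regional tallies, staged
group statistics, and a synthetic phantom generator that makes the whole
chain testable without patient data.

# CBF quantification

## Signal model

For a 2D multislice pCASL acquisition with background suppression, the
single-compartment model is

$$\mathrm{CBF} \;=\; \frac{6000\,\lambda\,\Delta SI\;
  e^{(T_{\mathrm{delay}}+T_{\mathrm{slice}}(z-1))/T_{1,\mathrm{blood}}}}
  {2\,\alpha\,\alpha_{\mathrm{inv}}\,T_{1,\mathrm{blood}}\,
   SI_{\mathrm{PD}}\,(1-e^{-\tau/T_{1,\mathrm{blood}}})}$$

with $\Delta SI$ the mean control-minus-label difference, $SI_{\mathrm{PD}}$
the proton-density reference, and $z$ the 1-based temporal slice index.
Times are entered in milliseconds (the console convention) and converted to
seconds internally so the factor 6000 yields ml/100 g/min.

Defaults (`asl_acquisition()`), all overridable:

| parameter | meaning | default |
|---|---|---|
| `lambda_bp` | blood-brain partition coefficient | 0.9 ml/g |
| `alpha` | labeling efficiency | 0.85 |
| `alpha_inv` | background-suppression correction | 0.83 |
| `t1_blood` | T1 of arterial blood at 3T | 1650 ms |
| `t_delay` | post-labeling delay, first slice | 1525 ms |
| `t_slice` | read-out time per slice | 35 ms |
| `tau` | label duration | 1650 ms |
| `n_slices` | slice count | 17 |

With these defaults the effective post-labeling delay grows from 1525 ms
(slice 1) to 2085 ms (slice 17). Slices are assumed acquired in ascending
spatial (feet-head) order; `slice_order` remaps spatial to temporal index
when they differ.

## Design choices

* **Pair quality control.** Visual rejection of corrupted control-label
  pairs is replaced by a deterministic robust rule: a pair is rejected when
  its whole-volume mean absolute subtraction deviates from the median pair
  by more than `k` (default 3) times the SD-consistent MAD (constant
  1.4826). A zero MAD — identical pairs — rejects nothing. The rule is
  reproducible and every decision is recorded (`kept_pairs`,
  `rejected_pairs`).
* **Partial-volume correction** divides voxel CBF by the grey-matter
  probability, but only where that probability is at least `min_gm`
  (default 0.3); voxels below the cutoff leave the validity mask instead of
  being divided, to avoid amplifying noise where there is hardly any GM. A
  regression-based correction would be a possible extension; division is
  what the container records (`gm_threshold_used`).
* **Negative CBF values are retained**, not clipped: clipping would bias
  the normative z-distribution downstream. Their count is kept for QC
  (`n_negative`).
* **Registration is upstream.** All volumes entering one analysis must
  share a grid; the package checks shapes and nothing else.

# Carotid flow

Phase-contrast pixels encode through-plane velocity linearly:
$v = \mathrm{venc}\cdot\phi/\pi$ (default venc 120 cm/s). Flow per cardiac
frame is the velocity integral over the vessel ROI,
$\sum_{\mathrm{pixels}} v\,A_{\mathrm{pixel}}$ in cm³/s, then averaged over
the (default 15-frame) cycle. ROIs are user-supplied masks drawn on the
magnitude image; segmentation is out of scope. Two conventions required a
decision:

* **Bilateral combination** defaults to the *sum* of left and right
  internal carotid means (both vessels feed the cerebrum, and literature
  values near 10–11 cm³/s correspond to the bilateral total); `combine =
  "mean"` is available and the choice is recorded in the result.
* **No phase unwrapping.** Phases outside $[-\pi,\pi]$ are an input error;
  velocities at the encoding limit raise an aliasing warning. An optional
  static-tissue median subtraction (off by default) corrects background
  phase offsets.

# The distributed deviating voxels statistic

Given reference CBF maps from $n$ subjects, `build_reference()` forms the
per-voxel mean $x_{\mathrm{ref}}$ and sample SD $SD_{\mathrm{ref}}$
($n-1$ denominator) on the intersection of the individual validity masks.
A subject map $x_i$ is scored voxelwise as

$$z = \frac{x_i - x_{\mathrm{ref}}}{SD_{\mathrm{ref}}}.$$

When the subject *is* a reference member, the mean and SD are first
recomputed without that subject (leave-one-out), using exact downdating
identities on the stored aggregates:
$\bar x_{-i} = (n\bar x - x_i)/(n-1)$ and
$SS_{-i} = SS - \tfrac{n}{n-1}(x_i-\bar x)^2$, which the test suite
verifies against brute-force rebuilds to $10^{-10}$.

Voxels beyond the two-sided threshold — strictly $z < -z_c$ or $z > +z_c$,
with $z_c = $ `critical_z(0.99)` $= 2.576$ by default — are counted per
atlas region, separately for the negative (hypoperfusion) and positive
tails, and expressed as a percentage of the subject's intracranial volume:
$100\cdot \mathrm{count}\cdot V_{\mathrm{voxel}} / \mathrm{ICV}$. Counting
is restricted to the intersection of the atlas GM mask, the subject's
validity mask and the reference common mask; the denominator stays the full
ICV. Reported regions are the whole cerebrum, the cerebral cortex (the four
lobes' union) and each individual region, so cortical counts are exactly
additive on a partitioning atlas.

Interpretation choices where the method description is open:

* **"Locally averaged"** is read as per-voxel aggregation across subjects
  with *no* spatial smoothing by default; an isotropic Gaussian FWHM can be
  supplied and is then applied identically to reference and subject maps
  (and recorded in the model).
* **Zero-SD voxels** are excluded from scoring and counted
  (`excluded_voxels`) instead of yielding infinite z.
* **Threshold ties** ($z$ exactly $\pm z_c$) are not flagged — a
  measure-zero convention fixed for determinism.

## Finite-reference calibration

The z-score uses an *estimated* mean and SD, so under the null the
statistic is not standard normal: $z\sqrt{n/(n+1)}$ follows a $t_{n-1}$
distribution. At the 2.576 threshold the flagged fraction is therefore
above the Gaussian 1% — about 3.5% at $n=10$, 1.2% at $n=100$ — and
converges to 1% as the reference grows. The test suite asserts this
monotone convergence and checks the $n = 100$, $10^6$-voxel case against
the exact t-tail value (≈ 98.8% of null voxels unflagged, i.e.
"approximately 99%"). Users with small reference groups should interpret
absolute fractions accordingly; group *comparisons* are unaffected because
both groups share the reference.

A second calibration finding from the simulations: the per-subject tally
fractions are heavy-tailed under the null, because a subject with a low
global perfusion offset flags many voxels at once. At moderate group sizes
the pooled t-test on tallies is therefore *conservative* (the full-pipeline
null simulation in the acceptance suite observed no false positives in 150
replicates at nominal 5%), while the staged testing machinery itself is
exactly calibrated on t-friendly metrics. This conservatism is a property
of applying a t-test to a skewed statistic, matches the spirit of a
cautious screening procedure, and is left as-is.

# Regional analysis and staged statistics

ROI means are unweighted averages over valid GM voxels per region.
Group comparisons use the equal-variance Student's t-test (the convention
of the usual "independent samples t-test"; Welch via `var_equal = FALSE`).
Covariate adjustment fits `value ~ group + covariates` by least squares and
reports the group coefficient; collinear designs are a named error, not a
silent drop. To limit the number of tests, `staged_testing()` evaluates the
whole cerebrum first and releases sub-region results only when the
whole-cerebrum p is strictly below `alpha` (default 0.05); no further
multiplicity correction is applied to the post-hoc tests, but their number
is always reported. Exclusion bookkeeping is staged the same way the study
data were: CBF-stage exclusions apply to everything, flow-stage exclusions
only to the flow analysis, and the per-reason count table is part of the
output.

# The synthetic phantom

`phantom_spec()` states the simulated world; the defaults are the
acquisition and cohort conditions the method was designed for, at desk
scale:

* 17 slices and 50 control/label pairs per ASL series; proton-density
  level 800 with per-repetition Gaussian noise SD 2 (ΔSI is then ≈ 2.7
  signal units for cortical CBF, a realistic single-pair SNR);
* grey-matter CBF around 31.5 ml/100 g/min (frontal 32, temporal 30,
  parietal 32, occipital 33, subcortical 31; non-GM tissue 15) with a
  between-subject global offset SD of 5.9 — the healthy-control
  distribution — plus voxel-level map noise SD 5;
* a 40×48×17 grid at 3×3×7 mm (tests use 20×24×8 for speed);
* covariates drawn from plausible community-cohort distributions
  (age ≈ 62 ± 8 y, ~56% male, ventricular volume ≈ 35 ± 12 ml, carotid
  flow ≈ 10.5–10.8 ± ~2 cm³/s) — documented as plausible defaults only.

The anatomy is an ellipsoidal head: a cortical shell split by axial angular
sector into four lobes that partition it exactly, a central subcortical GM
ellipsoid, and ICV defined as intracranial voxel count times voxel volume
(constant across simulated subjects, since all share one grid). ASL series
are generated by algebraically inverting the quantification equation per
slice, so with zero noise `quantify_cbf()` recovers the ground truth to
numerical precision — the forward/inverse consistency the tests assert at
$10^{-9}$.

Lesions emulate a diffuse disease: a stated fraction of a region's voxels,
shifted by `depth` × the per-voxel across-subject SD
($\sqrt{5.9^2+5^2}\approx 7.7$ ml/100 g/min), at random locations that are
*disjoint across subjects* in the default scatter mode. Phase-contrast
cines place two circular vessels with parabolic profiles scaled so the
discrete ROI integral equals the requested waveform exactly.

What the phantom does **not** emulate — so a green test does not establish
robustness to it: Rician magnitude noise, motion, physiological noise,
partial-volume mixing at region boundaries, spatially correlated noise,
atrophy-perfusion coupling, and per-subject ICV variation.

## Simulation design notes

The power simulations (deviating-voxel tally vs ROI mean on scattered
lesions, and the 3×3 depth-by-fraction monotonicity grid) run 200
replicates per setting on the 20×24×8 phantom with 12 subjects per group,
lesions in the frontal region at fractions 1–4% and depths 2.5–4 SD. The
monotonicity grid uses common random numbers — the same replicate seeds in
every cell — so that power differences between settings are not masked by
replicate noise; the assertion allows one binomial standard error of slack.
These regimes were fixed from a pilot power analysis before the acceptance
assertions were written.

# Numerical choices

* Gaussian smoothing uses a separable kernel truncated at 3σ with boundary
  renormalisation, so constant images are exactly invariant.
* The LOO downdate guards the squared-sum against tiny negative rounding
  residue before the square root.
* The MAD pair-QC rule treats MAD = 0 as "reject nothing".
* NIfTI-1 I/O is a minimal self-contained implementation (no R NIfTI
  package is available among the allowed dependencies): single-file
  `.nii`/`.nii.gz`, datatypes uint8/int16/int32/float32/float64 (+ uint16
  read), slope/intercept scaling, both byte orders on read; orientation
  metadata beyond voxel size is not interpreted. It is cross-validated
  against nibabel in the test suite.
* All simulators take explicit seeds; identical seeds give byte-identical
  outputs, including the full `run_study()` report.

# Known limitations

* The normative model is voxelwise-independent; no spatial covariance is
  modelled, so cluster-level inference is out of scope by design.
* Absolute deviating-voxel fractions depend on reference size (see the
  calibration section); compare them only within one reference.
* The t-test on tallies is conservative for heavy-tailed counts; a rank
  or permutation test would be a natural extension.
* GM partial-volume correction by division amplifies values in low-GM
  voxels up to the `min_gm` cutoff; regression-based correction is not
  implemented.
* Phase aliasing is detected but never unwrapped.
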