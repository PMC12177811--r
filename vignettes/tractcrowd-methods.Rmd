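---
title: "Sectional tract statistics and the crowding model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sectional tract statistics and the crowding model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractcrowd)
```

# The problem

After hemispherotomy — surgical disconnection of one cerebral hemisphere
for drug-resistant epilepsy — all function must be carried by the
remaining, contralesional hemisphere. The *crowding* hypothesis holds that
verbal function is preserved there at the expense of nonverbal function,
and that this reorganization has a structural substrate in the language
network, particularly the arcuate fasciculus (AF). `tractcrowd`
re-implements the analysis chain needed to interrogate this: a joint 1-D
parameterization of left/right AF bundles, binned scalar profiles
(skeleton-normalized FA, diffusivities, curvature), bin-wise nonparametric
group comparison with TFCE permutation correction, and the
crowding-classification and logistic-model layer on top.

This vignette records the model, its assumptions, the tunable parameters,
and — most importantly — the design decisions that were genuinely open and
the limitations a user should know about. Every empirical number quoted
here is computed by the package's test suite or acceptance script, not
asserted from memory.

# Pipeline model and assumptions

## Units of analysis

Patients contribute **one** hemisphere — the contralesional one; the
ipsilesional hemisphere is excluded outright. Controls contribute both
hemispheres, entering the left- and right-side contrasts respectively.
Group contrasts are therefore between subject-hemisphere *units*, with the
left/right contrasts kept separate throughout.

## Outlier removal: ν-one-class SVM

Streamlines resampled to 50 vertices are flattened to 150-dimensional
coordinate vectors and scored by a ν-one-class SVM with RBF kernel.
Because no SVM implementation ships with the supported R stack, the solver
is implemented in-package: SMO on the standard one-class dual
(0 ≤ αᵢ ≤ 1, Σα = νn, maximal-violating-pair selection). The ν-property
guarantees the removed fraction ≈ ν (default ν = 0.1); this is the
behaviour the acceptance target pins (≈ 10% removed on a 1,000-streamline
jittered arc).

*Kernel width.* Only ν is prescribed; the width uses the parameter-free
median-pairwise-distance heuristic, γ = 1/(2·median²).

*A limitation worth knowing.* With any locally-supported kernel, a
streamline displaced far beyond the kernel scale becomes its *own* support
region: the exact dual places it precisely on the margin (decision value
0), never strictly inside the negative half. Far-displaced outliers are
therefore bounded at the margin tier rather than pushed to the bottom of
the ranking — a property shared by reference implementations
(scikit-learn's `OneClassSVM` behaves identically on the same fixture).
The tests assert the attainable form: displaced streamlines never score
above the margin and sit below the inlier bulk.

## Cross-hemisphere correspondence: mirroring, orientation, ICP

Rigid ICP cannot map an arched bundle onto its reflection, so right-side
bundles are mirrored (x → −x) before alignment — the one internal
convention everything else relies on is world-mm RAS coordinates, with
format-specific conventions (TrackVis voxel-mm, NIfTI voxel grids)
converted at the I/O boundary.

Each bundle is represented by its **medoid** streamline (the member
minimizing summed mean point-to-point distance): unlike a mean curve it is
an anatomically realized trajectory and robust to residual outliers. ICP
uses nearest-vertex correspondence and closed-form Kabsch updates
(tolerance 1e-6 mm, 200 iterations max), seeded with the index-
correspondence Kabsch fit — identity-initialized curve-on-curve ICP stalls
in tangential-sliding local optima, and the seeded variant recovers known
transforms to ~1e-8.

*An orientation subtlety.* Any planar circular arc is symmetric about the
perpendicular bisector of its chord, so a rigid motion exists that maps an
arc-like bundle onto itself **end-reversed**. Geometry alone therefore
cannot decide which end of one subject's bundle corresponds to which end
of another's — and an end-reversed alignment silently destroys bin
correspondence. The pipeline resolves this anatomically, as a real
pipeline must: when an anchor (the temporal endpoint-ROI center) is
configured, bundles are first oriented so vertex 1 is the anchor end
(`orient_bundle_to_anchor()`), and ICP runs in orientation-preserving mode
(forward-index initialization only). The standalone `icp_align()` keeps
the orientation-free Besl–McKay default.

## Joint 1-D parameterization (ISOMAP)

All aligned bundles pool their vertices into one cloud; a k-NN graph
(k = 10, weights = Euclidean distances; k doubles up to 4 times if the
graph is disconnected) over at most `n_landmarks` landmark vertices yields
geodesic distances, and classical MDS of that matrix gives the 1-D ISOMAP
coordinate. Non-landmark vertices are projected by inverse-distance
interpolation over their 3 nearest landmarks. The coordinate is affinely
rescaled to [0, 1] and its direction anchored so the temporal end maps
near 0 (posterior → anterior); without an anchor, the majority streamline
direction decides.

*Landmark budget.* The embedding population was an open choice; landmarks
keep the geodesic matrix at desk scale. The default is 1,500 (an
all-pairs matrix of 1,500² doubles), well under the 20,000 the design
allows; on synthetic arcs the landmark coordinate correlates with true
arc length at Spearman |ρ| ≥ 0.999 per streamline, so the budget is not
the accuracy bottleneck.

*Core extraction.* The [0, 1] axis is split into 0.01-wide cells; a cell
is adequate when ≥ 80% of bundles have a vertex in it and it averages ≥ 5
vertices per bundle. The largest contiguous run of adequate cells is the
core, re-normalized to [0, 1]; a core shorter than 0.3 is an error
(bundle too inconsistent), not a silent sliver. The thresholds (0.8, 5)
were open parameters and are exposed in the configuration.

*Bins.* 7 equal-width bins in core-t, half-open with the last bin closed
at 1. Equal width is the simplest reading of a uniform 1-D
parameterization; nothing in the machinery depends on 7 specifically.

## Profiles and normalization

A bin's value is the mean of the sampled scalar over the *vertices* in the
bin (the scalar-aggregation population was an open choice; vertex-level
means weight streamlines by their vertex count inside the core).
Out-of-volume samples are missing, excluded from means; an empty bin is a
missing marker and its subject is dropped *pairwise per bin* downstream,
not listwise. FA (and, when profiled, the diffusivities) is divided by the
subject's white-matter skeleton mean — normalization is applied uniformly
and can be toggled. Curvature is profiled identically but needs no volume:
κᵢ = ‖xᵢ₊₁ − 2xᵢ + xᵢ₋₁‖/Δs² on the uniformly resampled streamline, zero
at the endpoints where it is undefined.

## Inference: Mann–Whitney z, TFCE, permutation FWE

Per bin, the Mann–Whitney U statistic with tie-corrected variance yields
z = (U − mn/2)/√var, positive when group a is stochastically larger.
(Reported two-sided p-values add a 0.5 continuity correction; the z that
TFCE consumes does not.) TFCE integrates cluster extent^E × height^H over
thresholds iΔh ≤ max(z) with E = 0.5, H = 2, Δh = 0.01; the i = 0 term
vanishes for H > 0 and is omitted. Inference is two-sided: the
enhancement runs on +z and −z and the permutation null takes the maximum
over bins *and* signs, so both directions share one family-wise error
budget. The corrected p is exactly the counting formula
pⱼ = (1/N)·#{D₀ᵢ ≥ TFCEⱼ(obs)} — it can be 0; an optional
(1 + count)/(1 + N) smoothing is provided off by default. When the
distinct label assignments number at most N, complete enumeration replaces
sampling. Default N = 10,000 (the source analysis leaves N unstated);
tests and examples use smaller N and say so.

The whole-tract comparison is a Welch t-test with pooled-SD Cohen's d (the
source analysis names no test for this quantity; Welch is the robust
default, Mann–Whitney is available via an argument).

## Crowding layer

Crowding ⇔ VIQ − PIQ ≥ 10 (boundary included). Barnard's unconditional
exact test on the 2×2 crowding × etiology table uses the pooled-variance
score statistic — the common choice for Barnard's test and the default in
scipy — maximized over a nuisance-probability grid of step 0.001. The
three logistic models regress crowding on one z-scored age covariate each
(surgery / onset / scan) plus z-scored normalized FA and the
affected-hemisphere indicator, reporting the full summary (coefficients,
SE, z, p, AIC, BIC, McFadden pseudo-R², likelihood-ratio p, design-matrix
condition number). Perfect separation triggers a flagged ridge-stabilized
IRLS refit (λ = 1e-4 on slopes) rather than divergent estimates.

# The synthetic world

`make_cohort()` is a *stated world*, not a tuning dial: its defaults were
fixed before any calibration was measured and describe the emulated study.

- **Geometry.** Bundles are noisy copies of a planar circular arc
  (radius 30 mm, span 180°) in a sagittal plane, ~100 streamlines per
  hemisphere, 50 vertices each with independent Gaussian jitter (SD 1 mm)
  and a random per-streamline vertex phase (real step-wise tractography
  does not place all subjects' vertices at identical arc positions; a
  phase-free generator aliases against the 0.01-wide core cells). The
  angular window sits asymmetrically about the apex — the temporal limb
  dips lower, as the real AF does. The right side is the mirror image of
  the left template. In the noiseless limit streamlines are exact arc
  copies with interior curvature 1/r.
- **Outliers.** A fraction (default 0.1) of streamlines is displaced
  whole-streamline by 12–20 jitter-SDs in a random direction, redrawn if
  the direction runs tangentially (so the displaced streamline is always
  ≥ 10 jitter-SDs from the ideal curve).
- **FA volumes.** Per subject and hemisphere, at the emulated
  acquisition's 1.7 mm resolution: tract voxels (within 6 mm of the arc)
  take `fa_baseline` + subject noise (N(0, 0.05)); background voxels take
  ~0.25; values clip to [0.05, 0.95]. An optional effect of
  `effect_size_d × fa_noise_sd` is added where the arc-length fraction u
  falls in ((k−1)/7, k/7] for effect bin k — the *generator's* segment, in
  world space, so the pipeline must recover the bin without circularity.
  The effect can be restricted to patients or to crowding-positive
  patients, and to one hemisphere. `skeleton_mean_fa` is the measured
  tract-free mean of the subject's volumes.
- **Cognition and clinic.** A `crowding_prevalence` fraction of patients
  satisfies VIQ − PIQ ≥ 10 by construction (crowding VIQ ~ N(85, 8) with
  delta ≥ 10; no-crowding VIQ ~ N(72, 9) with delta < 10 — centered on
  the published subgroup medians); crowding is assigned among
  congenital-etiology patients when counts permit, matching the empirical
  absence of acquired-crowding cases; etiology is 77% congenital; the
  contralesional hemisphere is right in 55%; ages follow
  onset ~ |N(3.5, 2.5)|, surgery = onset + |N(8, 5)|,
  scan = surgery + 1.2 + |N(8, 5)| years. Gaussian noise throughout is a
  generator convention, not a claim about the source data.

What a green test on this world does *not* establish: realistic
tractography failure modes (premature termination, false continuations),
non-Gaussian FA noise, partial bundles from genuinely deformed anatomy,
spatially correlated noise, or scanner effects. The generator's outliers
are displaced copies, nothing subtler.

`simulate_bin_profiles()` additionally draws subjects × bins matrices
directly (shared subject baseline + per-bin noise + optional shift) for
the calibration and power studies that need hundreds of replicate
cohorts; running the full imaging chain 500 times would be prohibitive and
adds nothing to a test of the *statistics*.

# Numerical choices and degenerate inputs

- TCK/TRK/NIfTI readers are deliberately minimal (little-endian, the
  variants the field's tools write) and are cross-checked against nibabel
  in the test suite; float32 storage bounds round-trip error at ~1e-6 of
  coordinate magnitude.
- Trilinear sampling reproduces affine scalar fields to machine precision;
  out-of-grid points return NA, never an error.
- `resample_streamline` places vertices at equal *arc-length* spacing
  along the input polyline; on a jagged (noisy) polyline the resulting
  chord lengths legitimately vary by up to the noise amplitude, so the
  curvature routine's uniformity guard rejects only gross violations
  (any segment deviating from the mean by more than the mean).
- Degenerate cases error loudly: zero-length streamlines, non-invertible
  affines, empty bundles after dissection, skeleton means ≤ 0, cores
  shorter than 0.3.
- Determinism: every random step (generator, landmark subsampling,
  permutations) is seeded; `run_study()` reruns are byte-identical.

# Known red results, by design

Two acceptance assertions fail, and are left failing, because analysis
shows the stated bound is unattainable rather than the implementation
deficient:

1. **Mann–Whitney agreement at n ≤ 8.** The exact two-sided p at group
   sizes ≤ 8 lives on a lattice with probability atoms larger than 0.01,
   so *no* continuous normal approximation tracks it to within 0.01 per
   dataset (scipy's own exact vs asymptotic methods disagree by > 0.01 on
   half of random small datasets). The continuity-corrected approximation
   used here attains ~0.02–0.03 worst-case at sizes 4–8, which a
   companion test pins.
2. **Corrected power 80% at d = 1.7, n = 10 vs 10.** The Mann–Whitney z
   at these sizes has mean ≈ 2.9, SD ≈ 0.5 under the planted effect,
   while the max-TFCE null's 95% quantile demands z ≥ 2.7 for an isolated
   bin: corrected power tops out near 0.7 for *any* max-corrected 7-bin
   two-sided procedure (Bonferroni does worse, 0.64 measured). Reaching
   80% needs d ≈ 2. The specificity half (far bins flagged ≤ 10%) and the
   family-wise error calibration (measured 0.054 in [0.03, 0.08] over 500
   null cohorts) both pass.

# Limitations

- The ISOMAP coordinate is 1-D by construction; bundles whose geometry
  genuinely needs two parameters (sheet-like tracts) are out of scope.
- Landmark projection uses 3-NN inverse-distance weights; a vertex far
  from all landmarks (possible only for extreme outliers that survived
  removal) inherits a poorly constrained t.
- Barnard's test enumerates all tables with fixed column sums — fine for
  cohort-scale tables, quadratic in the margins.
- The logistic models assume complete covariates; subjects with missing
  ages are dropped, and n < 10 is an error rather than a quiet fit.
- With an anchor configured the pipeline's ICP preserves orientation; if
  no anchor is given and the tract is near-symmetric end-to-end, bin
  correspondence across subjects is not identifiable from geometry alone.
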