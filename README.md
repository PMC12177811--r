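# tractcrowd

Along-tract statistics for diffusion-MRI fiber bundles, built around the
question of *cognitive crowding* after hemispherotomy: when one cerebral
hemisphere is surgically disconnected, does the remaining (contralesional)
arcuate fasciculus (AF) — the arched language tract between temporal and
frontal cortex — reorganize to preserve verbal function at the expense of
nonverbal function? `tractcrowd` is for neuroimaging researchers who want
sectional (bin-wise) tract comparisons with honest family-wise error
control, plus the cognitive-profile models that relate tract microstructure
to crowding.

## What it computes

Given per-subject streamline bundles (TCK/TRK), scalar maps (NIfTI-1:
FA/MD/RD/AD) and a subject table (TSV), the pipeline:

1. **Dissects** bundles with spherical endpoint / waypoint / exclusion
   ROIs and removes outlier streamlines with a ν-one-class SVM (RBF
   kernel, ν = 0.1 by default — ν bounds the removed fraction).
2. **Co-registers** hemispheres: right bundles are mirrored across the
   midsagittal plane (x → −x) and every bundle's medoid representative is
   rigidly aligned by ICP (Besl–McKay) to a common reference.
3. **Parameterizes** the pooled vertex cloud with a 1-D ISOMAP embedding
   (k-NN geodesic graph → classical MDS), rescaled to t ∈ [0, 1] running
   posterior→anterior, restricted to the well-supported core, and split
   into 7 equal-width bins that correspond across subjects and
   hemispheres.
4. **Profiles** each subject-hemisphere: mean scalar per bin, FA divided by
   the subject's white-matter skeleton mean (the TBSS-style normalization
   that absorbs global age/education effects), plus local streamline
   curvature κᵢ = ‖xᵢ₊₁ − 2xᵢ + xᵢ₋₁‖ / Δs² as a geometric control.
5. **Tests** each bin with a Mann–Whitney U z-score and corrects over bins
   with threshold-free cluster enhancement,

   TFCE(z)ⱼ = Σᵢ e(iΔh, j)^E · (iΔh)^H · Δh   (E = 0.5, H = 2, Δh = 0.01),

   where e is the contiguous supra-threshold run length containing bin j.
   The maximum TFCE over bins and signs under N random group-label
   permutations forms the null D₀, and pⱼ = (1/N) Σᵢ 1[D₀ᵢ ≥ TFCEⱼ(z_obs)]
   is the family-wise-corrected p-value.
6. **Models crowding**: the rule VIQ − PIQ ≥ 10 classifies the crowding
   profile; Barnard's unconditional exact test relates crowding to
   etiology (congenital vs acquired); three logistic models predict
   crowding from normalized FA, one age covariate each (surgery / onset /
   scan) and affected hemisphere, reporting coefficients, AIC/BIC,
   McFadden pseudo-R² and the design-matrix condition number.

A synthetic cohort generator (`cohort_spec()` / `make_cohort()`) emulates
the whole input world — arc-shaped bundles with vertex jitter and displaced
outlier streamlines, FA volumes with a localized group effect of chosen
Cohen's d in a chosen bin, IQ scores with a chosen crowding prevalence — so
every stage can be calibrated and power-tested without patient data.

## Worked example

Simulate a cohort of 12 patients and 12 controls whose patients carry an
FA increase of d = 3.5 confined to bin 3 of the AF, write it to disk in the
pipeline's input layout, and run the full study:

```r
library(tractcrowd)

spec <- cohort_spec(n_group_a = 12, n_group_b = 12, streamlines_per_bundle = 60,
                    effect_bin = 3, effect_size_d = 3.5,
                    effect_group = "patient", crowding_prevalence = 0.5,
                    seed = 42)
cohort <- make_cohort(spec)
data_dir <- file.path(tempdir(), "cohort")
write_cohort(cohort, data_dir)

config <- analysis_config(metrics = "fa", n_landmarks = 1000,
                          tfce = tfce_params(n_permutations = 2000, seed = 1),
                          anchor_point = arc_anchor_point(spec, "left"),
                          seed = 1)
result <- run_study(config, data_dir)
result$bin_results[["patient_vs_control_right.fa"]]
```

```
<tfce_result> 2000 permutations
 bin     z  tfce p_corrected significant
   1 0.422 0.065      0.8445       FALSE
   2 0.632 0.180      0.7045       FALSE
   3 3.057 9.598      0.0220        TRUE
   4 0.632 0.180      0.7045       FALSE
   5 0.527 0.115      0.7660       FALSE
   6 0.527 0.115      0.7660       FALSE
   7 0.316 0.028      0.9165       FALSE
```

The pipeline recovers the planted effect: bin 3 of the right-contralesional
AF is the only significant section after TFCE correction
(p_corrected = 0.022), while the whole-tract comparison of the same
contrast is unremarkable (Welch p = 0.35, Cohen's d = 0.67) — the
motivation for sectional analysis. `run_study(..., out_dir = "report")`
additionally writes `bin_results.tsv`, `whole_tract.tsv`, `attrition.tsv`,
`summary.json` (logistic models, Barnard p, core interval) and per-contrast
PNG profile plots.

## Command line

```sh
inst/cli/tractcrowd simulate --config cohort.json --out DIR
inst/cli/tractcrowd run --config analysis.json --data DIR --out REPORT
```

JSON config fields mirror `cohort_spec()` / `analysis_config()` arguments.

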