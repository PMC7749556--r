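# tendtract

Diffusion-tensor tractography with tensor deflection (TEND) and
tract-based group statistics, with a built-in simulation layer so the
whole analysis is testable without any scanner data.

## The problem

Case-control diffusion MRI studies of mood disorders ask whether white
matter "integrity" — summarized by fractional anisotropy (FA) — differs
between diagnostic groups, and whether tract-level FA relates to
cognitive performance. A typical design compares three groups (healthy
controls, major depressive disorder, bipolar disorder; n = 30 each):
fibers are tracked from atlas-defined white-matter parcels, FA is
sampled along each fiber and averaged per tract, and per-tract means are
compared by ANCOVA with demographic/clinical covariates under a
Bonferroni family correction, followed by Bonferroni post hoc pairwise
contrasts and Pearson FA-cognition correlations. Such subject-level
data are usually access-restricted, so `tendtract` pairs the analysis
chain with generators for diffusion phantoms (known fiber geometry,
Rician noise) and synthetic cohorts (known group effects and
correlations), making every stage verifiable by parameter recovery.

## What is implemented

- **Signal model.** Per voxel, diffusion is a symmetric tensor `D`
  (mm²/s); the DWI signal is `S = S0 · exp(−b gᵀDg)` for b-value `b` and
  unit direction `g`. Magnitude noise is Rician:
  `sqrt((S + ε₁)² + ε₂²)`, `ε ~ N(0, σ²)`. Encoding schemes (default 30
  directions at b = 1,000 s/mm² + one b = 0, 2.5 mm isotropic voxels)
  are generated by electrostatic repulsion with antipodal symmetry.
- **Tensor fit.** Ordinary least squares on the 7-parameter log-linear
  system (WLS optional), eigen-decomposition, and
  `FA = sqrt(1/2)·sqrt((λ₁−λ₂)² + (λ₂−λ₃)² + (λ₁−λ₃)²) / sqrt(λ₁²+λ₂²+λ₃²)`.
- **TEND tracking.** Bidirectional streamlines from every labeled parcel
  voxel: each 0.5 mm step deflects the incoming direction by the locally
  interpolated tensor, `v_out ∝ D v_in` (trilinear interpolation over the
  eight surrounding voxel centers); an end terminates when interpolated
  FA < 0.25, the per-step turning angle exceeds 45°, the track leaves
  the volume, or a step cap is hit. Every retained point carries its
  interpolated FA.
- **Tract metrics and statistics.** Pooled-point mean FA per tract;
  three-group ANCOVA (partial F for group over age, gender, illness
  duration, episode count — zero-filled for controls), literal-`.001`
  or exact Bonferroni family thresholds over the 54-tract family,
  Bonferroni post hoc contrasts, Pearson correlation tests, and
  summary-statistic χ² / t / one-way ANOVA for cohort description
  tables.
- **I/O.** NIfTI-1 (via RNifti), FSL `bval`/`bvec`, TCK/TRK streamline
  files (TRK carries per-point FA as a scalar channel), CSV cohort
  tables, and a CLI chaining all stages.

## Worked example

```r
library(tendtract)

# 1. simulate a phantom with two corpus-callosum-like bundles and track one
spec   <- tendtract:::example_phantom_spec(grid = c(24L, 24L, 12L), seed = 1)
ph     <- make_phantom(spec)
scheme <- make_gradient_scheme(n_dirs = 30, b = 1000, n_b0 = 1, seed = 1)
dwi    <- simulate_dwi(ph$field, scheme, S0 = 1000, sigma = 1000/30, seed = 1)
field  <- fit_tensor(dwi, scheme)
fa     <- fa_map(field)
bundle <- track_parcel(ph$labels, 3L, field, fa, tracking_params(),
                       parcel_name = "body_cc_L")
print(bundle)
#> tract_bundle 'body_cc_L' (parcel 3): 84 streamlines, 6062 points
mean_tract_fa(bundle)
#> [1] 0.790

# 2. synthetic cohort (3 x 30 subjects, BD has -0.05 FA on the CC body)
tab <- make_cohort(cohort_spec(seed = 1))
res <- family_correct(ancova_all_tracts(tab))
subset(res, significant, select = c(tract, F, p))
#>       tract     F         p
#> 3 body_cc_L 18.85 1.788e-07
#> 4 body_cc_R 21.46 3.072e-08
posthoc_pairwise(tab, "fa_body_cc_L")
#> Bonferroni post hoc contrasts on fa_body_cc_L (df = 83):
#>   contrast estimate       se      t         p     p_adj
#> 1   MDD-HC  0.02161 0.009923  2.178 3.225e-02 9.676e-02
#> 2    BD-HC -0.03507 0.012913 -2.716 8.035e-03 2.411e-02
#> 3   MDD-BD  0.05669 0.009516  5.957 5.978e-08 1.793e-07
```

The phantom bundle's pooled mean FA (0.790) sits below the tube's true
FA of 0.836 because stepping points near the tube boundary sample
partial-volume blends with the isotropic background. In the cohort
analysis only the two tracts carrying the simulated BD reduction
survive the `.001` family threshold, and the post hoc contrasts
attribute the effect to the BD group (both BD contrasts significant at
.05 after Bonferroni scaling by 3; MDD-HC not).

The same pipeline runs from the shell:

```sh
Rscript inst/cli/tendtract demo --out demo_out --seed 7
```

which writes `phantom_tract_fa.csv`, `cohort.csv`, `demographics.csv`,
`ancova.csv`, `posthoc.csv`, `correlations.csv` and a provenance block;
`simulate-phantom`, `fit-tensor`, `track`, `tract-fa`,
`simulate-cohort` and `group-stats` run the stages standalone on files.

## Documentation

The methods vignette (`vignettes/tend-tractography.Rmd`) describes the
model and its assumptions, the tracking and termination rules, what the
phantom and cohort generators do and do not emulate, the numerical
conventions that pin reproducibility, and known limitations.
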