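---
title: "Tensor-deflection tractography and tract statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor-deflection tractography and tract statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendtract)
```

`tendtract` implements a complete tract-based group analysis for
diffusion MRI — phantom simulation, tensor fitting, tensor-deflection
(TEND) streamline tracking with per-point FA sampling, per-tract mean-FA
reduction, and a three-group ANCOVA / post hoc / correlation battery —
in one tested chain. This vignette documents the model, the conventions
that pin reproducibility, the choices made where the method is
genuinely open, and what the simulation-based tests do and do not
establish.

## Signal model and tensor estimation

Water diffusion per voxel is modeled as a symmetric positive-definite
3×3 tensor $D$ (mm²/s). For an acquisition entry with b-value $b$
(s/mm²) and unit direction $g$, the noiseless diffusion-weighted signal
is the monoexponential forward model

$$S = S_0 \exp(-b\, g^\top D g),$$

and the recorded magnitude signal is Rician,
$\sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with
$\varepsilon_i \sim N(0, \sigma^2)$ — the standard model for
magnitude-reconstructed MRI. At zero true signal the expected magnitude
is $\sigma\sqrt{\pi/2}$ (the noise floor), a property the test suite
checks by Monte Carlo. The default phantom noise level $\sigma = S_0/30$
corresponds to a typical clinical DTI signal-to-noise ratio; the
emulated acquisition is 30 noncollinear directions at b = 1,000 s/mm²
plus one b = 0 volume on a 2.5 mm isotropic grid.
Because no standard direction table is prescribed, encoding directions
are generated by electrostatic-repulsion minimization with antipodal
symmetry from a seeded random start — reproducible, and within a few
percent of the best-known minimal-energy configurations (minimum
pairwise separation ≈ 25.6° for 30 directions).

Fitting inverts the log-linearized model
$\ln S = \ln S_0 - b\, g^\top D g$ by ordinary least squares in the
7 parameters $(\ln S_0, D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz},
D_{yz})$; six noncollinear directions plus one b = 0 image make the
design full rank, and the scheme validator enforces exactly that
(rank of the quadratic-form design, not a heuristic angle test).
OLS is the default because nothing in the emulated protocol indicates
otherwise; a single-pass weighted fit (weights = squared predicted
signals, the first-order correction for log-transformed noise) is
available via `method = "wls"`. Degenerate inputs are handled by
convention, not exception: non-positive signals are clamped to a small
positive floor before the log; all-zero voxels are excluded from the
fit mask and carry zero tensors; negative eigenvalues from noisy fits
are clamped to zero before FA (keeping FA in $[0,1]$) and recorded in a
per-voxel quality flag; the FA of an all-zero tensor is defined as 0
(background convention).

Fractional anisotropy is the usual normalized eigenvalue dispersion

$$\mathrm{FA} = \sqrt{\tfrac12}\,
\frac{\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
(\lambda_1-\lambda_3)^2}}{\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}},$$

dimensionless in $[0,1]$ and scale invariant — both properties are
asserted over randomized eigenvalue triples rather than assumed.

## Geometry conventions

All tracking runs in world millimeters. Voxel indices are 0-based and
the voxel-to-world affine maps voxel *centers*; with the default
diagonal affine, voxel $(0,0,0)$ is centered at the origin. Tensor and
FA interpolation is trilinear over the eight voxel centers surrounding
the query point, applied component-wise (which preserves symmetry and,
as a convex combination, positive semi-definiteness); at a voxel center
it returns that voxel's value exactly. The interpolation hull is the
box spanned by voxel centers — the outer half-voxel shell is
out-of-bounds, and crossing it is a tracking termination event rather
than an error.

## TEND tracking

From each seed, tracking is bidirectional along $\pm e_1$ of the
interpolated seed tensor (an explicit initial direction may be given).
Each 0.5 mm step deflects the incoming unit direction by the local
interpolated tensor:

$$v_{\text{out}} = \frac{D\,v_{\text{in}}}{\lVert D\,v_{\text{in}}\rVert},$$

sign-aligned to make an acute angle with $v_{\text{in}}$. This is the
*pure* deflection operator: isotropic tensors pass the direction
through unchanged, anisotropic tensors bend it toward the principal
axis. Where the literature sometimes blends deflection with the
incoming direction or with $e_1$ via a weighting parameter, the
unblended form is used here as the simplest faithful reading of
"tensor deflection"; the update is isolated in `tend_step()` so a blend
is a one-line extension. Integration is Euler with the direction held
over each step, matching a fixed "stepping width" description; no
Runge-Kutta variant is provided.

An end terminates when (checked in this order) the tensor cannot be
interpolated (out of bounds), the deflected direction is numerically
zero (degenerate), the turning angle between successive step directions
exceeds 45° (sharp turn), the candidate point leaves the hull, or the
interpolated FA at the candidate point falls below 0.25 (low FA); a
2,000-step safety cap bounds each direction. The "flip angle" is
interpreted as the per-0.5 mm-step turning angle — the most common
reading; an accumulated per-voxel angle would terminate more
aggressively on tight curves. Every retained point carries the FA
interpolated at it, and each end records the rejected candidate's FA or
angle so termination soundness is auditable after the fact. Seeds are
placed at the center of every voxel carrying the parcel label, visited
in lexicographic index order; densities above one seed per voxel use a
deterministic Halton offset pattern inside the voxel. If the seed FA is
already below threshold the streamline is empty and parcel tracking
drops it.

Tracking parameters, all in `tracking_params()`:

| parameter | default | units | role |
|---|---|---|---|
| `step_mm` | 0.5 | mm | arc-length step; consecutive points are exactly this far apart |
| `fa_threshold` | 0.25 | — | minimum interpolated FA at a candidate point |
| `max_angle_deg` | 45 | degrees | maximum per-step turning angle |
| `seeds_per_voxel` | 1 | — | seeds per labeled voxel |
| `max_steps` | 2000 | — | per-direction safety cap |

## Phantoms and what they establish

Phantoms embed tube-shaped bundles (straight segments or circular arcs)
with eigenvalues $(1.7, 0.3, 0.2)\times 10^{-3}$ mm²/s (FA ≈ 0.836)
in an isotropic background ($0.7\times10^{-3}$ mm²/s, FA = 0); inside a
tube the principal axis follows the analytic centerline tangent, so
tracking accuracy has an exact oracle. The tracking acceptance check
uses tubes of radius 1.8 mm — under one 2.5 mm voxel — so "90% of
points within one voxel of the centerline" measures the tracker, not
the seed spread: with tubes wider than a voxel, seeds legitimately sit
more than a voxel from the centerline and the band is uninformative.
The arc check uses a curvature radius of 25 mm (10 voxels), where the
per-step tangent rotation (≈1.1°) is far below the 45° limit.

Two boundary effects of the continuous-FA representation are worth
knowing. First, pooled tract FA sits below the tube's true FA (≈0.79
vs 0.836 in the worked example) because stepping points near the tube
wall sample the trilinear blend with background — real atlas-seeded
pipelines show the same partial-volume depression. Second,
seeding-density robustness (doubling `seeds_per_voxel` moving pooled
mean FA by less than 0.005) holds when seeds sample the resolved
interior of a bundle; it is measured on a wide tube seeded over its
morphologically eroded core, because seeds in rim voxels track along
the partial-volume blend for their whole length and shift the pooled
mean by an order of magnitude more than the density effect being
tested. Practically: seed parcels should be interior to the tract they
probe.

## Tract reduction and the cohort table

A tract's summary is the mean of *all stepping-point FA samples pooled
over all fibers* of its bundle — per-point FA sampling along fibers
makes point-level pooling the natural reduction, and it weights long
fibers proportionally to the white matter they traverse. The
alternative (mean of per-fiber means) is available via
`method = "per_streamline"`. Empty bundles reduce to `NA` with a
warning and propagate as missing cells; each tract's model then uses
listwise deletion.

The analysis table has one row per subject: group (HC/MDD/BD), age,
gender (coded 0/1, male = 1), illness duration, depressive-episode
count, cognition scores, and one `fa_<tract>` column per parcel.
Clinical-course variables that do not exist for controls (duration,
episodes) are fixed at 0 in every HC row — the zero-fill convention —
and the table validator enforces it. The shipped 54-name tract list is
a left/right parcellation of 27 structures modeled on the JHU DTI atlas
nomenclature; the widely used ICBM-DTI-81 atlas has 48 labels, and the
exact 54-parcel enumeration of the emulated protocol is not public, so
the list is a naming scheme for synthetic labels, not a claim about the
atlas — any label volume with its own ids can be supplied.

## Statistics

Per tract, the group effect is the partial F comparing
`fa ~ group + age + gender + duration + episodes` against the
covariates-only model, with the three-level group factor coded as two
dummies against the HC reference and exact F/t reference distributions.
The zero-filled covariates vary within the patient groups, so the
design is full rank; a genuinely collinear design (e.g. a constant
covariate) is rejected naming the offending column. Family control over
the 54 tracts defaults to the literal per-test threshold .001 — the
rounded Bonferroni level conventionally quoted as ≈ 0.05/54 — with an
exact $\alpha/m$ mode selectable; the literal mode is the default
because it reproduces the emulated analysis as printed. Post hoc
pairwise contrasts (MDD−HC, BD−HC, MDD−BD) are linear combinations of
the fitted group coefficients tested against the full-model residual t
distribution, with two-sided p values multiplied by 3 and capped at 1
(Bonferroni, not Tukey, matching the emulated plan). Pearson
correlations use the t transform with $n-2$ df. Cohort-description
tests are computable from printed summaries alone: pooled-variance
two-sample t (Welch optional; identical at equal n),
summary-statistic one-way ANOVA (exactly equal to the raw-data F when
given per-group moments), and Pearson χ² without continuity
correction.

One operating characteristic deserves emphasis. Because duration and
episodes are zero for every control and systematically larger in BD
than MDD, the covariates partially encode group membership; adjusting
for them inflates the variance of the adjusted group contrast (variance
inflation factor ≈ 3 for the BD dummy under the default demographic
design) and costs real power even when the covariates have no effect on
FA. The packaged power experiment (`benchmark_cohort_spec()`) therefore
measures detection of the design effect (−0.05 FA on one tract in BD,
SD 0.03, n = 30/group) with covariate distributions that carry no group
information beyond the structural zero-fill, isolating the detection
problem from this collinearity; under the full demographic design the
same effect sits near the detection boundary at the .001 threshold.
This is a property of covariate-adjusted designs with
group-confounded covariates, not of the implementation.

## The cohort generator

`make_cohort()` draws per-subject tract FA as
$N(\text{group tract mean}, \text{SD})$ with group offsets confined to
designated tracts; defaults reproduce the emulated study conditions:
n = 30 per group, 54 tracts, baseline FA 0.45 (a typical deep
white-matter value) with SD 0.03, a −0.05 BD offset on the left and
right body of the corpus callosum, demographics and cognition scores
matching the published group moments, and a target correlation
r = 0.387 between left CC-body FA and the sustained-attention score
within BD. The correlation is injected exactly at the population level:
$\text{score} = \mu_s + r\,\sigma_s\, z_{\mathrm{FA}} +
\sqrt{1-r^2}\,\sigma_s\,\varepsilon$, slope and noise variance solved
in closed form, so the sample correlation converges to the target
(±0.02 at n = 10,000, checked). Durations are truncated at zero and
episode counts additionally rounded to integers — a realism choice that
slightly perturbs the patient-group moments relative to their nominal
values but leaves every tested property intact. All generation is
deterministic given the spec seed, with the caller's RNG state
restored.

What the generator does *not* emulate: spatial structure within a
tract (each tract mean is drawn directly rather than tracked from a
per-subject image), FA covariance between neighboring tracts,
non-Gaussian FA distributions, scanner/session effects, and any real
registration or preprocessing error (synthesis is directly in atlas
space; eddy-current correction, brain extraction and spatial
normalization are out of scope). Passing tests therefore establish
that the estimator and inference chain recover known parameters under
the stated noise models — not that the pipeline is robust to real
acquisition artifacts.

## Problem sizes and runtime choices

The packaged checks use sizes chosen to make their Monte-Carlo error
small relative to the tested margins while keeping the suite quick on a
laptop: a 20³-voxel phantom for the noiseless round trip (relative
Frobenius error ~10⁻¹⁴ against a 10⁻⁸ bound), 500 null cohorts × 54
tracts for calibration (expected flag rate 0.1% at the .001 threshold;
bound 0.3%), 200 cohorts for power, and n = 10,000 per group for
moment and correlation convergence. The full suite runs in about a
minute; `scripts/acceptance.R` recomputes the headline numbers in
under a minute on one CPU.

## Known limitations

- Single-tensor model only: no crossing-fiber (multi-tensor/HARDI)
  representation, and no probabilistic tractography.
- Pure TEND without a blending parameter; on very sharp transitions the
  deflection operator can carry momentum across an interface rather
  than terminating, unless the turning-angle rule fires.
- Euler stepping: accuracy on curves is first order in step length
  (empirically well within a voxel at the default 0.5 mm step and
  ≥10-voxel curvature radii).
- The statistics layer implements the emulated analysis plan as
  specified (literal .001 family threshold, Bonferroni-scaled post hoc
  contrasts); it is not a general mixed-model framework.
- Clinical interpretation of FA differences is out of scope; FA is
  treated purely as a numeric outcome.
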