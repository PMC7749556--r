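Package: tendtract
Title: Tensor-Deflection Tractography and Tract-Based Group Statistics for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates diffusion-weighted MRI phantoms with known fiber geometry
    and Rician noise, fits per-voxel diffusion tensors by log-linear least
    squares, derives eigenvalue and fractional anisotropy (FA) maps, and runs
    tensor-deflection (TEND) streamline tractography seeded from atlas-style
    parcel labels with trilinear interpolation, a fixed 0.5 mm step, and
    FA / turning-angle termination rules. Streamlines carry per-point FA
    samples which are reduced to per-subject, per-tract mean FA. A companion
    cohort simulator and statistics layer reproduce a three-group
    case-control design: per-tract ANCOVA with demographic and clinical
    covariates under Bonferroni family correction, Bonferroni post hoc
    pairwise contrasts, Pearson FA-cognition correlations, and
    summary-statistic chi-square, t and one-way ANOVA tests. Includes NIfTI,
    FSL bval/bvec, TCK/TRK streamline and CSV input/output plus a scriptable
    command-line interface chaining the stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
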