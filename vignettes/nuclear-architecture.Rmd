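---
title: "Quantifying 3D nuclear lamin architecture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D nuclear lamin architecture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Hodgkin lymphoma cell lines contain mononuclear Hodgkin (H) cells and
multinucleated Reed–Sternberg (RS) cells. In 3D immunofluorescence
z-stacks the nuclear lamina (lamin A/C) of these cells is not a simple
shell: internal lamin structures — septa, short fragments, localized
accumulation points — subdivide the nuclear interior into compartments.
`laminatlas` turns multi-channel z-stacks (DAPI, lamin A/C, telomere
Q-FISH) into per-cell quantities:

* a **pattern label**: H cells are graded 0/A/B/C/D by how their
  internal lamin subdivides the nucleus (0: shell plus localized
  accumulation only; A: short internal structures that do not separate
  the interior; B/C/D: two/three/four-or-more compartments), RS cells
  are graded bi/tri/tetra/multi-nuclear purely by lobe count;
* the **intensity ratio** $I_e/I_i$ between total external (shell) and
  total internal lamin fluorescence — a scalar that tracks pattern
  complexity;
* **TeloView-style telomere metrics**: signal count, aggregate count,
  the a/c shape ratio of the telomere cloud, nuclear volume,
  intensities, and a binary-gate **co-localization fraction** between
  telomeres and internal lamin;
* **granulometry curves** of DNA and DNA-free space, i.e. cumulative
  structure-size distributions obtained by morphological sieving, and a
  two-sample Kolmogorov–Smirnov comparison between cell populations.

Because the raw microscopy behind the published analyses is not
publicly deposited, the package ships a synthetic z-stack generator
with voxel-level ground truth. All validation is against that truth.

# Conventions

Voxel arrays are indexed `(z, y, x)`; a voxel at 0-based index
`(i, j, k)` has physical position `(i dz, j dy, k dx)` micrometres
(voxel-centre convention). The default synthetic voxel size is
`(0.2, 0.1, 0.1)` µm: the axial step matches the 200 nm z-spacing of
the emulated acquisitions, the lateral sampling is a typical ~100 nm
camera pixel at 63×/1.4; the published protocol fixes only the axial
step, so the lateral value is a declared convention. Distances,
volumes and structuring elements are always computed in physical
units through an anisotropy-aware Euclidean distance transform.

# Segmentation and lamin decomposition

`segment_nucleus()` thresholds the smoothed DAPI and lamin channels and
takes the largest connected component of their union, with internal
holes filled (the laminar shell encloses DNA-free space that still
belongs to the nucleus). Two threshold rules are used, both relative
and therefore invariant under rescaling of the channel:

* *half-of-peak*: Otsu isolates the foreground, the threshold is half
  the foreground's upper-decile brightness. For a blurred step edge
  (DAPI: a filled volume) the half-maximum criterion places the
  boundary at the true edge.
* *half-of-median* for the lamin gate inside the nucleus-union step —
  deliberately permissive, so the whole shell contributes to the outer
  boundary even when parts of it are dim.

A thresholded bright rim still lands slightly outside the true surface
because of the PSF, so the mask is pulled back by `boundary_trim_um`
(default 0.25 µm ≈ the measured overshoot at these PSF widths) before
any depth measurement. Lobes of multinucleated cells are found by
seeding the distance transform at the significant maxima of its deep
core (≥ 60% of the global maximum, one seed per core component, 2 µm
minimum separation) and assigning every nucleus voxel to its nearest
seed.

`decompose_lamin()` splits lamin-positive voxels by **depth** from the
nuclear surface: within `shell_depth_um` of the boundary they are
external shell, deeper they are internal structure. Three choices
matter here, all exposed as arguments:

* `shell_depth_um = 0.55`. No published definition separates
  "external" from "internal" lamin; this is the single most
  consequential convention in the pipeline. 0.55 µm ≈ shell thickness
  plus one lateral PSF sigma beyond the trimmed boundary, which keeps
  the blurred shell out of the internal mask while sacrificing as
  little of each septum's rim as possible.
* `axial_depth_scale = 0.85`. The axial PSF is about twice as wide as
  the lateral one, so the detected shell band is thicker along z;
  z-distances are scaled down accordingly so that the depth cut sits
  at the same relative position in the band in every direction.
* `interior_floor = 0.45`. The interior is thresholded separately from
  the shell band (internal structures can be brighter or dimmer than
  the shell), with a floor at 45% of the shell's upper-decile
  brightness so the shell's inward blur tail is never read as internal
  structure.
* `shell_outer_um = 0.35`. The shell mask extends slightly beyond the
  segmented nuclear surface: boundary trimming plus the PSF push part
  of the shell's fluorescence outside the segmented nucleus, and the
  external intensity integral $I_e$ must collect that skirt to be
  unbiased.

Compartments are connected components of the interior after removing
the internal mask dilated by 0.15 µm (bridging PSF-thinned septum
rims); components below 1.5% of the interior volume are merged into
their nearest large neighbour. The volume reference is the interior,
not the whole nucleus: four-compartment cells split their interior
into pieces that are individually small against total nuclear volume
but are unambiguous fractions of the interior.

The classification itself (`classify_pattern()`) is a total,
deterministic function of lobe count, compartment count and internal
burden; the burden threshold separating pattern 0 from pattern A
defaults to 1% of nuclear volume, the published distinction being only
qualitative.

# The intensity ratio

$I_e$ and $I_i$ integrate the *raw* lamin channel over the shell and
internal masks; the ratio is flagged undefined when no internal lamin
is detected. The published measurements drew manual 2D contours on
selected planes; this package integrates the full 3D masks and
documents the difference. Validation is therefore against the
generator's noiseless intensity integrals, not the printed 2D values.
Since there is no canonical boundary between "external" and
"internal" lamin, the generator's intensity truth adopts the same
declared depth convention as the decomposition (a cell_spec setting,
defaulting to the analysis defaults) — recovery is only a well-posed
question when truth and measurement share one convention. Populations
calibrated to ground-truth ratios spanning the observed 1.9–5.4 range
are then recovered within ±15% with the correct ordering.
The calibration targets are assigned to labels so that the implied
internal-structure brightness stays within a detectable range
(0.5–3× shell brightness); a pattern-0 cell cannot carry a low ratio
target at all, because point-like accumulation volume would require
implausibly bright dots, so the ratio suite uses patterns A–D.

# Telomere spots

`detect_spots()` band-passes the Q-FISH channel with a
difference-of-Gaussians at the expected spot scale, takes local maxima
above 15% of the strongest response, and grows each maximum into a
region of nearby above-threshold voxels (nearest-seed assignment,
capped at 0.35 µm lateral-equivalent reach so remote signal never
joins a spot). Spot volume is measured at half the spot's own
band-pass peak (FWHM volume), which makes unresolved multi-telomere
clusters read measurably larger than single spots. `flag_aggregates()`
marks a spot as an aggregate if another centroid lies within 0.2 µm
(~the lateral resolution limit) or its FWHM volume exceeds 1.4× the
median; the TeloView aggregate criterion is not publicly specified, so
both gates are documented proxies and configurable.

The a/c ratio is implemented as the square root of the ratio of the
largest to smallest eigenvalue of the spot-centroid covariance matrix:
≈1 for isotropic (G0/G1-like) telomere distributions, larger for
flattened or elongated ones, invariant under rotation and uniform
scaling, and undefined below four spots or for degenerate (coplanar)
configurations. The exact TeloView formula is not restated in the
emulated study; this proxy preserves the stated limiting behaviour.

Co-localization uses the published binary logic gate: a spot scores 1
if its region, dilated by one lateral voxel, shares at least one voxel
with the internal lamin mask. The fraction is the mean gate over
spots — order-independent and idempotent by construction.

# Granulometry

`granulometry()` is a binary morphological sieve: the mask is opened
by anisotropy-aware balls of increasing radius (offsets `o` with
`||o·voxel_size|| ≤ r`), and the cumulative size distribution is one
minus the retained volume fraction. Openings are computed exactly via
two Euclidean distance transforms per radius — this is voxel-identical
to explicit structuring-element morphology (the test suite checks
exact equality against a brute-force offset implementation), with ties
on the ball surface resolved by a relative tolerance shared with the
oracle. The default radius grid is 0.1–1.5 µm in 0.1 µm steps; masks
are assumed not to touch the stack border (true for segmented nuclei).

For population comparison each cell contributes one number — the
volume-weighted mean structure size of its pattern spectrum — and the
two per-cell samples are compared with the package's two-sample KS
test. Cells, not voxels, are the independent units: voxel-level
pooling would inflate the effective sample size with spatially
correlated observations and reject matched distributions far too
often. The "finer" population is the one with the smaller mean size.

# Self-contained statistics

The two tests the claims rest on are implemented in the package rather
than delegated: Pearson's chi-square (expected counts from marginal
products, no continuity correction by default, switchable) and the
two-sided two-sample KS test (exact supremum of the ECDF difference
over pooled unique values, right-continuous convention for ties;
asymptotic Kolmogorov p-value at effective sample size `nm/(n+m)`).
The asymptotic p-value is mildly conservative at the ≥30-cell
population sizes used here; the suite verifies a null rejection rate
≤7% at α = 0.05. `stats::chisq.test()` and `stats::ks.test()` appear
in the tests as independent cross-checks only.

# What the generator emulates — and what it does not

`render_cell()` builds the pre-blur geometry (which *is* the ground
truth), then renders fluorescence: intensity assignment, separable
anisotropic Gaussian PSF (default σ = (0.25, 0.12, 0.12) µm, a cheap
stand-in for a deconvolved widefield PSF), Poisson shot noise and
Gaussian read noise. Identical `(spec, seed)` give bit-identical
output, and per-cell seeds in `sample_population()` derive
deterministically from the master seed.

Geometry choices worth knowing:

* **Septa are parallel planar slabs** along one randomized normal per
  cell, `n_compartments − 1` of them spread over 80% of the lobe
  extent. Parallel placement guarantees the requested compartment
  count inside an ellipsoid; independently oriented planes would
  produce unpredictable intersection counts. The generator asserts the
  realized count and errors out if the geometry cannot honour it.
* **Default lobe semi-axes (2.0, 2.6, 2.6) µm scale with pattern
  complexity** (×1.15 for HC, ×1.3 for HD): a nucleus carrying four
  optically resolvable compartments must be large enough to hold them,
  and the most compartmentalized cells in real samples are the largest.
* **Multi-lobed RS cells** are chains of tangent ellipsoids, each with
  its own complete shell; the lamin walls between fused lobes are
  internal lamin by construction.
* **Telomere placement is resolution-aware**: distinct spots keep a
  0.6 µm lateral-equivalent separation (axial distances scaled by the
  PSF anisotropy, since axially separated spots need ~1 µm to
  resolve); co-localized spots are planted on internal lamin deeper
  than 1.1 µm, where shell/internal attribution is unambiguous;
  non-co-localized spots keep a 0.8 µm clearance from any lamin
  (relaxed stepwise when the nucleus cannot honour it — crowded cells
  then trade spot resolvability, not gate correctness). Aggregates are
  clusters of three telomeres within 0.3 µm.
* **DNA-free cavities** are spheres with radii from a two-component
  Gaussian mixture (defaults 0.25/0.55 µm); shrinking the mixture
  means emulates "finer" chromatin structure.

Not emulated: photophysics (bleaching, chromatic shift), realistic
chromatin polymer texture, structured-illumination artefacts,
touching-cell fields of view, and the microscope's true PSF. Passing
tests therefore demonstrate that the measurement chain recovers known
geometry and intensity structure under realistic sampling, blur and
shot noise — not that it is robust to every artefact of real slides.

# Validation scale

The test suite validates at the population sizes the emulated study
design uses where that is statistically meaningful (200 mixed cells
for classification accuracy, 30-cell populations for co-localization
and granulometry comparisons, 1000 simulations for test calibration)
and at reduced sizes where a quantity is deterministic per cell. The
matched-distribution null for the granulometry KS test draws disjoint
30+30-cell partitions from one pool of i.i.d. rendered cells, which is
equivalent to independent draws from the same generator setting.

# Known limitations

* The external/internal split is a convention; results depend on
  `shell_depth_um` and collaborators should report it alongside any
  $I_e/I_i$ values.
* $I_e/I_i$ is computed on full 3D masks; the printed per-pattern 2D
  values from the emulated study are not directly comparable and are
  not reproduction targets.
* The aggregate and a/c definitions are documented proxies for
  TeloView behaviour, not reimplementations of its (unpublished)
  formulas.
* Binary (not grayscale) granulometry is implemented; the cumulative
  curves depend on the chosen radius grid at the discretization level.
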