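# laminatlas

Quantitative 3D nuclear architecture of lamin A/C in Hodgkin lymphoma
cells, from multi-channel fluorescence z-stacks.

In classical Hodgkin lymphoma, mononuclear Hodgkin (H) cells and
multinucleated Reed–Sternberg (RS) cells remodel their nuclear lamina:
instead of a single laminar shell, internal lamin A/C structures
subdivide the nuclear interior into compartments. `laminatlas` measures
that remodeling in 3D. Given z-stacks with DAPI (DNA), lamin A/C and
optionally telomere Q-FISH channels, it computes per cell:

* the **lamin pattern label** — H cells graded `H0/HA/HB/HC/HD` by
  internal-compartment count and internal lamin burden, RS cells graded
  `RS2/RS3/RS4/RSmulti` by nuclear lobe count;
* the intensity ratio **I<sub>e</sub>/I<sub>i</sub>** of total external
  (shell) to total internal lamin fluorescence;
* **telomere metrics** — signal count, aggregate count, the a/c shape
  ratio of the telomere cloud (eigenvalue ratio of the centroid
  covariance: ≈1 for isotropic G0/G1-like distributions), nuclear
  volume, and the binary-gate **telomere–lamin co-localization
  fraction**;
* **granulometry** of DNA and DNA-free space — cumulative
  structure-size distributions from morphological opening with
  anisotropy-aware balls — with two-sample Kolmogorov–Smirnov
  population comparison.

The package is validated end-to-end against a built-in synthetic
z-stack generator (`cell_spec()` / `render_cell()` /
`sample_population()`) that emits voxel-level ground truth: masks,
compartment labels, telomere positions with co-localization flags, and
noiseless intensity integrals.

It is aimed at quantitative microscopists and computational biologists
working on nuclear organisation who need a scriptable, reproducible
version of this analysis rather than interactive per-cell tooling.

## Worked example

Simulate a small mixed population at the published pattern frequencies
and push it through the full pipeline:

```r
library(laminatlas)

report <- run_pipeline(list(
  simulate = list(n_h = 12, n_rs = 6,
                  base_spec = list(n_telomeres = 20L)),
  seed = 42
))
report
#> <lamin_report v0.1.0> 18 cells analysed, 0 errors; 18 telomere rows, 540 curve rows

dplyr::select(report$calls, cell_id, label, n_lobes, n_compartments, ratio)[1:5, ]
#> # A tibble: 5 × 5
#>   cell_id   label n_lobes n_compartments   ratio
#>   <chr>     <chr>   <int>          <int>   <dbl>
#> 1 cell_0001 HB          1              2    5.18
#> 2 cell_0002 HB          1              2    4.92
#> 3 cell_0003 HB          1              2    5.20
#> 4 cell_0004 HB          1              2    5.20
#> 5 cell_0005 H0          1              1 7060.
```

Each row is one cell: its pattern call, the lobe and compartment counts
behind it, and the external/internal lamin intensity ratio (large for
pattern-0 cells, whose only internal lamin is a few accumulation
points; smaller as internal structure grows). The report also carries
the pattern frequency table (`report$table`, within-family percentages
summing to 100), the per-pattern ratio summary (`report$ratios`),
telomere metrics (`report$telomeres`) and granulometry curves
(`report$curves`); `autoplot()` methods plot the table and the curves.

Single stages are available as plain functions operating on
`voxel_grid` / `cell_stack` objects and returning tibbles:
`segment_nucleus()`, `decompose_lamin()`, `classify_pattern()`,
`intensity_ratio()`, `detect_spots()`, `flag_aggregates()`,
`ac_ratio()`, `coloc_fraction()`, `dna_and_free_masks()`,
`granulometry()`, `compare_populations()`, `chi_square()`,
`ks_two_sample()`. Stacks are read and written as TIFF with JSON
sidecar metadata (`read_stack()` / `write_stack()`; OME `PhysicalSize*`
attributes are honoured on read).

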