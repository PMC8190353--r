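# ctcurate

Systematic curation of CT imaging cohorts before quantitative analysis,
built around CT colonography (CTC). Retrospective CT archives arrive as
thousands of per-slice DICOM files of uneven completeness and quality;
before any segmentation or measurement can be trusted, a study team has to
screen diagnostic quality, reject artifact-ridden scans, verify DICOM
conformance series by series, tabulate acquisition parameters so datasets
can be picked by parameter of interest, and design a defensible sample.
ctcurate packages that workflow for R, aimed at medical-image-analysis
researchers curating public archives (e.g. TCIA-style CT collections) into
study-ready cohorts.

## What it does

* **DICOM model and I/O** — a minimal Part-10 reader/writer for
  uncompressed Explicit VR Little Endian CT slices, preserving the
  distinction between an *absent* attribute and a *present-but-empty* one,
  with Patient → Study → Series grouping and deterministic slice ordering.
  Slice position uses Slice Location (0020,1041) and falls back to the z
  component of Image Position (Patient) (0020,0032) when it is missing.
* **Validation framework** — declarative per-module rules over DICOM
  type-1/2/3 attribute classes, series/instance uniqueness checks,
  missing-slice gap detection from the median inter-slice spacing, vendor
  private-tag notes, and a series pass/fail verdict. The `strict` profile
  fails series whose type-2 attributes are empty (the curation behavior);
  `lenient` is the standard-conformant reading.
* **Cohort flow** — staged filtering with counts:
  intake → diagnostic-quality filter → artifact rejection → validation
  gate, driven by a JSON manifest of per-series flags.
* **Index sheet** — a per-series tabulation of acquisition attributes
  (slice thickness, kVp, mA, pixel spacing, kernel, window, position,
  demographics, ...), written as CSV, queryable with column predicates and
  bin counting.
* **Stratified sampling** — proportional allocation
  `n_i = (N_i / N) · n`, integerized by largest remainder so allocations
  always sum to `n`, plus seeded uniform without-replacement draws.
* **Volume reconstruction** — z-linear resampling toward isotropic voxels
  (CT stacks are anisotropic only along z), window/level + gamma display
  transforms `clip((v − (L − W/2))/W, 0, 1)^γ · 255`, and mean-projection
  DRR images.
* **Fixture generator** — synthetic DICOM series across the realistic
  acquisition grid with seven plantable defect kinds, each mapping
  one-to-one to a validation finding, plus full 187-series cohort profiles.

## Worked example

Generate a synthetic series, validate it, reconstruct and resample the
volume, and design a stratified sample:

```r
library(ctcurate)

dir <- file.path(tempdir(), "demo_series")
make_series(series_spec(series_id = "DEMO", n_slices = 4, slice_thickness = 2.5,
                        kvp = 120, ma = 240, phantom = "z_ramp"), dir)

validate_series(dir, profile = "strict")
#> <validation_report> series 1.2.826.0.1.3680043.9999.2.293
#>   profile: strict | instances: 4 | verdict: PASS
#>   TYPE3_NOTE         8
```

The verdict is `PASS`: every type-1 attribute is present and non-empty,
every type-2 attribute present, locations are gap-free and unique. The
eight `TYPE3_NOTE` rows are informational — the registry notes the
presence of the optional Convolution Kernel and Exposure Time tags on each
of the 4 slices; info findings never affect the verdict.

```r
vol <- assemble_volume(read_series(dir))
vol
#> <ct_volume> 32 x 32 x 4 voxels
#>   spacing 0.7031 x 0.7031 x 2.5000 mm | origin -11.25, -11.25,   0.00 mm | HU range [0, 75]

dim(resample_z_linear(vol, 0.703125)$data)   # toward isotropic voxels
#> [1] 32 32 11

apply_window(c(-160, 40, 240), width = 400, level = 40)
#> [1]   0 128 255
```

The stack is anisotropic (0.70 mm in-plane vs 2.5 mm slices); resampling
to 0.703125 mm turns 4 slices spanning 7.5 mm into 11. The abdomen display
window (W = 400, L = 40) maps its lower edge −160 HU to black, the level
to mid-gray, and the upper edge 240 HU to white.

```r
tidy(allocate_proportional(c(polyp = 540, no_polyp = 60), 150))
#> # A tibble: 2 × 4
#>   stratum   size quota allocation
#>   <chr>    <int> <dbl>      <int>
#> 1 polyp      540   135        135
#> 2 no_polyp    60    15         15
```

A sample of 150 over a 600-subject population split 540/60 allocates 135
and 15 — the quotas are integral, so the largest-remainder rule returns
them exactly. `draw_sample(sheet, alloc, "Polyp found", seed = 42)` then
draws the rows reproducibly.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/curate.R validate <series-dir> --profile strict --report report.json
Rscript inst/scripts/curate.R synth --profile flow --out cohort/ --seed 1
Rscript inst/scripts/curate.R flow cohort/manifest.json
```

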