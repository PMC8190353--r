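---
title: "Curation methods: DICOM validation, cohort flow, index classification, sampling and reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation methods: DICOM validation, cohort flow, index classification, sampling and reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcurate)
```

ctcurate implements the data-curation stage that precedes quantitative
image analysis on retrospective CT archives, built around the CT
colonography (CTC) use case: screening a downloaded cohort for diagnostic
quality and acquisition artifacts, validating every surviving DICOM series
for completeness and internal consistency, tabulating acquisition
parameters into a queryable index sheet, designing a stratified sample, and
reconstructing display-ready volumes. This vignette records the models,
parameter choices and their rationale, and the limits of what the test
suite shows.

## The DICOM data model

A CT archive organizes files as Patient → Study → Series → Image, one file
per slice. `read_dicom()` parses a Part-10 file (uncompressed Explicit VR
Little Endian) into a keyed element collection plus the pixel plane.
Two states of an attribute are deliberately distinguished:

* **absent** — the tag does not occur in the file;
* **present-but-empty** — the tag occurs with zero length.

The distinction carries the whole type-1/type-2 validation semantics:
anonymization pipelines routinely blank type-2 values rather than remove
the tags, and a curation rule that conflates the two states cannot express
"present but empty" failures.

The codec is intentionally minimal: single-frame CT slices, no sequence
(SQ) recursion, no compressed transfer syntaxes. The fixture generator only
emits Explicit VR LE, and public CT archives decompress to it; supporting
the full transfer-syntax zoo would add surface without adding coverage for
the curation logic this package exists for. File extensions `.dcm`, `.ima`
and none at all are accepted; the `DICM` magic is sniffed rather than
trusting names.

### Slice location and ordering

The slice position is stored redundantly: Slice Location (0020,1041) and
the z component of Image Position (Patient) (0020,0032). The effective
location rule is: use (0020,1041) when present and non-empty, otherwise
derive the location from (0020,0032). When Image Orientation (Patient) is
available the position is projected onto the slice normal (the cross
product of the row and column direction cosines); for axial scans this
degenerates to the raw z component, and for oblique acquisitions it keeps
the ordering geometrically meaningful. A property test asserts that
(0020,0032) is never consulted while (0020,1041) carries a value.

Sorting is ascending by effective location with ties broken by Instance
Number, then SOP Instance UID — a deterministic permutation, so shuffled
input always reproduces the same order (tested over random permutations).
All location comparisons use an absolute tolerance of 1e-3 mm: locations
are written as decimal strings and can carry sub-micron float noise that
must not perturb ordering or duplicate detection.

## The validation framework

`validate_series()` screens one series: element rules over every instance,
series/instance uniqueness, missing-slice gap detection, and vendor
private-tag notes, returning findings (a tibble) and a verdict. The verdict
is `fail` exactly when at least one finding has severity `fail`.

### Rule registry

Rules are declarative rows — module, tag, type class (1/1C/2/2C/3),
uniqueness scope, enabled flag — shipped as `default_registry()` and
overridable from YAML/JSON. The standard's module tables define type
classes per attribute but a curation tool must still choose the concrete
tag list; the shipped default covers the attributes the downstream steps
actually consume (identity and hierarchy UIDs, geometry, pixel-structure,
exposure and rescale attributes). Clinical Trial and Contrast Bolus rules
exist but are disabled by default: anonymized archives have those modules
stripped, and validating them would fail every series for reasons
unrelated to usability. Type-3 notes default to Convolution Kernel and
Exposure Time; 1C/2C rules evaluate only when their registered condition
predicate fires (e.g. `modality_is_ct` for Patient Position) and degrade to
an info note when no condition is registered, rather than guessing the
standard's prose conditions.

### Strict versus lenient profiles

The DICOM standard permits an empty type-2 attribute. A curation workflow
is stricter: a series whose type-2 identity attributes are blank is not
usable for cohort bookkeeping, so under the default `strict` profile
`EMPTY_TYPE2` fails the series, while the `lenient` profile downgrades it
to a warning (the standard-conformant reading). Both behaviors are kept so
the package neither misrepresents the standard nor silently accepts
unusable series.

### Missing slices

With locations sorted, the inter-slice spacing is inferred as the median of
successive differences — robust to a few gaps as long as most neighbors are
contiguous. Any difference exceeding 1.5× the inferred spacing is a gap
with `round(diff / spacing) − 1` estimated missing slices. The 1.5 factor
sits halfway between "noise in a regular grid" and "one whole missing
slice" (which produces a 2× difference); fewer than 3 slices cannot anchor
a spacing estimate and yield an indeterminate report instead of a guess.
Duplicate effective locations are reported at warning severity: a
duplicated position alone does not prove a broken series, but it deserves
review.

### Private tags

Recognized vendor private blocks (matched by the private-creator element)
produce informational findings recording presence and VR only; unknown
creators are ignored, and private tags never affect the verdict. This keeps
older vendor-dialect series flowing through the pipeline while leaving an
audit trail.

## The cohort flow

`run_flow()` chains three gates with fixed order — diagnostic-quality
filter, artifact filter, validation — and reports the surviving count at
each stage plus per-reason discard counts. Quality and artifact judgments
are radiologist calls; the package records them as manifest flags (with a
fixed reason vocabulary: inadequate distension, incomplete scan, retained
debris/stool, non-distended diverticulosis, patient too large, streak
artifact at the quality stage; metal artifact, motion artifact, quantum
noise at the artifact stage) rather than inventing an image-based
classifier the underlying methodology does not define. The source files
are never rewritten: curation is selection, not editing.

## The index sheet

`build_index()` produces one row per series with a fixed, ordered column
set (subject, quality and validation status, slice thickness, kVp, mA,
pixel spacing, kernel, matrix size, display window, position, counts,
demographics, ...), realized as plain CSV — bit-stable, diff-able, and
spreadsheet-openable. Blank cells are empty strings, never sentinel
numbers. Ages are stored as the header carries them (decade-binned values
in the fixtures), with no re-binning. `filter_index()` applies a
conjunction of column predicates preserving row order (chained filters
equal the conjunction — tested), and `classify_counts()` counts rows per
scalar or half-open `[lo, hi)` range bin, with rows matching no bin
reported under `other` and overlapping bins rejected.

## Stratified sampling

`allocate_proportional()` splits a required sample size `n` across strata
proportionally, `n_i = N_i / N · n`. The canonical design in the fixtures
is a population of 600 split 540 (with polyps) / 60 (without), `n = 150`,
giving 135 and 15 exactly. Exact quotas are integerized by the
largest-remainder (Hamilton) rule, chosen because it guarantees
`Σ n_i = n` for every input and reproduces integral quotas exactly; the
divisor methods (D'Hondt, Sainte-Laguë) trade those two properties for
house-monotonicity, which does not matter for a one-shot sample design.
Ties in remainders break deterministically (larger stratum, then name).

`draw_sample()` draws uniformly without replacement within each stratum —
the underlying study design states the split but not the within-stratum
mechanism, so uniform sampling is the assumption, made explicit. One
integer seed drives the draw; the caller's RNG state is saved and
restored, so sample designs are reproducible without global side effects.
An empirical check over 10,000 seeded single draws from 4 equal rows keeps
each row's frequency within 5σ of 0.25.

## Volume reconstruction and display

`assemble_volume()` stacks sorted slices into a rows × cols × slices HU
array (rescale slope/intercept applied first, always), infers z spacing as
the median inter-slice difference, and refuses to assemble across a
missing-slice gap rather than interpolating silently over absent anatomy.

CTC stacks are anisotropic only along z (in-plane ≈ 0.55–0.98 mm versus
1–5 mm slice spacing), so `resample_z_linear()` interpolates each (x, y)
column linearly along z only, leaving the in-plane grid untouched. The
default target spacing is the in-plane pixel size, which moves the voxels
toward isotropy — the motivation being that polyp sizes are systematically
underestimated on anisotropic voxels. The method has the standard linear
guarantees, which the tests assert: exact on fields affine in z (to 1e-9
relative), never overshooting the data range, and the identity on its own
grid. Endpoints are reproduced exactly and nothing is extrapolated.

`apply_window()` uses the plain linear window
`clip((v − (L − W/2)) / W, 0, 1)` rather than the PS3.3 VOI LUT variant
with its (w−1)/(c−0.5) offsets; the simpler map is documented, monotone,
and symmetric about the level, and nothing downstream depends on the
half-unit convention. Gamma correction raises the window-normalized value
to `gamma` (default 1.0 — gamma is named by the workflow but no value is
published, and 1.0 makes the correction a no-op until a site calibrates
it); the 8-bit cast rounds half up. With the default abdomen window
W=400, L=40: −160 HU → 0, 40 HU → 128, 240 HU → 255. `drr_project()`
produces a digitally reconstructed radiograph as the mean HU along one
axis, then windows it.

## The fixture generator

`make_series()` writes fully conformant synthetic series across the
realistic acquisition grid (slice thickness 1.25/2.5/5 mm, 100/120 kVp,
0.58–0.93 mm pixels, FFS/FFP/HFS/HFP, 16-bit planes), with three phantoms:
uniform water, a z-ramp whose HU is affine in z (10·z, exercising
interpolation exactness), and a centered cylinder (geometry and
windowing). Phantoms are deterministic, so equal specs give byte-identical
files. No anatomical realism is attempted — colon anatomy synthesis is far
outside scope, and nothing in the curation logic depends on it.

Each plantable defect kind maps to exactly one expected finding:
`drop_tag` → MISSING_TYPE1, `empty_tag` → EMPTY_TYPE2, `remove_slice` →
MISSING_SLICE, `duplicate_sop_uid`/`vary_series_constant` → NON_UNIQUE,
`corrupt_file` → CORRUPT_FILE, and `drop_slice_location` is expected to
*pass* through the position fallback. The one-to-one property — exactly
the expected code, no cross-talk, and a clean twin passes — is tested for
every kind.

`make_cohort()` materializes two cohort profiles of 187 series each.
The **flow profile** encodes the curated composition: 8 series flagged bad
diagnostic quality, 15 with artifact reasons, and 6 written with an empty
type-2 PatientID so strict validation fails them, yielding the staged
counts 187 → 179 → 164 → 158. The source material is internally
inconsistent about the validation failures (one passage says seven series
failed, the surviving counts imply six); the generator uses six so the
stage arithmetic is consistent, and this choice is recorded here rather
than hidden. The **index profile** reproduces the published per-column
distributions (kVp 185/2 at 120/100 kVp; mA 61/108/4 at 240/200/140 mA;
slice thickness 130/57 at 2.5/1 mm; quality 166/21; decade age groups
43/80/56; pixel-size groups 23/68/78/17). Those groups do not sum to 187
in every column and are mutually inconsistent as a joint distribution, so
each column is satisfied independently and padded with an explicit "other"
value (300 mA, the 71–80 age decade, 0.95 mm) — no single joint dataset
can satisfy all the published totals simultaneously.

Fixture series use small planes (8×8 or 16×16 pixels, 2–6 slices) so the
full suite builds hundreds of real Part-10 files in seconds; every
byte-level, geometric and statistical property under test is invariant to
the plane size, and the one cross-check against an independent DICOM
reader (pydicom) runs on such a plane.

## What passing tests do and do not show

The generator emulates header structure, geometry, and cohort composition
— not image content. Passing validation on the fixture grid shows the
rule engine is sound on conformant input and sharp on planted defects; it
does not show robustness to the full wilderness of vendor dialects,
compressed syntaxes, multi-frame objects, or localizer slices mixed into
series. Quality and artifact gates are exercised through manifest flags,
so the flow counts verify the bookkeeping, not any ability to detect
artifacts in pixels. Interpolation and windowing are verified against
their mathematical definitions, which is exactly what they claim.

## Known limitations

* No sequence-element recursion, DICOMDIR, or compressed transfer
  syntaxes; non-Explicit-VR-LE input is rejected with a format error.
* 1C/2C conditions are only as good as the registered predicates; unset
  conditions produce info notes, not conformance guarantees.
* The contrast correction step for under/over-exposed regions mentioned in
  the source workflow is unspecified there and deliberately not
  implemented.
* Colon segmentation, electronic cleansing, polyp measurement, surface and
  direct volume rendering, and archive download clients are out of scope.
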