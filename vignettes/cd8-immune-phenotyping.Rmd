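---
title: "Digital CD8+ T-cell immune phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital CD8+ T-cell immune phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the stain model, the segmentation and scoring procedures, the compartment
geometry, the diagnostic decision algorithm, what the synthetic generator
does and does not emulate, and the design choices made where the design
was genuinely open.

## 1. The measurement problem

Immune phenotyping of a tumor asks where the cytotoxic (CD8+) T cells are,
not merely how many there are. Three categories are clinically
established: *inflamed* tumors with T cells infiltrating the tumor
parenchyma, *excluded* tumors where T cells accumulate in stroma or at the
invasive margin but do not enter tumor cell nests, and *desert* tumors
with scarcely any T cells. The quantitative surrogate is the
area-normalized CD8+ density in three compartments of a whole-slide CD8
immunohistochemistry stain:

* **iTC** — intratumoral tumor center: tumor cell nests without
  intervening stroma;
* **sTC** — stromal tumor center: intratumoral stroma without tumor
  cells;
* **IM** — invasive margin: a 1 mm band centered on the annotated tumor
  border (Working Group convention).

Densities are written iCD8, sCD8, imCD8, in cells/µm². In metastatic
biopsies the margin is frequently absent; a central design property of the
workflow is that the diagnosis never requires it.

## 2. Stain model and deconvolution

Chromogenic stains attenuate transmitted light multiplicatively, so stain
amounts add linearly in optical density, `OD = -log10(I / I0)`. With a
3×3 basis of reference stain colors (rows: hematoxylin, AP-red, residual),
`deconvolve_stains()` converts an RGB image to per-stain OD maps by linear
unmixing, clipping negative concentrations at zero. The hematoxylin vector
is the standard published value `(0.650, 0.704, 0.286)`; the AP-red vector
`(0.100, 0.740, 0.665)` encodes a red chromogen (strong green/blue
absorption); the residual vector completes an independent basis and
absorbs eosinophilic background. Reference vectors are configuration
(`stain_vectors()`), since no canonical AP-red vector is published. The
forward model (`od_to_rgb()`, used by the renderer) is the exact inverse,
so deconvolution is invertible up to 8-bit quantization — a property the
test suite asserts at tolerance 1e-3.

## 3. Tissue classification

Whole-slide tissue context is classified into six classes — tumor,
desmoplastic stroma, immune-infiltrated stroma, glass, pigment,
hemorrhage/necrosis — from labeled patches. Each patch is summarized by
nine features: mean OD of the three stain channels, their texture
(population SD), and mean RGB. A random forest (default 200 trees)
predicts patch labels; dense maps come from a sliding window at stride
`patch/2` with per-pixel majority voting, ties broken by a fixed priority
(tumor > immune stroma > desmoplastic stroma > pigment >
hemorrhage/necrosis > glass) so that tumor is never silently missed and
the fusion is deterministic.

The classifier family is deliberately pluggable behind this surface: the
contract is the six-class map. A compact feature+forest head is the
default because it trains in seconds on a CPU and is fully reproducible
under a seed; the patch size defaults to 64 px for synthetic material
(simpler textures) and is configurable for real tissue, where larger
context windows (e.g. 256 px at 0.25 µm/px) are appropriate. Active-
learning style correction is represented by the ability to retrain on
edited labels; no automatic correction loop is claimed.

## 4. Nucleus detection and CD8 scoring

`detect_nuclei()` implements a seeded watershed on the hematoxylin
channel: Gaussian smoothing (σ = 1 µm, suppressing pixel noise at
0.25 µm/px), foreground threshold at the minimum nuclear OD, then a
watershed on the distance transform of the foreground to split touching
nuclei. Each region yields one candidate with centroid, area (µm² via
mpp), isoperimetric roundness `4π·area/perimeter²` (the standard formula;
"roundness" has no canonical alternative definition) and mean nuclear OD.

`filter_candidates()` applies the pathologist-style morphometric gates
with inclusive bounds: area within [10, 120] µm², roundness ≥ 0.4, mean
OD ≥ 0.35. These defaults are lymphocyte-scale calibration choices — the
platform thresholds used on clinical material are not published — and all
are configurable (`detection_params()`).

CD8 positivity is called from the AP-red OD in a peri-nuclear annulus of
width 1.5 µm just outside the nuclear boundary (`score_marker()`), because
the chromogen is membranous/cytoplasmic and the nuclear mask alone would
miss it. With the detector's label raster available, the annulus is the
morphological dilation of the actual nuclear mask, ring pixels attributed
to their nearest nucleus by propagation; without it (e.g. scoring an
imported cell table) a circular annulus of equivalent radius is used.
Cells whose annulus lies wholly outside the image are flagged, not scored.
The positivity threshold (default 0.2 OD) is inclusive and monotone:
raising it can only reduce the CD8+ count.

## 5. Compartment geometry

`build_margin_band()` realizes the "1 mm invasive margin" as ±500 µm on
each side of the annotated tumor border. The band is computed by distance
transforms of the rasterized border polygon set, which is robust for
arbitrary (also disjoint or concave) borders, and is returned as a raster
band mask; on a circular tumor it matches the closed-form annulus area to
well under 1%. Whether the band should be asymmetric (outward only) is not
settled; the centered band is the Working Group reading, and the
half-width is a parameter.

`build_compartment_mask()` partitions every pixel with the precedence
**exclusion > margin > tumor-center subdivision > outside**: exclusion
polygons (artifact, tertiary lymphoid structure, preexisting lymphoid
tissue, other) and artifact-classed pixels (glass, pigment,
hemorrhage/necrosis) are excluded from every denominator; margin-band
pixels are IM; inside the border, tumor-classed pixels are iTC and
stroma-classed pixels are sTC. The five labels partition the slide
exactly, so compartment areas sum to the canvas area — an identity the
tests assert. Lymph-node preexisting lymphoid tissue is a
pathologist-provided exclusion, not auto-detected: distinguishing
preexisting lymphoid stroma from tumor-associated stroma is the hardest
anatomical situation for human and machine alike, and no algorithm is
claimed here.

Cells are assigned by the mask label at their centroid pixel — simple,
deterministic, and consistent with area-normalized density semantics.

## 6. Densities, cut-offs and the decision algorithm

`compute_densities()` is deliberately trivial: CD8+ count over compartment
area. A slide without positive iTC and sTC area is unscorable (error); a
zero IM area yields an absent imCD8, not an error.

`classify_phenotype()` is the decision tree

```
iCD8 ≥ c_i → inflamed;  else sCD8 ≥ c_s → excluded;  else desert
```

It is total, deterministic, margin-free, and monotone: the inflamed
predicate is non-decreasing in iCD8, the desert predicate non-increasing
in both densities. Thresholds are inclusive by convention. The
tumor-first reading (iCD8 decides first) was chosen because it reproduces
the one error mode actually observed when validating such algorithms
against pathologists — excluded cases with relatively high intratumoral
densities spilling into *inflamed* — which a stroma-first reading cannot
produce.

`derive_cutoffs()` grid-searches candidate pairs taken from midpoints of
adjacent sorted observed densities, extended by one candidate below the
minimum and above the maximum so "no slide passes" and "every slide
passes" are representable; the objective defaults to balanced accuracy
(mean per-class recall), and ties resolve to the smallest `(c_i, c_s)`.
The shipped default cut-offs are geometric midpoints between adjacent
phenotype preset means (`c_i ≈ 3.5e-4`, `c_s ≈ 6.3e-4` cells/µm²). They
are explicitly *package defaults for convenience*, not published clinical
cut-offs: published figure-level cut-off lines could not be reconciled
with the printed density magnitudes, so cut-offs are treated as
configuration, and any real cohort should re-derive them. Because a
classifier's boundary errors shift measured densities (typically inflating
iCD8 for stroma-rich tumors), cut-offs should be derived on densities
measured by the *same* pipeline configuration that will be deployed.

## 7. Evaluation

`cross_tabulate()` builds the 3×3 confusion matrix (rows predicted,
columns reference diagnosis); `class_metrics()` reports one-vs-rest
TP/TN/FP/FN with sensitivity, specificity and precision per class. Ratios
with empty denominators are *not applicable* (`NA`), never zero. Display
percentages are rounded to integers except exact halves (62.5%); raw
ratios are stored unrounded. Macro averages are attached but nothing is
asserted about them.

`holm_sidak_adjust()` implements the step-down adjustment
`adj_(k) = max_{j≤k} 1 − (1 − p_(j))^(m−j+1)`, clipped at 1 and returned
in input order; with m = 1 it is the identity. `compare_density_groups()`
runs pairwise Welch t-tests per compartment between phenotype groups and
adjusts the whole family (all compartment × pair combinations) in one
step — the underlying cell-comparison statistic of published posttests is
not specified beyond the adjustment method, so the Welch test was chosen
and is documented here. `correlate_scorings()` is OLS plus Pearson r, with
the ordinal coding desert = 1, excluded = 2, inflamed = 3 for regressing
categorical diagnoses.

## 8. The synthetic slide generator

The generator emulates what the pipeline must be robust to, with exact
ground truth:

* **Layout** (`generate_layout()`): a tissue section blob on glass;
  `n_tumor_nests` smooth random blobs whose polygon areas sum exactly to
  `tumor_fraction` of the canvas (default 0.4); intratumoral stroma
  islands (desmoplastic or immune-infiltrated) strictly inside their
  nests at `stroma_fraction` of nest area; optional artifact patches
  (pigment, hemorrhage/necrosis, glass) covering `artifact_fraction`.
* **Cells** (`place_cells()`): homogeneous Poisson counts per compartment
  (expected count = density × area), uniform positions with a hard-core
  rejection rule (minimum center distance 1.2× summed radii); nuclear
  radii N(3.5, 0.5) µm truncated to 2–6 µm — lymphocyte/tumor nucleus
  scale that keeps the watershed meaningfully testable. CD8+ cells follow
  the requested densities in iTC/sTC/IM; CD8− background nuclei (default
  1e-3 cells/µm², a deliberately sparse desk-scale stand-in for real
  nuclear density) populate all tissue compartments.
* **Rendering** (`render_image()`): per-class base ODs plus per-class
  texture noise (immune stroma gets a strong hematoxylin speckle,
  desmoplastic stroma is smooth and eosinophilic, pigment is dark in all
  channels), hematoxylin ellipses per nucleus, an AP-red footprint peaked
  at the cell center and extending 1.5 µm past the nuclear rim for CD8+
  cells, then Beer–Lambert conversion to RGB, Gaussian sensor noise
  (SD 0.008) and 8-bit quantization.

The phenotype presets (`phenotype_preset()`) are the discovery-cohort mean
densities per compartment — desert (2e-5, 2e-4, 6e-4), excluded
(2e-4, 2e-3, 2e-3), inflamed (6e-4, 5e-3, 3e-3) cells/µm² for
(iCD8, sCD8, imCD8) — the only density values available to parameterize a
generator, and they are used as exactly that: generator parameters.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about clinical material: nuclear texture and chromatin
patterns, stain variation across scanners and labs, out-of-focus regions,
spindle-cell and other unusual morphologies, spatial clustering of T cells
(no clustering statistics are published, so homogeneous Poisson is a
stand-in, not a claim about real cohorts), tissue folds, and true
whole-slide scale. The default canvas is 2048² px (0.26 mm² at
0.25 µm/px), a desk-scale stand-in for clinical sections averaging tens of
mm². Synthetic cohorts are generated without an invasive margin by default
(`margin_halfwidth_um = 0`): at 512 µm canvas side a ±500 µm band would
swallow the slide, and the diagnosis is margin-free by design — this
mirrors the clinically common margin-free biopsy. Margin-bearing behavior
is exercised at coarser resolution where a band fits (the density study
uses 0.5 µm/px with a 75 µm half-width; the geometry checks use 4 µm/px
with the full ±500 µm band).

## 9. Numerical choices and degenerate inputs

* Rasterization is even-odd scanline filling on pixel centers with a
  half-open vertex convention, so adjacent polygons partition cleanly;
  rasterized areas converge to shoelace areas (tested against an
  independent point-in-polygon oracle).
* The margin band uses Euclidean distance transforms with a half-pixel
  offset correction (`d ≤ r + 0.5` px); a tumor smaller than the inner
  offset collapses to a warning, not an error.
* Deconvolution guards `log 0` with ε = 1/512, which the forward model
  cancels exactly.
* Watershed uses tolerance 1 on the distance map; smoothing σ converts
  from µm via mpp.
* Hard-core placement retries 40 positions per cell and raises a
  placement error only for a systematic shortfall (> 25% unplaced at
  n ≥ 20); a couple of unplaced cells in a cramped fragment at tiny
  Poisson counts is ordinary crowding.
* Cohort training drops tissue classes with fewer than 10 patches (with a
  message) rather than aborting; direct training via
  `train_tissue_classifier()` keeps the hard error naming the class.
* Tie-breaks are fixed everywhere (class priority in label fusion,
  smallest pair in cut-off search), making every stage deterministic
  under a seed; reruns of `run_pipeline()` with the same config and seed
  reproduce output files byte for byte.

## 10. Problem sizes used by the tests

Unit tests run on 512–1024 px slides at 0.5 µm/px. The acceptance suite
uses the study conditions: a 30-slide cohort (10 per phenotype) of
2048² px slides at 0.25 µm/px through the full pipeline with derived
cut-offs; a 10-seed density-recovery study on dense 2048² px slides at
0.5 µm/px (~500+ CD8+ cells per compartment: densities 2.7e-3 iTC /
5.5e-3 sTC / 1.4e-3 IM, chosen to sit safely below the hard-core packing
limit of ≈1e-2 cells/µm²); and the ±500 µm band of a 2000 µm circular
tumor at 4 µm/px against the closed-form annulus.

## 11. Known limitations

Cohort-scale clinical quantities (mean analyzed areas of ~73 mm², ~3.3e4
CD8+ cells per case, cohort p-values) are outside desk scale and are used
only as generator parameters and direction checks. The shipped cut-offs
are not clinically validated; neither were the empirically defined ones
they stand in for. Lymph-node preexisting lymphoid tissue must be excluded
manually. The classifier is a compact texture/color model — adequate for
the synthetic contract and small cohorts, not a claim of parity with deep
segmentation networks on clinical slides. Dual immune phenotypes
(discordant compartments treated as a separate clinical entity) are not an
output category.
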