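# cd8pheno

Spatial CD8+ T-cell density scoring and immune phenotyping of chromogenic
IHC slides.

## The problem

The density and spatial distribution of CD8+ tumor-infiltrating T cells is
one of the most informative predictive biomarkers in immuno-oncology:
"inflamed" (clinically hot) tumors respond best to immune checkpoint
inhibition, while "excluded" and "desert" (cold) tumors do not. Visual
scoring of CD8 immunohistochemistry is poorly reproducible, and in
metastatic disease the invasive margin is often not even captured in the
biopsy. `cd8pheno` implements a standardized digital-pathology workflow for
chromogenic CD8 IHC (hematoxylin counterstain, Alkaline-Phosphatase red
chromogen) of melanoma metastases that:

1. separates the stains into optical-density channels (Beer–Lambert
   unmixing on a 3×3 stain basis),
2. classifies tissue into six classes (tumor, desmoplastic stroma,
   immune-infiltrated stroma, glass, pigment, hemorrhage/necrosis) with a
   patch-feature + random-forest classifier trained on annotated regions,
3. detects nuclei by a seeded watershed on the hematoxylin channel and
   filters them by nuclear size, roundness and optical density, then calls
   CD8 positivity from the AP-red OD in a peri-nuclear annulus,
4. builds the three scoring compartments from the pathologist's
   tumor-border annotation — intratumoral tumor center (iTC), stromal
   tumor center (sTC) and a 1 mm invasive-margin band (IM) — honoring
   exclusion polygons (artifacts, tertiary lymphoid structures,
   preexisting lymphoid tissue),
5. computes area-normalized densities iCD8, sCD8, imCD8 (cells/µm²) and
   translates them into the immune diagnosis with a two-threshold decision
   tree:

   ```
   iCD8 ≥ c_i            →  inflamed
   else sCD8 ≥ c_s       →  excluded
   else                  →  desert
   ```

   The margin is never required, so biopsies without an invasive margin
   are fully diagnosable. Cut-offs (c_i, c_s) are derived from a labeled
   cohort by exhaustive grid search maximizing balanced accuracy
   (`derive_cutoffs()`).
6. evaluates diagnostic accuracy per class (one-vs-rest sensitivity,
   specificity, precision), with Holm–Šídák-adjusted pairwise density
   comparisons and correlation/regression of repeated scorings.

Because clinical slides cannot ship with a package, `cd8pheno` includes a
first-class synthetic slide generator (`generate_slide()`): seeded layouts
of blob-shaped tumor nests with intratumoral stroma islands and artifact
patches, hard-core Poisson cell placement at phenotype-preset densities,
and a forward stain renderer — with exact per-cell ground truth, so every
pipeline stage is testable end to end.

## Worked example

```r
library(cd8pheno)

# a small synthetic cohort: 2 slides per phenotype, full pipeline
cfg <- list(n_per_phenotype = 2L, width_px = 1024L, height_px = 1024L,
            mpp = 0.5, n_tumor_nests = 2L)
rep <- run_pipeline(cfg, seed = 11)
print(rep$cutoffs)
#> Cut-offs (cells/um^2): iCD8 >= 0.0005837 -> inflamed; else sCD8 >= 0.0009865 -> excluded; else desert
print(rep$confusion)
#> Confusion matrix (rows = predicted, columns = pathologist diagnosis):
#>           truth
#> predicted  desert excluded inflamed
#>   desert        2        0        0
#>   excluded      0        2        0
#>   inflamed      0        0        2
rep$profiles[, c("phenotype_truth", "icd8", "scd8", "category")]
#>   phenotype_truth     icd8     scd8 category
#> 1          desert 0.000000 3.30e-04   desert
#> 2          desert 0.000043 7.17e-05   desert
#> 3        excluded 0.000372 1.64e-03 excluded
#> 4        excluded 0.000277 1.91e-03 excluded
#> 5        inflamed 0.000795 5.01e-03 inflamed
#> 6        inflamed 0.000916 4.15e-03 inflamed
```

Each profile row is one slide: `icd8`/`scd8` are CD8+ T cells per µm² of
the intratumoral and stromal tumor-center compartments measured by the
full image pipeline, and `category` is the diagnosis under the derived
cut-offs — here all six slides recover their generating phenotype. For a
single slide:

```r
sl  <- generate_slide("excluded", width_px = 1024, height_px = 1024,
                      mpp = 0.5, seed = 7)
res <- analyze_slide(sl$image, sl$annotations, rep$classifier)
print(res$profile)
#> CD8+ densities (cells/um^2): iCD8 0.000399 (36 / 9.02e+04 um^2), sCD8 0.00207 (28 / 1.35e+04 um^2), imCD8 absent (no margin)
classify_phenotype(res$profile, rep$cutoffs)$category
#> [1] "excluded"
```

A command-line front end with `simulate`, `segment`, `detect`,
`phenotype`, `evaluate` and `run` subcommands lives in
`inst/cli/cd8pheno.R`.

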