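test_that("layout generation is deterministic and honors degenerate fractions", {
  l1 <- generate_layout(512, 512, 0.5, 3, 0.3, 0.05, seed = 7)
  l2 <- generate_layout(512, 512, 0.5, 3, 0.3, 0.05, seed = 7)
  expect_identical(l1, l2)
  l3 <- generate_layout(512, 512, 0.5, 3, 0.3, 0.05, seed = 8)
  expect_false(identical(l1$tumor_polygons, l3$tumor_polygons))

  l0 <- generate_layout(512, 512, 0.5, 1, 0, 0, seed = 1)
  expect_length(l0$tumor_polygons, 1)
  expect_length(l0$intratumoral_stroma_polygons, 0)
  expect_length(l0$artifact_polygons, 0)

  expect_error(generate_layout(100, 512, 0.5), "256")
  expect_error(generate_layout(512, 512, 0.5, stroma_fraction = 1), "stroma_fraction")
  expect_error(generate_layout(512, 512, -1), "mpp")
})

test_that("tumor polygons cover the requested canvas fraction (rasterization oracle)", {
  # scaled-down analogue of a multi-nest whole-slide layout
  lay <- generate_layout(1024, 1024, 0.5, 4, 0.3, 0.05, seed = 3,
                         tumor_fraction = 0.4)
  mask <- rasterize_polygons(lay$tumor_polygons, 1024, 1024)
  coverage <- sum(mask) / 1024^2
  expect_lt(abs(coverage - 0.4) / 0.4, 0.10)
})

test_that("stroma islands lie inside their tumor nests and layouts partition area", {
  lay <- generate_layout(768, 768, 0.5, 2, 0.35, 0.04, seed = 11)
  tumor <- rasterize_polygons(lay$tumor_polygons, 768, 768)
  for (isl in lay$intratumoral_stroma_polygons) {
    expect_true(all(point_in_polygon(
      lay$tumor_polygons[[which.max(vapply(lay$tumor_polygons, function(p) {
        mean(point_in_polygon(p, isl[, 1], isl[, 2]))
      }, numeric(1)))]], isl[, 1], isl[, 2])))
  }
  cm <- layout_class_raster(lay)
  expect_true(all(cm$labels %in% 1:6))
})

test_that("placed cell counts follow the compartment Poisson law", {
  lay <- generate_layout(1024, 1024, 1, 1, 0, 0, seed = 2, tumor_fraction = 0.5)
  cmp <- layout_compartments(lay)
  area <- cmp$areas[["iTC"]]
  expect_gt(area, 4e5)
  # iCD8 density of an inflamed tumor center
  spec <- phenotype_spec("inflamed", 6e-4, 5e-3, 3e-3,
                         background_nucleus_density = 0)
  lambda <- 6e-4 * area
  counts <- vapply(1:12, function(s) {
    cells <- place_cells(lay, spec, seed = s, compartments = cmp)
    sum(cells$cd8 & cells$compartment == "iTC")
  }, numeric(1))
  # every replicate within 4 SD of the Poisson expectation
  expect_true(all(abs(counts - lambda) < 4 * sqrt(lambda)))

  # zero intensity -> no cells
  spec0 <- phenotype_spec("desert", 0, 0, 0, background_nucleus_density = 0)
  expect_identical(nrow(place_cells(lay, spec0, seed = 1, compartments = cmp)), 0L)
})

test_that("mean realized density converges to the requested density", {
  lay <- generate_layout(512, 512, 1, 1, 0, 0, seed = 4, tumor_fraction = 0.5)
  cmp <- layout_compartments(lay)
  area <- cmp$areas[["iTC"]]
  spec <- phenotype_spec("inflamed", 2e-3, 2e-3, 0, background_nucleus_density = 0)
  counts <- vapply(1:120, function(s) {
    cells <- place_cells(lay, spec, seed = s, compartments = cmp)
    sum(cells$cd8 & cells$compartment == "iTC")
  }, numeric(1))
  expect_lt(abs(mean(counts) / (2e-3 * area) - 1), 0.02)
})

test_that("hard-core placement rejects overlapping nuclei and impossible densities", {
  lay <- generate_layout(512, 512, 1, 1, 0, 0, seed = 5, tumor_fraction = 0.4)
  cmp <- layout_compartments(lay)
  spec <- phenotype_spec("inflamed", 5e-3, 1e-3, 0, background_nucleus_density = 0)
  cells <- place_cells(lay, spec, seed = 9, compartments = cmp)
  cc <- cells[cells$compartment == "iTC", ]
  d <- as.matrix(dist(cc[, c("x", "y")]))
  diag(d) <- Inf
  rmin <- outer(cc$radius_um, cc$radius_um, "+") * 1.2  # mpp = 1
  expect_true(all(d >= rmin - 1e-9))
  # a density beyond the hard-core packing limit must error, not hang
  spec_hi <- phenotype_spec("inflamed", 0.05, 1e-3, 0, background_nucleus_density = 0)
  expect_error(place_cells(lay, spec_hi, seed = 1, compartments = cmp),
               "placement")
})

test_that("ground-truth compartments agree with assign_cells on the same annotations", {
  sl <- small_slide("excluded", seed = 13, artifact_fraction = 0.03)
  re <- assign_cells(sl$cells, sl$compartments)
  expect_identical(re$compartment, sl$cells$compartment)
})

test_that("phenotype presets enforce their invariants", {
  expect_error(phenotype_spec("inflamed", 0, 1e-3, 0), "inflamed")
  expect_error(phenotype_spec("desert", 5e-3, 1e-4, 1e-4,
                              background_nucleus_density = 1e-3), "desert")
  expect_error(phenotype_spec("excluded", -1, 1e-3, 0), "non-negative")
  for (ph in c("desert", "excluded", "inflamed")) {
    expect_s3_class(phenotype_preset(ph), "phenotype_spec")
  }
})

test_that("rendering places stains where the ground truth says (deconvolution round trip)", {
  lay <- generate_layout(256, 256, 0.5, 1, 0, 0, seed = 1, tumor_fraction = 0.3)
  cmr <- layout_class_raster(lay)

  # empty cell list: no AP-red signal anywhere (no artifacts on this layout)
  img0 <- render_image(lay, data.frame(x = numeric(0), y = numeric(0),
                                       radius_um = numeric(0), cd8 = logical(0),
                                       compartment = character(0)),
                       class_map = cmr, seed = 2)
  od0 <- deconvolve_stains(img0, mpp = 0.5)
  expect_lt(mean(od0$ap_red), 0.02)

  # one CD8+ cell: AP-red local maximum at the cell position
  cell <- data.frame(x = 128, y = 120, radius_um = 3.5, cd8 = TRUE,
                     compartment = "iTC")
  img1 <- render_image(lay, cell, class_map = cmr, seed = 2)
  od1 <- deconvolve_stains(img1, mpp = 0.5)
  A <- matrix(as.numeric(EBImage::gblur(EBImage::Image(od1$ap_red), 1)), 256, 256)
  ix <- which(A == max(A), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((ix[[2]] - 1 - 128)^2 + (ix[[1]] - 1 - 120)^2), 2.5)

  # CD8- nuclei carry hematoxylin but no marker
  cell2 <- data.frame(x = 60, y = 60, radius_um = 3.5, cd8 = FALSE,
                      compartment = "iTC")
  img2 <- render_image(lay, cell2, class_map = cmr, seed = 2)
  od2 <- deconvolve_stains(img2, mpp = 0.5)
  expect_gt(od2$hematoxylin[61, 61], 0.6)
  expect_lt(od2$ap_red[61, 61], 0.15)

  expect_error(stain_params(bogus_key = 1), "unknown stain parameter")
})

test_that("generated slides are bit-identical under a fixed seed", {
  s1 <- small_slide("desert", seed = 21, width_px = 512, height_px = 512)
  s2 <- small_slide("desert", seed = 21, width_px = 512, height_px = 512)
  expect_identical(s1, s2)
})

test_that("slide export writes image, cells, annotations and spec", {
  sl <- small_slide("excluded", seed = 3, width_px = 512, height_px = 512)
  d <- withr::local_tempdir()
  paths <- write_slide(sl, d)
  expect_true(all(file.exists(paths)))
  img <- read_slide_image(paths[["image"]])
  expect_equal(img, sl$image, tolerance = 1e-7)
  cells <- read_cells(paths[["cells"]])
  expect_equal(nrow(cells), nrow(sl$cells))
  ann <- read_annotations(paths[["annotations"]])
  expect_equal(length(ann$tumor_border), length(sl$annotations$tumor_border))
  expect_equal(ann$mpp, sl$annotations$mpp)
})
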