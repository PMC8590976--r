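test_that("deconvolution recovers the forward stain model", {
  sv <- stain_vectors()
  # pure white -> zero OD in all channels
  white <- array(1, c(8, 8, 3))
  odw <- deconvolve_stains(white, sv)
  expect_lt(max(abs(c(odw$hematoxylin, odw$ap_red, odw$residual))), 1e-8)

  # forward-render known stain amounts, recover them (8-bit quantization aside)
  set.seed(5)
  H <- matrix(runif(64, 0, 1.2), 8, 8)
  A <- matrix(runif(64, 0, 1.2), 8, 8)
  R <- matrix(runif(64, 0, 0.6), 8, 8)
  img <- od_to_rgb(H, A, R, sv)
  od <- deconvolve_stains(img, sv)
  expect_equal(od$hematoxylin, H, tolerance = 1e-3)
  expect_equal(od$ap_red, A, tolerance = 1e-3)
  expect_equal(od$residual, R, tolerance = 1e-3)

  # a pixel with exactly the hematoxylin reference color at OD 1
  img1 <- od_to_rgb(matrix(1, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1), sv)
  od1 <- deconvolve_stains(img1, sv)
  expect_equal(od1$hematoxylin[1, 1], 1, tolerance = 1e-6)
  expect_lt(od1$ap_red[1, 1], 1e-6)
})

test_that("degenerate stain bases are rejected", {
  expect_error(stain_vectors(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)), "singular")
  expect_error(stain_vectors(c(-1, 0, 0)), "non-negative")
})

test_that("hematoxylin channel of a rendered slide tracks the nuclear mask", {
  sl <- small_slide("inflamed", seed = 4, width_px = 512, height_px = 512)
  od <- deconvolve_stains(sl$image, mpp = 0.5)
  nuc <- matrix(FALSE, 512, 512)
  for (i in seq_len(nrow(sl$cells))) {
    r <- sl$cells$radius_um[i] / 0.5
    xs <- max(0, floor(sl$cells$x[i] - r)):min(511, ceiling(sl$cells$x[i] + r))
    ys <- max(0, floor(sl$cells$y[i] - r)):min(511, ceiling(sl$cells$y[i] + r))
    dd <- outer((ys - sl$cells$y[i])^2, (xs - sl$cells$x[i])^2, "+")
    nuc[ys + 1, xs + 1] <- nuc[ys + 1, xs + 1] | (dd <= (0.8 * r)^2)
  }
  expect_gt(cor(as.numeric(od$hematoxylin), as.numeric(nuc)), 0.5)
  expect_gt(mean(od$hematoxylin[nuc]), 3 * mean(od$hematoxylin[!nuc]))
})

test_that("patch extraction labels by majority class and counts tiles", {
  sl <- small_slide("excluded", seed = 9, width_px = 512, height_px = 512,
                    artifact_fraction = 0.04)
  ds <- extract_patches(sl, sl$class_map, patch_px = 64, stride = 64)
  expect_equal(nrow(ds$features), 8 * 8)  # 512 / 64 tiling
  expect_true(all(ds$features$label %in% c("tumor", "desmoplastic_stroma",
                                           "immune_stroma", "glass", "pigment",
                                           "hemorrhage_necrosis")))
  # majority label of a sampled patch equals the dominant ground-truth class
  f <- ds$features[5, ]
  sub <- sl$class_map$labels[(f$y0 + 1):(f$y0 + 64), (f$x0 + 1):(f$x0 + 64)]
  expect_equal(f$label,
               c("tumor", "desmoplastic_stroma", "immune_stroma", "glass",
                 "pigment", "hemorrhage_necrosis")[which.max(tabulate(sub, 6))])
})

test_that("patch extraction from labeled regions keeps only interior patches", {
  sl <- small_slide("inflamed", seed = 2, width_px = 512, height_px = 512)
  nest <- sl$layout$tumor_polygons[[1]]
  regions <- list(list(polygon = nest, class = "tumor"))
  ds <- extract_patches(sl, regions, patch_px = 64, stride = 64)
  expect_gt(nrow(ds$features), 0)
  expect_true(all(ds$features$label == "tumor"))
  # a region smaller than one patch is skipped with a warning
  tiny <- list(list(polygon = circle_polygon(100, 100, 10, 16), class = "glass"))
  expect_warning(extract_patches(sl, tiny, patch_px = 64), "smaller than a patch")
  # empty annotation set -> empty dataset, no error
  ds0 <- extract_patches(sl, list(), patch_px = 64)
  expect_equal(nrow(ds0$features), 0)
})

test_that("trivially separable classes are learned perfectly and training is seeded", {
  # pure glass (near-white) vs pure pigment (brown-black) patch features:
  # separable by mean color alone
  set.seed(2)
  n <- 30
  mk <- function(mu, lab) {
    f <- as.data.frame(matrix(rep(mu, each = n), n) +
                         matrix(rnorm(n * 9, sd = 0.01), n))
    names(f) <- c("mean_h", "mean_ap", "mean_res", "sd_h", "sd_ap", "sd_res",
                  "mean_r", "mean_g", "mean_b")
    f$label <- lab; f$x0 <- 0L; f$y0 <- 0L
    f
  }
  glass <- mk(c(0.01, 0, 0.01, 0.005, 0.005, 0.005, 0.97, 0.97, 0.97), "glass")
  pigment <- mk(c(0.85, 0.45, 0.85, 0.06, 0.06, 0.06, 0.25, 0.15, 0.1), "pigment")
  sub <- structure(list(features = rbind(glass, pigment), patch_px = 64L,
                        stride = 64L, mpp = 0.5, vectors = stain_vectors(),
                        class_counts = NULL), class = "patch_dataset")
  clf <- train_tissue_classifier(sub, seed = 1)
  expect_equal(clf$holdout_accuracy, 1)

  sl <- small_slide("excluded", seed = 9, width_px = 512, height_px = 512,
                    artifact_fraction = 0.04)
  ds <- extract_patches(sl, sl$class_map, patch_px = 64, stride = 16)
  clf1 <- train_tissue_classifier(ds, seed = 5)
  clf2 <- train_tissue_classifier(ds, seed = 5)
  m1 <- classify_tissue(sl, clf1)
  m2 <- classify_tissue(sl, clf2)
  expect_identical(m1$labels, m2$labels)
})

test_that("training refuses starved or single-class datasets", {
  sl <- small_slide("inflamed", seed = 2, width_px = 512, height_px = 512)
  ds <- extract_patches(sl, sl$class_map, patch_px = 64, stride = 64)
  starved <- ds
  starved$features <- ds$features[c(which(ds$features$label == "tumor"),
                                    which(ds$features$label == "glass")[1:3]), ]
  expect_error(train_tissue_classifier(starved, seed = 1), "glass")
  mono <- ds
  mono$features <- ds$features[ds$features$label == "tumor", ]
  expect_error(train_tissue_classifier(mono, seed = 1), "2 tissue classes")
})

test_that("tissue classification generalizes across slides of the same generator", {
  sl <- small_slide("excluded", seed = 9, width_px = 1024, height_px = 1024,
                    artifact_fraction = 0.04)
  ds <- extract_patches(sl, sl$class_map, patch_px = 64, stride = 32)
  clf <- train_tissue_classifier(ds, seed = 5)
  expect_gte(clf$holdout_accuracy, 0.9)
  sl2 <- small_slide("inflamed", seed = 10, width_px = 1024, height_px = 1024,
                     artifact_fraction = 0.04)
  cm <- classify_tissue(sl2, clf)
  expect_gte(mean(cm$labels == sl2$class_map$labels), 0.85)
  # partition: every pixel carries exactly one of the six labels
  expect_true(all(cm$labels %in% 1:6))
  areas <- table(factor(cm$labels, levels = 1:6)) * cm$mpp^2
  expect_equal(sum(areas), 1024^2 * cm$mpp^2)
})

test_that("resolution mismatches between slide and classifier are refused", {
  sl <- small_slide("inflamed", seed = 2, width_px = 512, height_px = 512)
  ds <- extract_patches(sl, sl$class_map, patch_px = 64, stride = 16)
  clf <- train_tissue_classifier(ds, seed = 1)
  expect_error(classify_tissue(sl$image, clf, mpp = 2), "resolution")
})

test_that("classifier serialization round-trips", {
  sl <- small_slide("inflamed", seed = 2, width_px = 512, height_px = 512)
  ds <- extract_patches(sl, sl$class_map, patch_px = 64, stride = 16)
  clf <- train_tissue_classifier(ds, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, path)
  clf2 <- load_classifier(path)
  expect_identical(classify_tissue(sl, clf)$labels, classify_tissue(sl, clf2)$labels)
})
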