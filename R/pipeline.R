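# End-to-end pipeline: annotation -> tissue classification -> cell
# detection -> compartment assignment -> densities -> immune diagnosis ->
# cohort evaluation. The synthetic mode generates a seeded cohort, trains
# the tissue classifier on ground-truth-annotated patches (the stand-in for
# the pathologist-annotated training regions) and evaluates the derived
# cut-offs against the generating phenotypes.

#' Analyze one slide
#'
#' Runs the per-slide analysis chain: stain deconvolution, tissue
#' classification (unless a class map is supplied), invasive-margin band,
#' compartment mask, nucleus detection + morphometric filtering + marker
#' scoring, compartment assignment and density computation.
#'
#' @param image RGB array in `[0, 1]`.
#' @param annotations An [annotation_set()] (tumor border + exclusions).
#' @param classifier A trained `tissue_classifier` (ignored when
#'   `class_map` is given).
#' @param det_params A [detection_params()] list.
#' @param margin_halfwidth_um Invasive-margin half-width; 0 means no margin
#'   compartment.
#' @param class_map Optional precomputed [tissue_class_map()].
#' @param vectors Stain basis for deconvolution.
#' @return List with `cells`, `class_map`, `mask` and `profile`.
#' @export
analyze_slide <- function(image, annotations, classifier = NULL,
                          det_params = detection_params(),
                          margin_halfwidth_um = 0, class_map = NULL,
                          vectors = stain_vectors()) {
  stopifnot(inherits(annotations, "annotation_set"))
  od <- deconvolve_stains(image, vectors, mpp = annotations$mpp)
  if (is.null(class_map)) {
    if (is.null(classifier)) stop("need a classifier or a precomputed class map", call. = FALSE)
    class_map <- classify_tissue(image, classifier, mpp = annotations$mpp)
  }
  margin <- NULL
  if (margin_halfwidth_um > 0) {
    margin <- build_margin_band(annotations, margin_halfwidth_um)
  }
  mask <- build_compartment_mask(annotations, class_map, margin)
  cells <- detect_nuclei(od, det_params)
  cells <- filter_candidates(cells, det_params)
  cells <- score_marker(cells, od, det_params)
  cells <- assign_cells(cells, mask)
  profile <- compute_densities(cells, mask)
  list(cells = cells, class_map = class_map, mask = mask, profile = profile)
}

default_pipeline_config <- function() {
  list(
    mode = "synthetic",
    n_per_phenotype = 10L,
    width_px = 2048L, height_px = 2048L, mpp = 0.25,
    n_tumor_nests = 3L, stroma_fraction = 0.3, artifact_fraction = 0,
    tumor_fraction = 0.4, margin_halfwidth_um = 0,
    patch_px = 64L, max_patches_per_class = 300L,
    n_train_slides_per_phenotype = 1L,
    detection = list(),
    cutoffs = "derive",
    write_cells = FALSE
  )
}

#' Run the cohort pipeline
#'
#' In synthetic mode (the default), generates `n_per_phenotype` slides per
#' immune phenotype at the preset densities, trains the tissue classifier
#' on ground-truth-labeled patches from one slide per phenotype, analyzes
#' every slide end to end, derives density cut-offs against the generating
#' phenotypes (unless fixed cut-offs are configured), and cross-tabulates
#' the digital diagnoses against the generating phenotypes. All randomness
#' derives from `seed`; a rerun with the same config and seed reproduces
#' the outputs byte for byte.
#'
#' In `mode = "slides"`, a list of `config$slides` entries (`image` path,
#' `annotations` GeoJSON path, optional `id` and `reference` diagnosis) is
#' analyzed with a previously saved classifier (`config$classifier`) and
#' configured cut-offs.
#'
#' @param config List or path to a YAML file; unknown fields are an error.
#' @param seed Integer master seed (overrides `config$seed`).
#' @param outdir Output directory; when given, writes `profiles.csv`,
#'   `diagnoses.csv`, `cutoffs.yaml`, `metrics.csv`, `confusion.txt` and
#'   `manifest.json` (and per-slide cell tables when `write_cells`).
#' @return A `cohort_report`: list with `profiles` (data.frame), `cutoffs`,
#'   `confusion`, `metrics`, `agreement`, `classifier`, `config`.
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), c(names(base), "seed", "slides", "classifier"))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(base, config)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  det <- do.call(detection_params, cfg$detection)

  if (cfg$mode == "synthetic") {
    report <- run_synthetic_cohort(cfg, det, seed)
  } else if (cfg$mode == "slides") {
    report <- run_slide_list(cfg, det)
  } else {
    stop("unknown pipeline mode: ", cfg$mode, call. = FALSE)
  }
  report$config <- cfg
  report$seed <- seed
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

run_synthetic_cohort <- function(cfg, det, seed) {
  phenos <- rep(DIAGNOSIS_LEVELS, each = cfg$n_per_phenotype)
  set.seed(seed)
  slide_seeds <- sample.int(.Machine$integer.max - 1L, length(phenos))
  train_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  gen <- function(i) {
    generate_slide(phenos[i], width_px = cfg$width_px, height_px = cfg$height_px,
                   mpp = cfg$mpp, n_tumor_nests = cfg$n_tumor_nests,
                   stroma_fraction = cfg$stroma_fraction,
                   artifact_fraction = cfg$artifact_fraction,
                   tumor_fraction = cfg$tumor_fraction,
                   margin_halfwidth_um = cfg$margin_halfwidth_um,
                   seed = slide_seeds[i])
  }

  # tissue classifier trained on ground-truth-labeled patches of the first
  # slide(s) of each phenotype (pathologist-annotation stand-in)
  train_idx <- unlist(lapply(DIAGNOSIS_LEVELS, function(ph) {
    which(phenos == ph)[seq_len(cfg$n_train_slides_per_phenotype)]
  }))
  sets <- list()
  for (i in train_idx) {
    sl <- gen(i)
    sets[[length(sets) + 1L]] <- extract_patches(
      sl, sl$class_map, patch_px = cfg$patch_px, stride = cfg$patch_px %/% 2L,
      seed = train_seed, max_per_class = cfg$max_patches_per_class)
    rm(sl)
  }
  feat <- do.call(rbind, lapply(sets, function(s) s$features))
  # rare classes without enough training support are left to the remaining
  # classes rather than aborting the cohort
  tab <- table(feat$label)
  starved <- names(tab)[tab < 10]
  if (length(starved)) {
    message("dropping tissue class(es) with fewer than 10 training patches: ",
            paste(starved, collapse = ", "))
    feat <- feat[!feat$label %in% starved, , drop = FALSE]
  }
  pooled <- structure(list(features = feat, patch_px = cfg$patch_px,
                           stride = cfg$patch_px, mpp = cfg$mpp,
                           vectors = sets[[1]]$vectors,
                           class_counts = table(factor(feat$label, levels = TISSUE_CLASSES))),
                      class = "patch_dataset")
  classifier <- train_tissue_classifier(pooled, seed = train_seed)

  rows <- list()
  for (i in seq_along(phenos)) {
    sl <- gen(i)
    res <- analyze_slide(sl$image, sl$annotations, classifier,
                         det_params = det,
                         margin_halfwidth_um = cfg$margin_halfwidth_um)
    p <- res$profile
    rows[[i]] <- data.frame(
      slide_id = sprintf("synthetic_%03d", i), phenotype_truth = phenos[i],
      icd8 = p$icd8, scd8 = p$scd8, imcd8 = p$imcd8,
      area_itc = p$area_itc, area_stc = p$area_stc, area_im = p$area_im,
      n_itc = p$n_itc, n_stc = p$n_stc, n_im = p$n_im,
      n_cells = nrow(res$cells), seed = slide_seeds[i])
    attr(rows[[i]], "cells") <- if (isTRUE(cfg$write_cells)) res$cells else NULL
    rm(sl, res)
  }
  profiles <- do.call(rbind, rows)

  cutoffs <- if (identical(cfg$cutoffs, "derive")) {
    derive_cutoffs(profiles, profiles$phenotype_truth)
  } else {
    cutoff_config(cfg$cutoffs$c_i, cfg$cutoffs$c_s)
  }
  profiles$category <- vapply(seq_len(nrow(profiles)), function(i) {
    classify_phenotype(list(icd8 = profiles$icd8[i], scd8 = profiles$scd8[i]),
                       cutoffs)$category
  }, character(1))
  profiles$c_i <- cutoffs$c_i
  profiles$c_s <- cutoffs$c_s

  cm <- cross_tabulate(profiles$category, profiles$phenotype_truth)
  metrics <- class_metrics(cm)
  agreement <- mean(profiles$category == profiles$phenotype_truth)
  cell_tables <- lapply(rows, attr, "cells")
  list(profiles = profiles, cutoffs = cutoffs, confusion = cm,
       metrics = metrics, agreement = agreement, classifier = classifier,
       cell_tables = if (isTRUE(cfg$write_cells)) cell_tables else NULL)
}

run_slide_list <- function(cfg, det) {
  if (is.null(cfg$slides) || !length(cfg$slides)) {
    stop("mode 'slides' needs a non-empty config$slides list", call. = FALSE)
  }
  for (s in cfg$slides) {
    if (is.null(s$image) || !file.exists(s$image)) {
      stop("missing slide image: ", s$image %||% "<unset>", call. = FALSE)
    }
    if (is.null(s$annotations) || !file.exists(s$annotations)) {
      stop("missing annotation file: ", s$annotations %||% "<unset>", call. = FALSE)
    }
  }
  if (is.null(cfg$classifier)) stop("mode 'slides' needs config$classifier (path to a saved classifier)", call. = FALSE)
  classifier <- load_classifier(cfg$classifier)
  cutoffs <- if (identical(cfg$cutoffs, "derive")) {
    stop("mode 'slides' needs fixed cut-offs in the config", call. = FALSE)
  } else if (inherits(cfg$cutoffs, "cutoff_config")) {
    cfg$cutoffs
  } else {
    cutoff_config(cfg$cutoffs$c_i, cfg$cutoffs$c_s)
  }
  rows <- list()
  for (k in seq_along(cfg$slides)) {
    s <- cfg$slides[[k]]
    img <- read_slide_image(s$image)
    ann <- read_annotations(s$annotations)
    res <- analyze_slide(img, ann, classifier, det_params = det,
                         margin_halfwidth_um = cfg$margin_halfwidth_um)
    p <- res$profile
    rows[[k]] <- data.frame(
      slide_id = s$id %||% basename(s$image),
      phenotype_truth = s$reference %||% NA_character_,
      icd8 = p$icd8, scd8 = p$scd8, imcd8 = p$imcd8,
      area_itc = p$area_itc, area_stc = p$area_stc, area_im = p$area_im,
      n_itc = p$n_itc, n_stc = p$n_stc, n_im = p$n_im,
      n_cells = nrow(res$cells), seed = NA_integer_)
  }
  profiles <- do.call(rbind, rows)
  profiles$category <- vapply(seq_len(nrow(profiles)), function(i) {
    classify_phenotype(list(icd8 = profiles$icd8[i], scd8 = profiles$scd8[i]),
                       cutoffs)$category
  }, character(1))
  profiles$c_i <- cutoffs$c_i
  profiles$c_s <- cutoffs$c_s
  have_ref <- !is.na(profiles$phenotype_truth)
  cm <- NULL; metrics <- NULL; agreement <- NA_real_
  if (any(have_ref)) {
    cm <- cross_tabulate(profiles$category[have_ref], profiles$phenotype_truth[have_ref])
    metrics <- class_metrics(cm)
    agreement <- mean(profiles$category[have_ref] == profiles$phenotype_truth[have_ref])
  }
  list(profiles = profiles, cutoffs = cutoffs, confusion = cm,
       metrics = metrics, agreement = agreement, classifier = classifier,
       cell_tables = NULL)
}

#' Read a slide image from PNG or TIFF
#' @param path Image path.
#' @return RGB array `height x width x 3` in `[0, 1]`.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(format(df, digits = 10, scientific = NA, trim = TRUE),
                     file.path(outdir, name), row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(report$profiles, file.path(outdir, "profiles.csv"),
                   row.names = FALSE)
  write_cutoffs(report$cutoffs, file.path(outdir, "cutoffs.yaml"))
  if (!is.null(report$metrics)) {
    utils::write.csv(as.data.frame(report$metrics),
                     file.path(outdir, "metrics.csv"), row.names = FALSE)
  }
  if (!is.null(report$confusion)) {
    writeLines(format_confusion(report$confusion),
               file.path(outdir, "confusion.txt"))
  }
  if (!is.null(report$cell_tables)) {
    for (i in seq_along(report$cell_tables)) {
      if (!is.null(report$cell_tables[[i]])) {
        write_cells(report$cell_tables[[i]],
                    file.path(outdir, sprintf("cells_%03d.csv", i)))
      }
    }
  }
  manifest <- list(
    package = "cd8pheno",
    version = as.character(utils::packageVersion("cd8pheno")),
    seed = report$seed,
    agreement = report$agreement,
    cutoffs = list(c_i = report$cutoffs$c_i, c_s = report$cutoffs$c_s),
    config = report$config[setdiff(names(report$config), c("slides"))],
    classifier_hash = report$classifier$config_hash %||% NA
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
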