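# Synthetic chromogenic-IHC slide generator. Slides emulate a CD8
# immunohistochemistry stain of a melanoma metastasis: hematoxylin-blue
# nuclei, Alkaline-Phosphatase-red CD8 signal, tumor nests with intratumoral
# stroma islands, optional pigment / hemorrhage-necrosis / glass artifact
# patches, and a glass border around the tissue section. Every cell carries
# exact ground truth (position, CD8 status, compartment), which is what makes
# the downstream pipeline testable without clinical material.

TISSUE_CLASSES <- c("tumor", "desmoplastic_stroma", "immune_stroma",
                    "glass", "pigment", "hemorrhage_necrosis")
ARTIFACT_CLASSES <- c("glass", "pigment", "hemorrhage_necrosis")
COMPARTMENT_LEVELS <- c("iTC", "sTC", "IM", "excluded", "outside")

#' Per-phenotype CD8+ density presets
#'
#' Mean compartment densities (cells per square micron) of CD8+
#' tumor-infiltrating T cells for the three immune phenotypes, as observed in
#' a metastatic-melanoma discovery cohort: these are the generator's default
#' study conditions. `background_nucleus_density` controls the CD8-negative
#' nuclei (tumor cells, fibroblasts, other leukocytes) drawn in every tissue
#' compartment.
#'
#' @param phenotype One of `"desert"`, `"excluded"`, `"inflamed"`.
#' @param background_nucleus_density CD8-negative nucleus density
#'   (cells/um^2), all compartments.
#' @return A `phenotype_spec` object.
#' @export
phenotype_preset <- function(phenotype = c("desert", "excluded", "inflamed"),
                             background_nucleus_density = 1e-3) {
  phenotype <- match.arg(phenotype)
  d <- switch(phenotype,
    desert   = c(icd8 = 2e-5, scd8 = 2e-4, imcd8 = 6e-4),
    excluded = c(icd8 = 2e-4, scd8 = 2e-3, imcd8 = 2e-3),
    inflamed = c(icd8 = 6e-4, scd8 = 5e-3, imcd8 = 3e-3)
  )
  phenotype_spec(phenotype, d[["icd8"]], d[["scd8"]], d[["imcd8"]],
                 background_nucleus_density)
}

#' Construct a phenotype specification for the slide generator
#'
#' @param phenotype Category label the densities are meant to represent.
#' @param icd8_density CD8+ density in the intratumoral tumor center (iTC),
#'   cells/um^2.
#' @param scd8_density CD8+ density in the stromal tumor center (sTC).
#' @param imcd8_density CD8+ density in the invasive margin (IM).
#' @param background_nucleus_density CD8- nucleus density, all compartments.
#' @return A `phenotype_spec` object.
#' @export
phenotype_spec <- function(phenotype, icd8_density, scd8_density,
                           imcd8_density, background_nucleus_density = 1e-3) {
  phenotype <- match.arg(phenotype, c("desert", "excluded", "inflamed"))
  dens <- c(icd8_density, scd8_density, imcd8_density, background_nucleus_density)
  if (any(!is.finite(dens)) || any(dens < 0)) {
    stop("densities must be finite and non-negative", call. = FALSE)
  }
  if (phenotype == "inflamed" && icd8_density <= 0) {
    stop("an inflamed phenotype requires icd8_density > 0", call. = FALSE)
  }
  if (phenotype == "desert" &&
      any(c(icd8_density, scd8_density, imcd8_density) > background_nucleus_density)) {
    stop("a desert phenotype requires all CD8+ densities <= background_nucleus_density",
         call. = FALSE)
  }
  structure(list(phenotype = phenotype,
                 icd8_density = icd8_density,
                 scd8_density = scd8_density,
                 imcd8_density = imcd8_density,
                 background_nucleus_density = background_nucleus_density),
            class = "phenotype_spec")
}

#' @export
print.phenotype_spec <- function(x, ...) {
  cat(sprintf("Phenotype spec '%s' (cells/um^2): iCD8 %.2g, sCD8 %.2g, imCD8 %.2g, background %.2g\n",
              x$phenotype, x$icd8_density, x$scd8_density, x$imcd8_density,
              x$background_nucleus_density))
  invisible(x)
}

# Pick n blob centers inside a centered box with a greedy best-candidate rule
# (maximizes the minimum pairwise distance among k random candidates).
spread_centers <- function(n, xlo, xhi, ylo, yhi, k = 40L) {
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    cx <- stats::runif(k, xlo, xhi); cy <- stats::runif(k, ylo, yhi)
    if (i == 1) {
      pts[1, ] <- c(cx[1], cy[1])
    } else {
      d <- vapply(seq_len(k), function(j) {
        min((pts[seq_len(i - 1), 1] - cx[j])^2 + (pts[seq_len(i - 1), 2] - cy[j])^2)
      }, numeric(1))
      best <- which.max(d)
      pts[i, ] <- c(cx[best], cy[best])
    }
  }
  pts
}

#' Generate a seeded synthetic slide layout
#'
#' Lays out a tissue section on glass, `n_tumor_nests` blob-shaped tumor
#' nests whose summed polygon area equals `tumor_fraction` of the canvas,
#' intratumoral stroma islands (desmoplastic or immune-infiltrated) inside
#' each nest, and optional artifact patches. All geometry is drawn from a
#' seeded RNG, so identical arguments give an identical layout.
#'
#' @param width_px,height_px Canvas size in pixels (>= 256).
#' @param mpp Microns per pixel (> 0).
#' @param n_tumor_nests Number of tumor nests.
#' @param stroma_fraction Fraction of each nest occupied by intratumoral
#'   stroma islands, in `[0, 1)`.
#' @param artifact_fraction Fraction of the canvas covered by artifact
#'   patches (pigment, hemorrhage/necrosis, glass), in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param tumor_fraction Fraction of the canvas covered by tumor nest
#'   polygons.
#' @param margin_halfwidth_um Invasive-margin half-width stored with the
#'   layout and used when deriving ground-truth compartments; 0 emulates
#'   biopsy material without a captured margin.
#' @return A `slide_layout` object.
#' @export
generate_layout <- function(width_px, height_px, mpp, n_tumor_nests = 3L,
                            stroma_fraction = 0.3, artifact_fraction = 0,
                            seed = 1L, tumor_fraction = 0.4,
                            margin_halfwidth_um = 0) {
  if (width_px < 256 || height_px < 256) stop("canvas must be at least 256 x 256 px", call. = FALSE)
  if (mpp <= 0) stop("mpp must be > 0", call. = FALSE)
  if (stroma_fraction < 0 || stroma_fraction >= 1) stop("stroma_fraction must be in [0, 1)", call. = FALSE)
  if (artifact_fraction < 0 || artifact_fraction >= 1) stop("artifact_fraction must be in [0, 1)", call. = FALSE)
  if (tumor_fraction <= 0 || tumor_fraction >= 0.75) stop("tumor_fraction must be in (0, 0.75)", call. = FALSE)
  if (n_tumor_nests < 1) stop("need at least one tumor nest", call. = FALSE)
  set.seed(as.integer(seed))
  w <- width_px; h <- height_px

  # tissue section: one large smooth blob; outside it is glass
  tissue <- blob_polygon(w / 2, h / 2, 0.60 * min(w, h), amp = 0.10,
                         n_vertices = 72L)
  tissue <- clip_polygon_to_canvas(tissue, w, h)

  # tumor nests: equal target areas summing exactly to the requested coverage
  target_total <- tumor_fraction * w * h
  a_nest <- target_total / n_tumor_nests
  r0 <- sqrt(a_nest / pi)
  m <- 1.35 * r0
  xlo <- min(m, (w - 1) / 2); xhi <- max(w - 1 - m, (w - 1) / 2)
  ylo <- min(m, (h - 1) / 2); yhi <- max(h - 1 - m, (h - 1) / 2)
  centers <- spread_centers(n_tumor_nests, xlo, xhi, ylo, yhi)
  tumor_polygons <- vector("list", n_tumor_nests)
  for (i in seq_len(n_tumor_nests)) {
    p <- blob_polygon(centers[i, 1], centers[i, 2], r0, amp = 0.20)
    tumor_polygons[[i]] <- scale_polygon_to_area(p, a_nest)
  }

  # intratumoral stroma islands, strictly inside their nest
  stroma_polygons <- list()
  if (stroma_fraction > 0) {
    for (i in seq_len(n_tumor_nests)) {
      nest <- tumor_polygons[[i]]
      c0 <- colMeans(nest)
      rmin <- min(sqrt((nest[, 1] - c0[1])^2 + (nest[, 2] - c0[2])^2))
      target <- stroma_fraction * polygon_area(nest)
      n_isl <- max(1L, round(stroma_fraction * 6))
      a_isl <- target / n_isl
      placed_area <- 0
      tries <- 0L
      while (placed_area < target - a_isl / 2 && tries < 60L) {
        tries <- tries + 1L
        r_isl <- sqrt(a_isl / pi)
        ang <- stats::runif(1, 0, 2 * pi)
        dd <- stats::runif(1, 0, max(0, 0.60 * rmin - 1.25 * r_isl))
        px <- c0[1] + dd * cos(ang); py <- c0[2] + dd * sin(ang)
        isl <- blob_polygon(px, py, r_isl, amp = 0.18, n_vertices = 32L)
        isl <- scale_polygon_to_area(isl, a_isl)
        if (all(point_in_polygon(nest, isl[, 1], isl[, 2]))) {
          attr(isl, "stroma_type") <- sample(c("desmoplastic_stroma", "immune_stroma"), 1)
          stroma_polygons[[length(stroma_polygons) + 1L]] <- isl
          placed_area <- placed_area + a_isl
        }
      }
    }
  }

  # immune-infiltrated stroma patches outside the nests (texture realism and
  # so all six tissue classes appear on a default slide)
  outside_immune <- list()
  for (i in 1:2) {
    q <- blob_polygon(stats::runif(1, 0.2 * w, 0.8 * w),
                      stats::runif(1, 0.2 * h, 0.8 * h),
                      0.07 * min(w, h), amp = 0.25, n_vertices = 32L)
    outside_immune[[i]] <- clip_polygon_to_canvas(q, w, h)
  }

  # artifact patches
  artifact_polygons <- list()
  if (artifact_fraction > 0) {
    n_art <- max(1L, round(artifact_fraction * 20))
    a_art <- artifact_fraction * w * h / n_art
    for (i in seq_len(n_art)) {
      q <- blob_polygon(stats::runif(1, 0.15 * w, 0.85 * w),
                        stats::runif(1, 0.15 * h, 0.85 * h),
                        sqrt(a_art / pi), amp = 0.2, n_vertices = 32L)
      q <- clip_polygon_to_canvas(scale_polygon_to_area(q, a_art), w, h)
      attr(q, "artifact_label") <- sample(ARTIFACT_CLASSES, 1,
                                          prob = c(0.2, 0.4, 0.4))
      artifact_polygons[[i]] <- q
    }
  }

  structure(list(width_px = as.integer(w), height_px = as.integer(h),
                 mpp = mpp, tissue_polygon = tissue,
                 tumor_polygons = tumor_polygons,
                 intratumoral_stroma_polygons = stroma_polygons,
                 outside_immune_polygons = outside_immune,
                 artifact_polygons = artifact_polygons,
                 tumor_fraction = tumor_fraction,
                 stroma_fraction = stroma_fraction,
                 artifact_fraction = artifact_fraction,
                 margin_halfwidth_um = margin_halfwidth_um,
                 rng_seed = as.integer(seed)),
            class = "slide_layout")
}

#' @export
print.slide_layout <- function(x, ...) {
  cat(sprintf("Slide layout %d x %d px @ %.3g um/px: %d tumor nest(s), %d stroma island(s), %d artifact patch(es), seed %d\n",
              x$width_px, x$height_px, x$mpp, length(x$tumor_polygons),
              length(x$intratumoral_stroma_polygons),
              length(x$artifact_polygons), x$rng_seed))
  invisible(x)
}

#' Ground-truth tissue class raster of a layout
#'
#' Rasterizes the layout into the six-class tissue label map (paint order:
#' glass base, tissue section, immune-stroma patches, tumor nests,
#' intratumoral stroma islands, artifacts on top).
#'
#' @param layout A `slide_layout`.
#' @return A [tissue_class_map()] with ground-truth labels.
#' @export
layout_class_raster <- function(layout) {
  w <- layout$width_px; h <- layout$height_px
  lab <- matrix(match("glass", TISSUE_CLASSES), h, w)
  paint <- function(lab, polys, class_of) {
    for (p in polys) {
      m <- rasterize_polygons(p, w, h)
      lab[m] <- match(class_of(p), TISSUE_CLASSES)
    }
    lab
  }
  lab <- paint(lab, list(layout$tissue_polygon), function(p) "desmoplastic_stroma")
  lab <- paint(lab, layout$outside_immune_polygons, function(p) "immune_stroma")
  lab <- paint(lab, layout$tumor_polygons, function(p) "tumor")
  lab <- paint(lab, layout$intratumoral_stroma_polygons,
               function(p) attr(p, "stroma_type"))
  lab <- paint(lab, layout$artifact_polygons,
               function(p) attr(p, "artifact_label"))
  tissue_class_map(lab, layout$mpp)
}

#' Ground-truth annotations of a layout
#'
#' The tumor nest outlines become the pathologist-style tumor-border
#' annotation; artifact patches become exclusion polygons with reason
#' `"artifact"`.
#'
#' @param layout A `slide_layout`.
#' @return An [annotation_set()].
#' @export
layout_annotations <- function(layout) {
  exclusions <- lapply(layout$artifact_polygons, function(p) {
    list(polygon = p, reason = "artifact")
  })
  annotation_set(tumor_border = layout$tumor_polygons,
                 exclusions = exclusions,
                 mpp = layout$mpp,
                 width_px = layout$width_px, height_px = layout$height_px)
}

#' Ground-truth compartment mask of a layout
#'
#' Builds the iTC / sTC / IM / excluded / outside compartment mask from the
#' layout's own annotations and class raster, using the layout's stored
#' invasive-margin half-width.
#'
#' @param layout A `slide_layout`.
#' @param class_map Optional precomputed ground-truth class map.
#' @return A `compartment_mask`.
#' @export
layout_compartments <- function(layout, class_map = NULL) {
  if (is.null(class_map)) class_map <- layout_class_raster(layout)
  ann <- layout_annotations(layout)
  margin <- NULL
  if (layout$margin_halfwidth_um > 0) {
    margin <- build_margin_band(ann, layout$margin_halfwidth_um)
  }
  build_compartment_mask(ann, class_map, margin)
}

# Hard-core sequential placement of n points among candidate pixels.
# Minimum center distance between two cells is `min_factor` times the sum of
# their radii (radii in um, positions in px). Returns a data.frame; throws a
# placement error if more than 25% of the requested points cannot be placed.
place_hardcore <- function(n, pix_xy, radii_um, mpp, grid_env, min_factor = 1.2,
                           tries_per_cell = 40L) {
  if (n == 0L || nrow(pix_xy) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), radius_um = numeric(0)))
  }
  g <- grid_env$cell_px
  xs <- numeric(n); ys <- numeric(n); rs <- numeric(n)
  placed <- 0L
  streak <- 0L                           # consecutive placement failures
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(tries_per_cell)) {
      j <- sample.int(nrow(pix_xy), 1L)
      x <- pix_xy[j, 1] + stats::runif(1, -0.49, 0.49)
      y <- pix_xy[j, 2] + stats::runif(1, -0.49, 0.49)
      gx <- floor(x / g); gy <- floor(y / g)
      clash <- FALSE
      for (dx in -1:1) for (dy in -1:1) {
        key <- paste0(gx + dx, ",", gy + dy)
        pts <- grid_env$cells[[key]]
        if (!is.null(pts)) {
          dmin <- min_factor * (radii_um[i] + pts[, 3]) / mpp
          if (any((pts[, 1] - x)^2 + (pts[, 2] - y)^2 < dmin^2)) { clash <- TRUE; break }
        }
      }
      if (!clash) {
        placed <- placed + 1L
        xs[placed] <- x; ys[placed] <- y; rs[placed] <- radii_um[i]
        key <- paste0(gx, ",", gy)
        grid_env$cells[[key]] <- rbind(grid_env$cells[[key]], c(x, y, radii_um[i]))
        ok <- TRUE
        break
      }
    }
    streak <- if (ok) 0L else streak + 1L
    if (streak >= 100L) break            # saturated: bail out early
  }
  # a systematic shortfall means the requested density exceeds what the
  # hard-core constraint can pack; a couple of unplaced cells at tiny n is
  # ordinary crowding and not an error
  if (n >= 20L && placed < 0.75 * n) {
    stop(sprintf("cell placement failed: only %d of %d cells placed; density too high for the hard-core constraint", placed, n), call. = FALSE)
  }
  data.frame(x = xs[seq_len(placed)], y = ys[seq_len(placed)],
             radius_um = rs[seq_len(placed)])
}

#' Place ground-truth cells on a layout
#'
#' CD8+ cells are placed as a homogeneous Poisson process per compartment at
#' the requested densities (expected count = density x compartment area in
#' um^2); CD8- background nuclei are placed at the background density in all
#' tissue compartments. A hard-core rejection rule keeps nuclei from
#' overlapping (minimum center distance 1.2x the summed radii); nuclear radii
#' are drawn from N(3.5, 0.5) um truncated to the range 2-6 um. Cells never fall in
#' excluded (artifact) regions because those pixels belong to no placement
#' compartment.
#'
#' @param layout A `slide_layout`.
#' @param spec A [phenotype_spec()].
#' @param seed Integer RNG seed.
#' @param compartments Optional precomputed ground-truth `compartment_mask`.
#' @return `data.frame` with columns `x`, `y` (0-based px), `radius_um`,
#'   `cd8` (logical), `compartment`.
#' @export
place_cells <- function(layout, spec, seed = 1L, compartments = NULL) {
  stopifnot(inherits(layout, "slide_layout"), inherits(spec, "phenotype_spec"))
  if (is.null(compartments)) compartments <- layout_compartments(layout)
  set.seed(as.integer(seed))
  mpp <- layout$mpp
  lab <- compartments$labels
  grid_env <- new.env(parent = emptyenv())
  grid_env$cells <- list()
  grid_env$cell_px <- max(4, ceiling(1.2 * 2 * 6 / mpp))

  draw_radii <- function(n) pmin(6, pmax(2, stats::rnorm(n, 3.5, 0.5)))
  sample_comp <- function(code, density, cd8) {
    idx <- which(lab == code)
    if (!length(idx)) return(NULL)
    area_um2 <- length(idx) * mpp^2
    n <- stats::rpois(1, density * area_um2)
    if (n == 0) return(NULL)
    pix_xy <- cbind(((idx - 1) %/% nrow(lab)),   # x = column - 1
                    ((idx - 1) %% nrow(lab)))    # y = row - 1
    pts <- place_hardcore(n, pix_xy, draw_radii(n), mpp, grid_env)
    if (!nrow(pts)) return(NULL)
    pts$cd8 <- cd8
    pts$compartment <- COMPARTMENT_LEVELS[code]
    pts
  }

  out <- list()
  cd8_dens <- c(iTC = spec$icd8_density, sTC = spec$scd8_density,
                IM = spec$imcd8_density)
  for (comp in names(cd8_dens)) {
    out[[length(out) + 1L]] <- sample_comp(match(comp, COMPARTMENT_LEVELS),
                                           cd8_dens[[comp]], TRUE)
  }
  for (comp in c("iTC", "sTC", "IM", "outside")) {
    out[[length(out) + 1L]] <- sample_comp(match(comp, COMPARTMENT_LEVELS),
                                           spec$background_nucleus_density, FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(x = numeric(0), y = numeric(0), radius_um = numeric(0),
                      cd8 = logical(0), compartment = character(0)))
  }
  cells <- do.call(rbind, out)
  rownames(cells) <- NULL
  cells
}

#' Rendering parameters of the forward stain model
#'
#' @param vectors Stain OD basis, see [stain_vectors()].
#' @param nucleus_od Peak hematoxylin OD of a nucleus.
#' @param marker_od Peak AP-red OD over a CD8+ cell.
#' @param marker_ring_um Width of the AP-red rim beyond the nuclear boundary
#'   (the chromogen is membranous/cytoplasmic).
#' @param noise_sd Gaussian RGB sensor noise (transmittance units).
#' @param ... Unknown keys raise a configuration error.
#' @return A `stain_params` list.
#' @export
stain_params <- function(vectors = stain_vectors(), nucleus_od = 0.9,
                         marker_od = 0.9, marker_ring_um = 1.5,
                         noise_sd = 0.008, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown stain parameter key(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(vectors, "stain_vectors")) stop("'vectors' must be a stain_vectors object", call. = FALSE)
  list(vectors = vectors, nucleus_od = nucleus_od, marker_od = marker_od,
       marker_ring_um = marker_ring_um, noise_sd = noise_sd)
}

# Per-class base optical densities (hematoxylin, AP-red, residual) and
# per-class hematoxylin texture noise SD. Immune-infiltrated stroma gets a
# strong speckle texture (lymphocyte-rich chromatin), desmoplastic stroma is
# smooth and eosinophilic, pigment is dark in all channels.
class_base_od <- function() {
  rbind(tumor               = c(0.18, 0.00, 0.30),
        desmoplastic_stroma = c(0.06, 0.00, 0.36),
        immune_stroma       = c(0.13, 0.00, 0.20),
        glass               = c(0.012, 0.000, 0.010),
        pigment             = c(0.85, 0.45, 0.85),
        hemorrhage_necrosis = c(0.09, 0.08, 0.55))
}
class_texture_sd <- function() {
  c(tumor = 0.035, desmoplastic_stroma = 0.015, immune_stroma = 0.085,
    glass = 0.004, pigment = 0.06, hemorrhage_necrosis = 0.05)
}

#' Render a synthetic slide image
#'
#' Applies the forward stain model: per-class base optical densities plus
#' per-class texture noise, hematoxylin ellipses for every nucleus, an
#' AP-red chromogen footprint (peaked at the cell center, extending
#' `marker_ring_um` beyond the nuclear rim) for CD8+ cells, then
#' Beer-Lambert conversion to RGB with sensor noise and 8-bit quantization.
#'
#' @param layout A `slide_layout`.
#' @param cells Cell table from [place_cells()].
#' @param params A [stain_params()] list.
#' @param class_map Optional precomputed ground-truth class map.
#' @param seed Seed for texture and sensor noise.
#' @return RGB array `height x width x 3` in `[0, 1]`, quantized to 8 bits.
#' @export
render_image <- function(layout, cells, params = stain_params(),
                         class_map = NULL, seed = 1L) {
  if (is.null(class_map)) class_map <- layout_class_raster(layout)
  set.seed(as.integer(seed))
  h <- layout$height_px; w <- layout$width_px; mpp <- layout$mpp
  lab <- class_map$labels
  base <- class_base_od()
  tex <- class_texture_sd()
  H <- matrix(base[TISSUE_CLASSES, 1][lab], h, w)
  A <- matrix(base[TISSUE_CLASSES, 2][lab], h, w)
  R <- matrix(base[TISSUE_CLASSES, 3][lab], h, w)
  sd_map <- tex[TISSUE_CLASSES][as.integer(lab)]
  H <- H + matrix(abs(stats::rnorm(h * w)) * sd_map, h, w)
  R <- R + matrix(stats::rnorm(h * w, sd = 0.4) * sd_map, h, w)
  R[R < 0] <- 0

  ring_px <- params$marker_ring_um / mpp
  if (nrow(cells)) {
    ecc <- stats::runif(nrow(cells), 0.75, 1)
    th <- stats::runif(nrow(cells), 0, pi)
    for (i in seq_len(nrow(cells))) {
      a <- cells$radius_um[i] / mpp
      b <- a * ecc[i]
      ext <- a + if (cells$cd8[i]) ring_px else 0
      x0 <- max(0, floor(cells$x[i] - ext)); x1 <- min(w - 1, ceiling(cells$x[i] + ext))
      y0 <- max(0, floor(cells$y[i] - ext)); y1 <- min(h - 1, ceiling(cells$y[i] + ext))
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      dx <- outer(rep(1, length(ys)), xs - cells$x[i])
      dy <- outer(ys - cells$y[i], rep(1, length(xs)))
      u <- dx * cos(th[i]) + dy * sin(th[i])
      v <- -dx * sin(th[i]) + dy * cos(th[i])
      rho <- sqrt((u / a)^2 + (v / b)^2)
      nuc <- rho <= 1
      if (any(nuc)) {
        sub <- H[ys + 1L, xs + 1L]
        val <- params$nucleus_od * (0.85 + 0.25 * (1 - rho[nuc]^2))
        sub[nuc] <- pmax(sub[nuc], val)
        H[ys + 1L, xs + 1L] <- sub
      }
      if (cells$cd8[i]) {
        mk <- rho <= 1 + ring_px / a
        if (any(mk)) {
          sub <- A[ys + 1L, xs + 1L]
          val <- params$marker_od * (1 - 0.35 * rho[mk] / (1 + ring_px / a))
          sub[mk] <- pmax(sub[mk], val)
          A[ys + 1L, xs + 1L] <- sub
        }
      }
    }
  }

  img <- od_to_rgb(H, A, R, params$vectors)
  img <- img + array(stats::rnorm(length(img), sd = params$noise_sd), dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  array(round(img * 255) / 255, dim(img))
}

#' Generate a complete synthetic slide
#'
#' Convenience wrapper chaining [generate_layout()], [place_cells()] and
#' [render_image()] under one seed; returns the rendered image together with
#' all ground truth.
#'
#' @param spec A [phenotype_spec()] or a phenotype name understood by
#'   [phenotype_preset()].
#' @param width_px,height_px,mpp,n_tumor_nests,stroma_fraction,artifact_fraction,tumor_fraction,margin_halfwidth_um
#'   Passed to [generate_layout()].
#' @param params Rendering parameters, see [stain_params()].
#' @param seed Integer master seed (all stages are derived from it).
#' @return A `synthetic_slide`: list with `image`, `layout`, `cells`,
#'   `annotations`, `class_map`, `compartments`, `spec`, `seed`.
#' @export
generate_slide <- function(spec = "inflamed", width_px = 2048L,
                           height_px = 2048L, mpp = 0.25, n_tumor_nests = 3L,
                           stroma_fraction = 0.3, artifact_fraction = 0,
                           tumor_fraction = 0.4, margin_halfwidth_um = 0,
                           params = stain_params(), seed = 1L) {
  if (is.character(spec)) spec <- phenotype_preset(spec)
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  layout <- generate_layout(width_px, height_px, mpp, n_tumor_nests,
                            stroma_fraction, artifact_fraction, seed = sub[1],
                            tumor_fraction = tumor_fraction,
                            margin_halfwidth_um = margin_halfwidth_um)
  class_map <- layout_class_raster(layout)
  compartments <- layout_compartments(layout, class_map)
  cells <- place_cells(layout, spec, seed = sub[2], compartments = compartments)
  image <- render_image(layout, cells, params, class_map = class_map,
                        seed = sub[3])
  structure(list(image = image, layout = layout, cells = cells,
                 annotations = layout_annotations(layout),
                 class_map = class_map, compartments = compartments,
                 spec = spec, seed = as.integer(seed)),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("Synthetic slide (%s): %d x %d px @ %.3g um/px, %d cells (%d CD8+), seed %d\n",
              x$spec$phenotype, x$layout$width_px, x$layout$height_px,
              x$layout$mpp, nrow(x$cells), sum(x$cells$cd8), x$seed))
  invisible(x)
}

#' Write a synthetic slide to disk
#'
#' Writes the image (PNG or TIFF), the ground-truth cell table (CSV with
#' columns x, y, radius_um, cd8, compartment), the annotations (GeoJSON) and
#' the phenotype spec (YAML) into a directory.
#'
#' @param slide A `synthetic_slide`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_slide <- function(slide, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0("slide.", ifelse(format == "png", "png", "tif")))
  if (format == "png") {
    png::writePNG(slide$image, img_path)
  } else {
    tiff::writeTIFF(slide$image, img_path, bits.per.sample = 8L)
  }
  cells_path <- file.path(dir, "cells.csv")
  utils::write.csv(slide$cells, cells_path, row.names = FALSE)
  ann_path <- file.path(dir, "annotations.geojson")
  write_annotations(slide$annotations, ann_path)
  spec_path <- file.path(dir, "spec.yaml")
  yaml::write_yaml(unclass(slide$spec), spec_path)
  invisible(c(image = img_path, cells = cells_path, annotations = ann_path,
              spec = spec_path))
}
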