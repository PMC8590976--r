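# Tumor-compartment geometry. The scoring compartments follow the
# Immuno-Oncology Biomarker Working Group convention: a tumor center split
# into an intratumoral (iTC, tumor cell nests) and a stromal (sTC,
# intratumoral stroma) compartment, plus a 1 mm invasive-margin band (IM)
# centered on the annotated tumor border. Exclusion polygons (artifacts,
# tertiary lymphoid structures, preexisting lymphoid tissue of lymph nodes)
# and artifact-classed pixels never enter any density denominator.

EXCLUSION_REASONS <- c("artifact", "tertiary_lymphoid_structure",
                       "preexisting_lymphoid", "other")

#' Construct a pathologist-style annotation set
#'
#' @param tumor_border List of simple polygons (`n x 2` matrices, pixel
#'   coordinates) outlining the tumor.
#' @param exclusions List of `list(polygon = <matrix>, reason = <string>)`
#'   entries; reasons must come from `"artifact"`,
#'   `"tertiary_lymphoid_structure"`, `"preexisting_lymphoid"`, `"other"`.
#' @param mpp Microns per pixel.
#' @param width_px,height_px Canvas size the coordinates refer to.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(tumor_border, exclusions = list(), mpp,
                           width_px, height_px) {
  if (is.matrix(tumor_border)) tumor_border <- list(tumor_border)
  stopifnot(length(tumor_border) >= 0, mpp > 0)
  for (p in tumor_border) stopifnot(is.matrix(p), ncol(p) == 2, nrow(p) >= 3)
  for (e in exclusions) {
    stopifnot(is.list(e), is.matrix(e$polygon))
    if (!e$reason %in% EXCLUSION_REASONS) {
      stop("unknown exclusion reason: ", e$reason, call. = FALSE)
    }
  }
  structure(list(tumor_border = tumor_border, exclusions = exclusions,
                 mpp = mpp, width_px = as.integer(width_px),
                 height_px = as.integer(height_px)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d tumor-border polygon(s), %d exclusion(s), %d x %d px @ %.3g um/px\n",
              length(x$tumor_border), length(x$exclusions), x$width_px,
              x$height_px, x$mpp))
  invisible(x)
}

#' Write annotations as GeoJSON
#'
#' Emits a FeatureCollection of polygon features with property `role`
#' (`"tumor_border"` or `"exclusion"`, the latter with property `reason`);
#' `mpp`, `width_px`, `height_px` are stored as collection-level properties.
#' Coordinates are in pixel units.
#'
#' @param annotations An [annotation_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  poly_coords <- function(p) {
    ring <- rbind(p, p[1, , drop = FALSE])
    list(lapply(seq_len(nrow(ring)), function(i) unname(ring[i, ])))
  }
  feats <- c(
    lapply(annotations$tumor_border, function(p) {
      list(type = "Feature", properties = list(role = "tumor_border"),
           geometry = list(type = "Polygon", coordinates = poly_coords(p)))
    }),
    lapply(annotations$exclusions, function(e) {
      list(type = "Feature",
           properties = list(role = "exclusion", reason = e$reason),
           geometry = list(type = "Polygon", coordinates = poly_coords(e$polygon)))
    })
  )
  obj <- list(type = "FeatureCollection",
              properties = list(mpp = annotations$mpp,
                                width_px = annotations$width_px,
                                height_px = annotations$height_px),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotations from GeoJSON
#'
#' Counterpart of [write_annotations()]. Features with role `"artifact"` are
#' accepted and mapped to exclusions with reason `"artifact"`.
#'
#' @param path GeoJSON file path.
#' @param mpp,width_px,height_px Overrides when the file lacks collection
#'   properties.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, mpp = NULL, width_px = NULL, height_px = NULL) {
  obj <- jsonlite::read_json(path)
  props <- obj$properties
  mpp <- mpp %||% props$mpp
  width_px <- width_px %||% props$width_px
  height_px <- height_px %||% props$height_px
  if (is.null(mpp) || is.null(width_px) || is.null(height_px)) {
    stop("GeoJSON lacks mpp/width_px/height_px metadata; pass them explicitly",
         call. = FALSE)
  }
  tumor <- list(); excl <- list()
  for (f in obj$features) {
    ring <- f$geometry$coordinates[[1]]
    p <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    if (nrow(p) > 3 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    role <- f$properties$role %||% "tumor_border"
    if (role == "tumor_border") {
      tumor[[length(tumor) + 1L]] <- p
    } else if (role %in% c("exclusion", "artifact")) {
      excl[[length(excl) + 1L]] <- list(polygon = p,
                                        reason = f$properties$reason %||% "artifact")
    }
  }
  annotation_set(tumor, excl, mpp = mpp, width_px = width_px,
                 height_px = height_px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a tissue class map
#'
#' @param labels Integer matrix with values indexing the six tissue classes
#'   `tumor`, `desmoplastic_stroma`, `immune_stroma`, `glass`, `pigment`,
#'   `hemorrhage_necrosis`.
#' @param mpp Microns per pixel.
#' @return A `tissue_class_map` object.
#' @export
tissue_class_map <- function(labels, mpp) {
  stopifnot(is.matrix(labels), mpp > 0)
  labs <- as.integer(labels)
  if (any(is.na(labs)) || any(labs < 1L) || any(labs > length(TISSUE_CLASSES))) {
    stop("class labels must index the six tissue classes", call. = FALSE)
  }
  structure(list(labels = matrix(labs, nrow(labels), ncol(labels)),
                 classes = TISSUE_CLASSES, mpp = mpp),
            class = "tissue_class_map")
}

#' @export
print.tissue_class_map <- function(x, ...) {
  cat(sprintf("Tissue class map %d x %d px @ %.3g um/px\n", nrow(x$labels),
              ncol(x$labels), x$mpp))
  tab <- table(factor(TISSUE_CLASSES[x$labels], levels = TISSUE_CLASSES))
  print(round(100 * tab / sum(tab), 1))
  invisible(x)
}

#' Build the invasive-margin band
#'
#' Returns the region within `band_halfwidth_um` on each side of the
#' annotated tumor border (total width 1 mm at the default), computed by
#' distance transforms of the rasterized tumor mask and clipped to the
#' canvas. If the tumor is so small that the inner offset collapses (every
#' tumor pixel lies within the band) a warning is raised.
#'
#' @param annotations An [annotation_set()] with a non-empty tumor border.
#' @param band_halfwidth_um Band half-width in microns (default 500, i.e. a
#'   1 mm band centered on the border).
#' @return Logical `height x width` matrix (`TRUE` inside the band) with
#'   attributes `band_halfwidth_um` and `mpp`.
#' @export
build_margin_band <- function(annotations, band_halfwidth_um = 500) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (!length(annotations$tumor_border)) stop("tumor border annotation is empty", call. = FALSE)
  if (band_halfwidth_um < 0) stop("band_halfwidth_um must be >= 0", call. = FALSE)
  h <- annotations$height_px; w <- annotations$width_px
  band <- matrix(FALSE, h, w)
  if (band_halfwidth_um > 0) {
    r_px <- band_halfwidth_um / annotations$mpp
    tumor <- rasterize_polygons(annotations$tumor_border, w, h)
    if (any(tumor) && !all(tumor)) {
      din <- EBImage::distmap(EBImage::Image(tumor * 1))
      dout <- EBImage::distmap(EBImage::Image((!tumor) * 1))
      din <- matrix(as.numeric(din), h, w)
      dout <- matrix(as.numeric(dout), h, w)
      band <- (tumor & din <= r_px + 0.5) | (!tumor & dout <= r_px + 0.5)
      if (all(din[tumor] <= r_px + 0.5)) {
        warning("inner margin offset collapses: the whole tumor lies within the band")
      }
    } else if (all(tumor)) {
      warning("tumor border covers the entire canvas; margin band is empty")
    }
  }
  attr(band, "band_halfwidth_um") <- band_halfwidth_um
  attr(band, "mpp") <- annotations$mpp
  band
}

#' Build the compartment mask
#'
#' Partitions every pixel into `iTC`, `sTC`, `IM`, `excluded` or `outside`.
#' Precedence: exclusion polygons and artifact-classed pixels (glass,
#' pigment, hemorrhage/necrosis) dominate, then the invasive-margin band,
#' then the tumor-center subdivision (tumor-classed pixels inside the border
#' become iTC, stroma-classed pixels become sTC); everything else is
#' outside.
#'
#' @param annotations An [annotation_set()].
#' @param class_map A [tissue_class_map()] of the same shape and resolution.
#' @param margin Optional band mask from [build_margin_band()]; `NULL` means
#'   no margin compartment (biopsy without captured margin).
#' @return A `compartment_mask`: list with integer `labels` matrix (levels
#'   `iTC`, `sTC`, `IM`, `excluded`, `outside`), named `areas` vector in
#'   um^2, and `mpp`.
#' @export
build_compartment_mask <- function(annotations, class_map, margin = NULL) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(class_map, "tissue_class_map"))
  h <- annotations$height_px; w <- annotations$width_px
  if (nrow(class_map$labels) != h || ncol(class_map$labels) != w) {
    stop("class map shape does not match the annotation canvas", call. = FALSE)
  }
  if (abs(class_map$mpp - annotations$mpp) > 1e-9 * annotations$mpp) {
    stop("class map and annotations disagree on mpp", call. = FALSE)
  }
  cls <- class_map$labels
  tumor_mask <- rasterize_polygons(annotations$tumor_border, w, h)
  excl <- matrix(FALSE, h, w)
  for (e in annotations$exclusions) excl <- excl | rasterize_polygons(e$polygon, w, h)
  excl <- excl | matrix(TISSUE_CLASSES[cls] %in% ARTIFACT_CLASSES, h, w)

  lab <- matrix(match("outside", COMPARTMENT_LEVELS), h, w)
  inside <- tumor_mask & !excl
  if (!is.null(margin)) {
    if (!all(dim(margin) == c(h, w))) stop("margin band shape mismatch", call. = FALSE)
    im <- margin & !excl
    lab[im] <- match("IM", COMPARTMENT_LEVELS)
    inside <- inside & !im
  }
  is_tumor_px <- cls == match("tumor", TISSUE_CLASSES)
  is_stroma_px <- cls %in% match(c("desmoplastic_stroma", "immune_stroma"), TISSUE_CLASSES)
  lab[inside & is_tumor_px] <- match("iTC", COMPARTMENT_LEVELS)
  lab[inside & matrix(is_stroma_px, h, w)] <- match("sTC", COMPARTMENT_LEVELS)
  lab[excl] <- match("excluded", COMPARTMENT_LEVELS)

  counts <- tabulate(lab, nbins = length(COMPARTMENT_LEVELS))
  areas <- counts * annotations$mpp^2
  names(areas) <- COMPARTMENT_LEVELS
  structure(list(labels = lab, areas = areas, mpp = annotations$mpp),
            class = "compartment_mask")
}

#' @export
print.compartment_mask <- function(x, ...) {
  cat(sprintf("Compartment mask %d x %d px @ %.3g um/px; areas (um^2):\n",
              nrow(x$labels), ncol(x$labels), x$mpp))
  print(signif(x$areas, 4))
  invisible(x)
}

#' Assign detected cells to compartments
#'
#' Looks up the compartment label at each cell's centroid pixel. Centroids
#' outside the mask bounds are labeled `outside` with a warning.
#'
#' @param cells Cell table with columns `x`/`y` or `x_px`/`y_px` (0-based
#'   pixel coordinates).
#' @param mask A `compartment_mask`.
#' @return The cell table with its `compartment` column set.
#' @export
assign_cells <- function(cells, mask) {
  stopifnot(inherits(mask, "compartment_mask"))
  xc <- if ("x_px" %in% names(cells)) cells$x_px else cells$x
  yc <- if ("y_px" %in% names(cells)) cells$y_px else cells$y
  if (is.null(xc) || is.null(yc)) stop("cell table needs x/y columns", call. = FALSE)
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  col <- round(xc) + 1L; row <- round(yc) + 1L
  oob <- col < 1L | col > w | row < 1L | row > h
  comp <- rep("outside", length(xc))
  if (any(!oob)) {
    comp[!oob] <- COMPARTMENT_LEVELS[mask$labels[cbind(row[!oob], col[!oob])]]
  }
  if (any(oob)) warning(sum(oob), " cell centroid(s) outside the mask; labeled 'outside'")
  cells$compartment <- comp
  cells
}
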