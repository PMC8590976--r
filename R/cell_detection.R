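# Nucleus detection and CD8 marker scoring. Nuclei are segmented by a
# seeded watershed on the (smoothed) hematoxylin optical-density channel,
# candidates are filtered by pathologist-style morphometric rules (nuclear
# size, roundness, optical density), and CD8 positivity is called from the
# mean AP-red OD in a peri-nuclear annulus (the red chromogen is
# membranous/cytoplasmic, so the nuclear mask alone would miss it).

#' Nucleus detection and marker scoring parameters
#'
#' Defaults are lymphocyte-scale calibration choices and can be overridden;
#' areas are in um^2, ODs in optical-density units, the ring width in um.
#'
#' @param min_nuclear_area,max_nuclear_area Inclusive nuclear area bounds.
#' @param min_roundness Minimum isoperimetric roundness `4*pi*area/perimeter^2`.
#' @param min_nuclear_od Minimum mean hematoxylin OD; also the seed
#'   threshold for the watershed.
#' @param marker_od_threshold Mean annulus AP-red OD at or above which a
#'   cell is called CD8+.
#' @param marker_ring_um Width of the peri-nuclear scoring annulus.
#' @param smooth_sigma_um Gaussian smoothing applied to the hematoxylin
#'   channel before seeding (suppresses pixel noise).
#' @return A `detection_params` list.
#' @export
detection_params <- function(min_nuclear_area = 10, max_nuclear_area = 120,
                             min_roundness = 0.4, min_nuclear_od = 0.35,
                             marker_od_threshold = 0.2, marker_ring_um = 1.5,
                             smooth_sigma_um = 1) {
  if (!(min_nuclear_area > 0 && min_nuclear_area < max_nuclear_area)) {
    stop("need 0 < min_nuclear_area < max_nuclear_area", call. = FALSE)
  }
  if (!(min_roundness > 0 && min_roundness <= 1)) stop("min_roundness must be in (0, 1]", call. = FALSE)
  if (min_nuclear_od < 0 || marker_od_threshold < 0) stop("OD thresholds must be >= 0", call. = FALSE)
  if (marker_ring_um <= 0) stop("marker_ring_um must be > 0", call. = FALSE)
  list(min_nuclear_area = min_nuclear_area, max_nuclear_area = max_nuclear_area,
       min_roundness = min_roundness, min_nuclear_od = min_nuclear_od,
       marker_od_threshold = marker_od_threshold,
       marker_ring_um = marker_ring_um, smooth_sigma_um = smooth_sigma_um)
}

empty_cells <- function() {
  data.frame(x_px = numeric(0), y_px = numeric(0), area_um2 = numeric(0),
             roundness = numeric(0), nuc_od = numeric(0),
             marker_od = numeric(0), cd8 = logical(0),
             compartment = character(0))
}

#' Detect nuclei by seeded watershed on the hematoxylin channel
#'
#' The hematoxylin OD map is Gaussian-smoothed, thresholded at
#' `min_nuclear_od`, and the resulting foreground is split into nuclei by a
#' watershed on its distance transform (separating touching nuclei). Each
#' region becomes one candidate with centroid, area, isoperimetric roundness
#' and mean nuclear OD; physical units come from the map's `mpp`.
#'
#' @param od An `od_maps` object from [deconvolve_stains()]; `mpp` must be
#'   set, otherwise densities downstream would be meaningless.
#' @param params A [detection_params()] list.
#' @return Cell table (`data.frame`, columns `x_px`, `y_px`, `area_um2`,
#'   `roundness`, `nuc_od`, `marker_od`, `cd8`, `compartment`) with the
#'   nucleus label raster attached as attribute `"labels"`.
#' @export
detect_nuclei <- function(od, params = detection_params()) {
  stopifnot(inherits(od, "od_maps"))
  if (!is.finite(od$mpp) || od$mpp <= 0) {
    stop("od maps carry no microns-per-pixel; physical morphometrics are undefined",
         call. = FALSE)
  }
  mpp <- od$mpp
  H <- od$hematoxylin
  sigma_px <- params$smooth_sigma_um / mpp
  Hs <- matrix(as.numeric(EBImage::gblur(EBImage::Image(H), sigma = sigma_px)),
               nrow(H), ncol(H))
  mask <- Hs >= params$min_nuclear_od
  if (!any(mask)) return(empty_cells())
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labmat <- matrix(as.integer(EBImage::imageData(labels)), nrow(H), ncol(H))
  n <- max(labmat)
  if (n == 0L) return(empty_cells())

  shp <- EBImage::computeFeatures.shape(labels)
  mom <- EBImage::computeFeatures.moment(labels)
  # index per-label statistics by label id (feature rows are named by label)
  by_label <- function(m, col) {
    v <- rep(NA_real_, n)
    v[as.integer(rownames(m))] <- m[, col]
    v
  }
  # label rasters use matrix (row, col) axes: m.cx is the row (y) direction
  # center, m.cy the column (x); EBImage centroids are 1-based
  y_px <- by_label(mom, "m.cx") - 1
  x_px <- by_label(mom, "m.cy") - 1
  area_px <- by_label(shp, "s.area")
  perim <- pmax(by_label(shp, "s.perimeter"), 1e-6)
  lv <- as.integer(labmat)
  keep <- lv > 0L
  od_sum <- rowsum(as.numeric(H)[keep], lv[keep])
  nuc_od <- rep(NA_real_, n)
  idx <- as.integer(rownames(od_sum))
  nuc_od[idx] <- as.numeric(od_sum) / area_px[idx]

  cells <- data.frame(
    x_px = x_px, y_px = y_px,
    area_um2 = area_px * mpp^2,
    roundness = pmin(1, 4 * pi * area_px / perim^2),
    nuc_od = nuc_od,
    marker_od = NA_real_, cd8 = NA, compartment = NA_character_
  )
  rownames(cells) <- NULL
  attr(cells, "labels") <- labmat
  attr(cells, "mpp") <- mpp
  cells
}

#' Filter nucleus candidates by morphometric rules
#'
#' Keeps exactly the candidates with
#' `min_nuclear_area <= area <= max_nuclear_area`, `roundness >=
#' min_roundness` and `mean nuclear OD >= min_nuclear_od` (all bounds
#' inclusive); input order is preserved.
#'
#' @param cands Cell table from [detect_nuclei()].
#' @param params A [detection_params()] list.
#' @return The filtered cell table.
#' @export
filter_candidates <- function(cands, params = detection_params()) {
  if (!nrow(cands)) return(cands)
  keep <- cands$area_um2 >= params$min_nuclear_area &
    cands$area_um2 <= params$max_nuclear_area &
    cands$roundness >= params$min_roundness &
    cands$nuc_od >= params$min_nuclear_od
  keep <- !is.na(keep) & keep
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  labs <- attr(cands, "labels")
  if (!is.null(labs)) {
    attr(out, "labels") <- labs
    attr(out, "keep_labels") <- which(keep)
  }
  attr(out, "mpp") <- attr(cands, "mpp")
  out
}

#' Score CD8 marker positivity from the AP-red channel
#'
#' For each cell, `marker_od` is the mean AP-red OD in an annulus of width
#' `marker_ring_um` just outside the nuclear boundary; `cd8` is `TRUE` when
#' `marker_od >= marker_od_threshold`. When the cell table carries the
#' nucleus label raster (from [detect_nuclei()]), the annulus is the
#' morphological dilation of the actual nuclear mask with ring pixels
#' attributed to their nearest nucleus; otherwise a circular annulus of
#' equivalent radius around the centroid is used. Cells whose annulus lies
#' entirely outside the image are flagged (`marker_od = NA`), not scored.
#'
#' @param cells Cell table.
#' @param od An `od_maps` object.
#' @param params A [detection_params()] list.
#' @return The cell table with `marker_od` and `cd8` filled in.
#' @export
score_marker <- function(cells, od, params = detection_params()) {
  stopifnot(inherits(od, "od_maps"))
  if (!nrow(cells)) return(cells)
  A <- od$ap_red
  mpp <- if (is.finite(od$mpp)) od$mpp else attr(cells, "mpp")
  if (is.null(mpp) || !is.finite(mpp)) stop("microns-per-pixel unknown; cannot size the scoring annulus", call. = FALSE)
  ring_px <- max(1L, ceiling(params$marker_ring_um / mpp))
  labmat <- attr(cells, "labels")
  marker <- rep(NA_real_, nrow(cells))

  if (!is.null(labmat)) {
    keep_labels <- attr(cells, "keep_labels") %||% seq_len(max(labmat))
    nucmask <- labmat > 0L
    brush <- EBImage::makeBrush(2L * ring_px + 1L, shape = "disc")
    dil <- EBImage::dilate(EBImage::Image(nucmask * 1), brush) > 0.5
    dilmask <- matrix(as.logical(dil), nrow(labmat), ncol(labmat))
    ringmask <- dilmask & !nucmask
    ringlab <- EBImage::propagate(EBImage::Image(A), EBImage::Image(labmat),
                                  mask = EBImage::Image(dilmask * 1))
    rl <- as.integer(EBImage::imageData(ringlab))
    rl[!ringmask] <- 0L                 # keep only annulus pixels
    sel <- rl > 0L
    s <- rowsum(as.numeric(A)[sel], rl[sel])
    cnt <- rowsum(rep(1, sum(sel)), rl[sel])
    mean_by_label <- rep(NA_real_, max(labmat))
    mean_by_label[as.integer(rownames(s))] <- as.numeric(s) / as.numeric(cnt)
    marker <- mean_by_label[keep_labels]
  } else {
    xc <- if ("x_px" %in% names(cells)) cells$x_px else cells$x
    yc <- if ("y_px" %in% names(cells)) cells$y_px else cells$y
    r_eq <- if ("area_um2" %in% names(cells)) {
      sqrt(cells$area_um2 / pi) / mpp
    } else if ("radius_um" %in% names(cells)) {
      cells$radius_um / mpp
    } else rep(3.5 / mpp, nrow(cells))
    h <- nrow(A); w <- ncol(A)
    for (i in seq_len(nrow(cells))) {
      r2 <- r_eq[i] + ring_px
      x0 <- floor(xc[i] - r2); x1 <- ceiling(xc[i] + r2)
      y0 <- floor(yc[i] - r2); y1 <- ceiling(yc[i] + r2)
      if (x1 < 0 || y1 < 0 || x0 > w - 1 || y0 > h - 1) next  # fully outside
      xs <- max(0, x0):min(w - 1, x1); ys <- max(0, y0):min(h - 1, y1)
      dx <- outer(rep(1, length(ys)), xs - xc[i])
      dy <- outer(ys - yc[i], rep(1, length(xs)))
      dd <- sqrt(dx^2 + dy^2)
      ann <- dd > r_eq[i] & dd <= r2
      if (any(ann)) marker[i] <- mean(A[ys + 1L, xs + 1L][ann])
    }
  }
  cells$marker_od <- marker
  cells$cd8 <- ifelse(is.na(marker), NA, marker >= params$marker_od_threshold)
  cells
}

#' Write / read a cell table as CSV
#'
#' Columns: `x_px`, `y_px`, `area_um2`, `roundness`, `nuc_od`, `marker_od`,
#' `cd8`, `compartment`; coordinates are 0-based pixel centers.
#'
#' @param cells Cell table.
#' @param path CSV file path.
#' @return Invisibly `path` (write) or the cell table (read).
#' @export
write_cells <- function(cells, path) {
  cols <- c("x_px", "y_px", "area_um2", "roundness", "nuc_od", "marker_od",
            "cd8", "compartment")
  df <- as.data.frame(cells)[, intersect(cols, names(cells)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Match detections against ground-truth positions
#'
#' Greedy nearest-neighbor matching within a radius; each truth point and
#' each detection is used at most once. Used for precision/recall
#' diagnostics of the detector against generator ground truth.
#'
#' @param truth_xy,det_xy Two-column matrices (x, y) in pixels.
#' @param radius_px Maximum match distance.
#' @return List with `n_matched`, `precision`, `recall`, `f1` and the index
#'   matrix `pairs`.
#' @export
match_detections <- function(truth_xy, det_xy, radius_px = 5) {
  truth_xy <- as.matrix(truth_xy); det_xy <- as.matrix(det_xy)
  nt <- nrow(truth_xy); nd <- nrow(det_xy)
  if (nt == 0L || nd == 0L) {
    return(list(n_matched = 0L, precision = ifelse(nd == 0, NA, 0),
                recall = ifelse(nt == 0, NA, 0), f1 = 0,
                pairs = matrix(integer(0), 0, 2)))
  }
  d2 <- outer(truth_xy[, 1], det_xy[, 1], "-")^2 +
    outer(truth_xy[, 2], det_xy[, 2], "-")^2
  d2[d2 > radius_px^2] <- Inf
  pairs <- matrix(integer(0), 0, 2)
  repeat {
    m <- which.min(d2)
    if (!length(m) || !is.finite(d2[m])) break
    i <- (m - 1L) %% nt + 1L; j <- (m - 1L) %/% nt + 1L
    pairs <- rbind(pairs, c(i, j))
    d2[i, ] <- Inf; d2[, j] <- Inf
  }
  nm <- nrow(pairs)
  precision <- nm / nd; recall <- nm / nt
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(n_matched = nm, precision = precision, recall = recall, f1 = f1,
       pairs = pairs)
}
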