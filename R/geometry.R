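# Polygon utilities shared by the slide generator and the compartment
# geometry. Rasters are plain R matrices indexed [y + 1, x + 1] with (x, y)
# 0-based pixel-center coordinates; polygons are n x 2 matrices (columns x, y)
# in the same pixel coordinate system.

#' Signed and absolute polygon area
#'
#' Shoelace area of a simple polygon given as an `n x 2` matrix of vertex
#' coordinates (columns x, y). The polygon is closed implicitly.
#'
#' @param poly Numeric matrix with two columns (x, y).
#' @return Absolute area in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting test for a set of query points against one simple polygon.
#' Points exactly on an edge may fall on either side; callers that care about
#' boundary pixels should keep query points away from edges.
#'
#' @param poly Numeric matrix with columns (x, y).
#' @param x,y Numeric vectors of query coordinates.
#' @return Logical vector, `TRUE` for points inside.
#' @export
point_in_polygon <- function(poly, x, y) {
  nx <- poly[, 1]; ny <- poly[, 2]
  n <- length(nx)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ny[i] > y) != (ny[j] > y))
    if (any(cross)) {
      xi <- nx[i] + (y[cross] - ny[i]) * (nx[j] - nx[i]) / (ny[j] - ny[i])
      inside[cross] <- xor(inside[cross], x[cross] < xi)
    }
    j <- i
  }
  inside
}

# Scanline fill of one polygon into a logical matrix. Pixel (x, y) is set
# when its center lies inside the polygon (even-odd rule, half-open vertex
# convention so shared borders between adjacent polygons partition cleanly).
rasterize_one <- function(mask, poly) {
  h <- nrow(mask); w <- ncol(mask)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1L)
  x2 <- x1[nxt]; y2 <- y1[nxt]
  keep <- y1 != y2                      # horizontal edges never cross a scanline
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (!length(x1)) return(mask)
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  rows <- max(0L, floor(min(ylo))):min(h - 1L, ceiling(max(yhi)))
  slope <- (x2 - x1) / (y2 - y1)
  for (yy in rows) {
    cross <- (y1 <= yy & yy < y2) | (y2 <= yy & yy < y1)
    if (!any(cross)) next
    xs <- sort(x1[cross] + (yy - y1[cross]) * slope[cross])
    for (k in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[k]); b <- ceiling(xs[k + 1]) - 1
      a <- max(a, 0); b <- min(b, w - 1)
      if (a <= b) mask[yy + 1L, (a:b) + 1L] <- TRUE
    }
  }
  mask
}

#' Rasterize polygons into a logical mask
#'
#' Fills the union of a list of simple polygons into a `height x width`
#' logical matrix using even-odd scanline filling on pixel centers.
#'
#' @param polys A single polygon matrix or a list of polygon matrices.
#' @param width_px,height_px Canvas size in pixels.
#' @return Logical matrix of dimension `height_px x width_px`.
#' @export
rasterize_polygons <- function(polys, width_px, height_px) {
  if (is.matrix(polys)) polys <- list(polys)
  mask <- matrix(FALSE, height_px, width_px)
  for (p in polys) mask <- rasterize_one(mask, p)
  mask
}

#' Regular polygon approximation of a circle
#'
#' @param cx,cy Center coordinates (pixels).
#' @param r Radius (pixels).
#' @param n Number of vertices.
#' @return An `n x 2` polygon matrix.
#' @export
circle_polygon <- function(cx, cy, r, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Smooth star-shaped "blob" polygon: radius modulated by a low-order random
# Fourier series. Used for tumor nests, stroma islands and artifact patches.
blob_polygon <- function(cx, cy, mean_radius, amp = 0.25, n_vertices = 48L,
                         n_harmonics = 5L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  s <- rep(0, n_vertices)
  for (k in seq_len(n_harmonics)) {
    s <- s + stats::rnorm(1) / k * cos(k * th) + stats::rnorm(1) / k * sin(k * th)
  }
  if (max(abs(s)) > 0) s <- s / max(abs(s))
  r <- mean_radius * (1 + amp * s)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Rescale a polygon about its centroid so that its shoelace area equals
# `target_area` exactly.
scale_polygon_to_area <- function(poly, target_area) {
  c0 <- colMeans(poly)
  f <- sqrt(target_area / polygon_area(poly))
  sweep(sweep(poly, 2, c0, "-") * f, 2, c0, "+")
}

# Clamp polygon vertices to the canvas.
clip_polygon_to_canvas <- function(poly, width_px, height_px) {
  poly[, 1] <- pmin(pmax(poly[, 1], 0), width_px - 1)
  poly[, 2] <- pmin(pmax(poly[, 2], 0), height_px - 1)
  poly
}
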