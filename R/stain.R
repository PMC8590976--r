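# Optical-density stain model. Chromogenic stains attenuate light
# multiplicatively, so stain amounts add linearly in OD space
# (OD = -log10 transmittance); a 3x3 basis of reference stain colors then
# separates hematoxylin (nuclear counterstain) from the Alkaline-Phosphatase
# red CD8 chromogen by linear unmixing.

#' Reference stain vectors for hematoxylin / AP-red deconvolution
#'
#' Returns the unit-norm optical-density color vectors used both by the
#' forward renderer and by [deconvolve_stains()]. The hematoxylin vector is
#' the standard published value; the AP-red vector is a fixed reference for
#' the red chromogen (strong green/blue absorption); the residual vector
#' completes an independent basis and absorbs eosinophilic background.
#'
#' @param hematoxylin,ap_red,residual Optional length-3 replacement vectors
#'   (RGB optical densities, need not be normalized).
#' @return Object of class `stain_vectors`: list with unit 3-vectors
#'   `hematoxylin_od`, `ap_red_od`, `residual_od` and the 3x3 matrix `M`
#'   (rows = stains).
#' @export
stain_vectors <- function(hematoxylin = c(0.650, 0.704, 0.286),
                          ap_red = c(0.100, 0.740, 0.665),
                          residual = c(0.268, 0.570, 0.776)) {
  norm1 <- function(v) {
    v <- as.numeric(v)
    if (length(v) != 3 || any(!is.finite(v)) || any(v < 0) || sum(v) == 0) {
      stop("stain vectors must be non-negative finite 3-vectors", call. = FALSE)
    }
    v / sqrt(sum(v^2))
  }
  M <- rbind(hematoxylin = norm1(hematoxylin),
             ap_red = norm1(ap_red),
             residual = norm1(residual))
  if (abs(det(M)) < 1e-6) {
    stop("stain basis is singular: the three stain vectors must be linearly independent",
         call. = FALSE)
  }
  structure(list(hematoxylin_od = M[1, ], ap_red_od = M[2, ],
                 residual_od = M[3, ], M = M),
            class = "stain_vectors")
}

#' @export
print.stain_vectors <- function(x, ...) {
  cat("Stain OD basis (rows = stains, cols = R,G,B):\n")
  print(round(x$M, 4))
  invisible(x)
}

#' Separate an RGB image into stain optical-density channels
#'
#' Converts the image to optical density (`OD = -log10((I + eps) / I0)` per
#' channel) and projects onto the stain basis; negative stain amounts are
#' clipped at zero.
#'
#' @param image RGB array `height x width x 3` with values in `[0, 1]` (or
#'   8-bit integers in `[0, 255]`).
#' @param vectors A [stain_vectors()] object.
#' @param mpp Microns per pixel carried through to the output.
#' @return Object of class `od_maps`: list with matrices `hematoxylin`,
#'   `ap_red`, `residual` (OD units, >= 0) and scalar `mpp`.
#' @export
deconvolve_stains <- function(image, vectors = stain_vectors(), mpp = NA_real_) {
  if (!inherits(vectors, "stain_vectors")) stop("'vectors' must be a stain_vectors object", call. = FALSE)
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("'image' must be a height x width x 3 RGB array", call. = FALSE)
  }
  if (max(image, na.rm = TRUE) > 1.5) image <- image / 255
  d <- dim(image)
  eps <- 1 / 512                         # guards log of pure black
  od <- -log10(pmin(pmax(image, 0) + eps, 1))
  od <- matrix(od, ncol = 3L)            # pixels x RGB
  conc <- od %*% solve(vectors$M)        # pixels x stains
  conc[conc < 0] <- 0
  out <- list(
    hematoxylin = matrix(conc[, 1], d[1], d[2]),
    ap_red = matrix(conc[, 2], d[1], d[2]),
    residual = matrix(conc[, 3], d[1], d[2]),
    mpp = mpp
  )
  class(out) <- "od_maps"
  out
}

# Forward model: stain OD maps -> RGB transmittance image. Inverse of
# deconvolve_stains up to 8-bit quantization; used by the renderer.
od_to_rgb <- function(hematoxylin, ap_red, residual, vectors = stain_vectors()) {
  d <- dim(hematoxylin)
  C <- cbind(as.numeric(hematoxylin), as.numeric(ap_red), as.numeric(residual))
  od <- C %*% vectors$M                  # pixels x RGB
  img <- 10^(-od) - 1 / 512              # cancels the eps guard of the inverse
  img[img < 0] <- 0; img[img > 1] <- 1
  array(img, c(d[1], d[2], 3L))
}

#' @export
print.od_maps <- function(x, ...) {
  cat(sprintf("OD maps %d x %d px (mpp = %s)\n", nrow(x$hematoxylin),
              ncol(x$hematoxylin), format(x$mpp)))
  cat(sprintf("  hematoxylin OD: mean %.3f max %.3f\n",
              mean(x$hematoxylin), max(x$hematoxylin)))
  cat(sprintf("  AP-red OD:      mean %.3f max %.3f\n",
              mean(x$ap_red), max(x$ap_red)))
  invisible(x)
}
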