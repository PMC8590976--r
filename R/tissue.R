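# Patch-based six-class tissue classification. Patches are summarized into
# color/texture features (per-channel means of the stain OD and RGB
# channels, plus OD texture SDs) and classified with a random-forest head;
# the classifier family is pluggable behind this surface, but the contract
# is the six-class map, not the architecture. Dense maps come from
# sliding-window majority voting.

# priority used to break voting ties: never miss tumor
CLASS_PRIORITY <- c("tumor", "immune_stroma", "desmoplastic_stroma",
                    "pigment", "hemorrhage_necrosis", "glass")

FEATURE_NAMES <- c("mean_h", "mean_ap", "mean_res", "sd_h", "sd_ap", "sd_res",
                   "mean_r", "mean_g", "mean_b")

# population SD (matches the block-statistics fast path in classify_tissue)
psd <- function(v) sqrt(max(0, mean(v^2) - mean(v)^2))

patch_feature_row <- function(chs) {
  c(mean(chs$H), mean(chs$A), mean(chs$R),
    psd(chs$H), psd(chs$A), psd(chs$R),
    mean(chs$r), mean(chs$g), mean(chs$b))
}

slide_channels <- function(image, vectors) {
  od <- deconvolve_stains(image, vectors)
  list(H = od$hematoxylin, A = od$ap_red, R = od$residual,
       r = image[, , 1], g = image[, , 2], b = image[, , 3])
}

#' Extract labeled patches for tissue-classifier training
#'
#' Tiles the slide with `patch_px` patches at the given stride and labels
#' each patch by the majority ground-truth class under it. Labels can come
#' from a [tissue_class_map()] (the whole canvas is tiled) or from a list of
#' labeled annotation regions `list(polygon = <matrix>, class = <name>)`
#' (only patches fully inside a region are kept; regions smaller than a
#' patch are skipped with a warning).
#'
#' @param slide A `synthetic_slide`, or an RGB array (then pass `mpp`).
#' @param labels A `tissue_class_map` or a list of labeled regions.
#' @param patch_px Patch edge length in pixels (>= 32).
#' @param stride Tiling stride in pixels.
#' @param seed Seed for the per-class subsampling.
#' @param max_per_class Keep at most this many patches per class
#'   (subsampled with `seed`).
#' @param mpp Microns per pixel when `slide` is a bare array.
#' @param vectors Stain basis used for the OD features.
#' @return A `patch_dataset`: list with `features` (data.frame: `label`,
#'   feature columns, patch origin `x0`/`y0`), `patch_px`, `stride`, `mpp`,
#'   `vectors`, `class_counts`.
#' @export
extract_patches <- function(slide, labels, patch_px = 64L, stride = patch_px,
                            seed = 1L, max_per_class = Inf, mpp = NULL,
                            vectors = stain_vectors()) {
  if (inherits(slide, "synthetic_slide")) {
    image <- slide$image; mpp <- slide$layout$mpp
  } else {
    image <- slide
    if (is.null(mpp)) stop("pass 'mpp' when 'slide' is a bare image array", call. = FALSE)
  }
  if (patch_px < 32) stop("patch_px must be >= 32", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  chs <- slide_channels(image, vectors)

  rows <- list(); labs <- character(0); xs0 <- integer(0); ys0 <- integer(0)
  add_patch <- function(x0, y0, lab) {
    sub <- lapply(chs, function(m) m[(y0 + 1):(y0 + patch_px), (x0 + 1):(x0 + patch_px)])
    rows[[length(rows) + 1L]] <<- patch_feature_row(sub)
    labs <<- c(labs, lab); xs0 <<- c(xs0, x0); ys0 <<- c(ys0, y0)
  }

  if (inherits(labels, "tissue_class_map")) {
    stopifnot(all(dim(labels$labels) == c(h, w)))
    for (y0 in seq(0L, h - patch_px, by = stride)) {
      for (x0 in seq(0L, w - patch_px, by = stride)) {
        sub <- labels$labels[(y0 + 1):(y0 + patch_px), (x0 + 1):(x0 + patch_px)]
        tab <- tabulate(sub, nbins = length(TISSUE_CLASSES))
        add_patch(x0, y0, TISSUE_CLASSES[which.max(tab)])
      }
    }
  } else if (is.list(labels)) {
    for (reg in labels) {
      stopifnot(is.matrix(reg$polygon), reg$class %in% TISSUE_CLASSES)
      m <- rasterize_polygons(reg$polygon, w, h)
      bb_x <- range(which(colSums(m) > 0)) - 1L
      bb_y <- range(which(rowSums(m) > 0)) - 1L
      found <- 0L
      if (diff(bb_x) + 1 >= patch_px && diff(bb_y) + 1 >= patch_px) {
        for (y0 in seq(bb_y[1], bb_y[2] - patch_px + 1L, by = stride)) {
          for (x0 in seq(bb_x[1], bb_x[2] - patch_px + 1L, by = stride)) {
            if (all(m[(y0 + 1):(y0 + patch_px), (x0 + 1):(x0 + patch_px)])) {
              add_patch(x0, y0, reg$class); found <- found + 1L
            }
          }
        }
      }
      if (found == 0L) warning("region of class '", reg$class,
                               "' is smaller than a patch; skipped")
    }
  } else {
    stop("'labels' must be a tissue_class_map or a list of labeled regions", call. = FALSE)
  }

  feat <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows))
  } else {
    as.data.frame(matrix(numeric(0), 0, length(FEATURE_NAMES)))
  }
  names(feat) <- FEATURE_NAMES
  feat$label <- labs
  feat$x0 <- xs0; feat$y0 <- ys0

  if (is.finite(max_per_class) && nrow(feat)) {
    set.seed(as.integer(seed))
    keep <- unlist(lapply(split(seq_len(nrow(feat)), feat$label), function(ix) {
      if (length(ix) > max_per_class) sort(sample(ix, max_per_class)) else ix
    }), use.names = FALSE)
    feat <- feat[sort(keep), , drop = FALSE]
    rownames(feat) <- NULL
  }
  structure(list(features = feat, patch_px = as.integer(patch_px),
                 stride = as.integer(stride), mpp = mpp, vectors = vectors,
                 class_counts = table(factor(feat$label, levels = TISSUE_CLASSES))),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("Patch dataset: %d patches of %d px @ %.3g um/px\n",
              nrow(x$features), x$patch_px, x$mpp))
  print(x$class_counts)
  invisible(x)
}

#' Train the tissue classifier
#'
#' Fits a random forest on the patch features; a stratified hold-out split
#' provides an accuracy estimate against the generator's labels. Training
#' is fully seeded and reproducible.
#'
#' @param train A `patch_dataset`; at least 2 classes with >= 10 patches
#'   each must be present.
#' @param config List of options: `ntree` (default 200), `holdout_fraction`
#'   (default 0.2).
#' @param seed Integer RNG seed.
#' @return A `tissue_classifier` (serializable with [save_classifier()]).
#' @export
train_tissue_classifier <- function(train, config = list(), seed = 1L) {
  stopifnot(inherits(train, "patch_dataset"))
  feat <- train$features
  present <- table(feat$label)
  if (length(present) < 2) stop("need at least 2 tissue classes to train", call. = FALSE)
  starved <- names(present)[present < 10]
  if (length(starved)) {
    stop("class(es) with fewer than 10 patches: ", paste(starved, collapse = ", "),
         call. = FALSE)
  }
  ntree <- config$ntree %||% 200L
  holdout_fraction <- config$holdout_fraction %||% 0.2
  set.seed(as.integer(seed))
  y <- factor(feat$label, levels = TISSUE_CLASSES)
  X <- as.matrix(feat[, FEATURE_NAMES])
  hold <- unlist(lapply(split(seq_len(nrow(feat)), feat$label), function(ix) {
    sample(ix, max(1L, floor(holdout_fraction * length(ix))))
  }), use.names = FALSE)
  rf <- randomForest::randomForest(X[-hold, , drop = FALSE], droplevels(y[-hold]),
                                   ntree = ntree)
  pred <- predict(rf, X[hold, , drop = FALSE])
  acc <- mean(as.character(pred) == as.character(y[hold]))
  cfg <- list(ntree = ntree, holdout_fraction = holdout_fraction,
              patch_px = train$patch_px, mpp = train$mpp)
  structure(list(rf = rf, patch_px = train$patch_px, mpp = train$mpp,
                 vectors = train$vectors, classes = TISSUE_CLASSES,
                 holdout_accuracy = acc, n_train = nrow(feat) - length(hold),
                 n_holdout = length(hold),
                 config_hash = paste0("v1-", sum(utf8ToInt(paste(deparse(cfg), collapse = ""))) %% 100000L),
                 version = "1"),
            class = "tissue_classifier")
}

#' @export
print.tissue_classifier <- function(x, ...) {
  cat(sprintf("Tissue classifier (random-forest head): patch %d px @ %.3g um/px, held-out accuracy %.1f%% (%d train / %d holdout)\n",
              x$patch_px, x$mpp, 100 * x$holdout_accuracy, x$n_train, x$n_holdout))
  invisible(x)
}

#' Serialize / restore a tissue classifier
#'
#' Single-file serialization embedding the version and config hash.
#'
#' @param classifier A `tissue_classifier`.
#' @param path File path.
#' @return Invisibly `path` (save) or the classifier (load).
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "tissue_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "tissue_classifier")) stop("not a tissue classifier file", call. = FALSE)
  obj
}

# Block statistics: sums and sums of squares of `M` over non-overlapping
# s x s blocks after replicate-padding to a multiple of s.
block_sums <- function(M, s) {
  h <- nrow(M); w <- ncol(M)
  hp <- ceiling(h / s) * s; wp <- ceiling(w / s) * s
  if (hp > h) M <- M[c(seq_len(h), rep(h, hp - h)), , drop = FALSE]
  if (wp > w) M <- M[, c(seq_len(w), rep(w, wp - w)), drop = FALSE]
  ri <- rep(seq_len(hp / s), each = s)
  ci <- rep(seq_len(wp / s), each = s)
  t(rowsum(t(rowsum(M, ri)), ci))
}

#' Classify a whole slide into the six tissue classes
#'
#' Slides a `patch_px` window at `stride = patch_px / 2`, predicts each
#' window with the classifier, and fuses the overlapping window labels per
#' pixel by majority vote; ties are broken by the fixed class priority
#' tumor > immune_stroma > desmoplastic_stroma > pigment >
#' hemorrhage_necrosis > glass. Every pixel receives exactly one label.
#'
#' @param slide A `synthetic_slide` or an RGB array (then pass `mpp`).
#' @param classifier A trained `tissue_classifier`.
#' @param patch_px Window size; defaults to the classifier's training size.
#' @param stride Window stride; must be `patch_px / 2`.
#' @param mpp Microns per pixel when `slide` is a bare array; checked
#'   against the classifier's training resolution (20% tolerance).
#' @return A [tissue_class_map()].
#' @export
classify_tissue <- function(slide, classifier, patch_px = classifier$patch_px,
                            stride = patch_px / 2L, mpp = NULL) {
  stopifnot(inherits(classifier, "tissue_classifier"))
  if (inherits(slide, "synthetic_slide")) {
    image <- slide$image; mpp <- slide$layout$mpp
  } else {
    image <- slide
    if (is.null(mpp)) stop("pass 'mpp' when 'slide' is a bare image array", call. = FALSE)
  }
  if (is.finite(classifier$mpp) &&
      abs(mpp - classifier$mpp) > 0.2 * classifier$mpp) {
    stop(sprintf("slide resolution (%.3g um/px) incompatible with classifier training resolution (%.3g um/px)",
                 mpp, classifier$mpp), call. = FALSE)
  }
  if (patch_px != classifier$patch_px) {
    stop("patch_px must match the classifier's training patch size", call. = FALSE)
  }
  s <- as.integer(stride)
  if (2L * s != patch_px) stop("stride must be patch_px / 2", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  chs <- slide_channels(image, classifier$vectors)

  nbr <- ceiling(h / s); nbc <- ceiling(w / s)
  n_px <- s^2
  S <- lapply(chs, block_sums, s = s)
  S2 <- lapply(chs[c("H", "A", "R")], function(M) block_sums(M^2, s))

  # per-patch stats: each patch = 2 x 2 adjacent s-blocks
  agg <- function(B) B[1:(nbr - 1), 1:(nbc - 1)] + B[2:nbr, 1:(nbc - 1)] +
    B[1:(nbr - 1), 2:nbc] + B[2:nbr, 2:nbc]
  pm <- lapply(S, function(B) agg(B) / (4 * n_px))
  pv <- mapply(function(B2, m) pmax(0, agg(B2) / (4 * n_px) - m^2),
               S2, pm[c("H", "A", "R")], SIMPLIFY = FALSE)
  X <- cbind(as.numeric(pm$H), as.numeric(pm$A), as.numeric(pm$R),
             sqrt(as.numeric(pv$H)), sqrt(as.numeric(pv$A)), sqrt(as.numeric(pv$R)),
             as.numeric(pm$r), as.numeric(pm$g), as.numeric(pm$b))
  colnames(X) <- FEATURE_NAMES
  pred <- predict(classifier$rf, X)
  pred_idx <- matrix(match(as.character(pred), TISSUE_CLASSES), nbr - 1, nbc - 1)

  # vote per s-block: each block is covered by up to 4 patches
  votes <- array(0L, c(nbr, nbc, length(TISSUE_CLASSES)))
  for (dy in 0:1) for (dx in 0:1) {
    rr <- seq_len(nbr - 1) + dy; cc <- seq_len(nbc - 1) + dx
    for (k in seq_along(TISSUE_CLASSES)) {
      votes[rr, cc, k] <- votes[rr, cc, k] + (pred_idx == k)
    }
  }
  # deterministic argmax with class-priority tie-break
  prio_bonus <- (length(CLASS_PRIORITY) - match(TISSUE_CLASSES, CLASS_PRIORITY)) * 1e-3
  best <- matrix(1L, nbr, nbc); bestv <- votes[, , 1] + prio_bonus[1]
  for (k in 2:length(TISSUE_CLASSES)) {
    vk <- votes[, , k] + prio_bonus[k]
    upd <- vk > bestv
    best[upd] <- k; bestv[upd] <- vk[upd]
  }
  lab <- best[rep(seq_len(nbr), each = s)[1:h], rep(seq_len(nbc), each = s)[1:w]]
  tissue_class_map(lab, mpp)
}
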