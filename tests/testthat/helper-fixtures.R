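# Shared fixtures and independent brute-force oracles. Slides used in unit
# tests are small (512 px at 0.5 um/px) to keep the suite fast; scale-up
# behavior is exercised in the acceptance tests.

small_slide <- function(phenotype = "inflamed", seed = 7, width_px = 512,
                        height_px = 512, mpp = 0.5, n_tumor_nests = 2,
                        ...) {
  generate_slide(phenotype, width_px = width_px, height_px = height_px,
                 mpp = mpp, n_tumor_nests = n_tumor_nests, seed = seed, ...)
}

od_from_matrix <- function(H, mpp, A = H * 0) {
  structure(list(hematoxylin = H, ap_red = A, residual = H * 0, mpp = mpp),
            class = "od_maps")
}

random_candidates <- function(n) {
  data.frame(
    x_px = runif(n, 0, 100), y_px = runif(n, 0, 100),
    area_um2 = runif(n, 0, 200),
    roundness = runif(n, 0.01, 1),
    nuc_od = runif(n, 0, 1.2),
    marker_od = NA_real_, cd8 = NA, compartment = NA_character_
  )
}

# brute-force predicate filter (independent of filter_candidates)
oracle_filter <- function(cands, p) {
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    keep[i] <- cands$area_um2[i] >= p$min_nuclear_area &&
      cands$area_um2[i] <= p$max_nuclear_area &&
      cands$roundness[i] >= p$min_roundness &&
      cands$nuc_od[i] >= p$min_nuclear_od
  }
  cands[keep, , drop = FALSE]
}

# brute-force per-cell raster lookup (independent of assign_cells)
oracle_assign <- function(cells, mask) {
  out <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- round(cells$y[i]) + 1; c <- round(cells$x[i]) + 1
    out[i] <- if (r < 1 || c < 1 || r > nrow(mask$labels) || c > ncol(mask$labels)) {
      "outside"
    } else {
      c("iTC", "sTC", "IM", "excluded", "outside")[mask$labels[r, c]]
    }
  }
  out
}

# brute-force pair counting (independent of cross_tabulate)
oracle_crosstab <- function(pred, truth) {
  lev <- c("desert", "excluded", "inflamed")
  m <- matrix(0L, 3, 3, dimnames = list(lev, lev))
  for (i in seq_along(pred)) {
    m[pred[i], truth[i]] <- m[pred[i], truth[i]] + 1L
  }
  m
}

# direct step-down formula evaluation (independent of holm_sidak_adjust)
oracle_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    vals <- numeric(k)
    for (j in seq_len(k)) vals[j] <- 1 - (1 - p[o[j]])^(m - j + 1)
    adj_sorted[k] <- min(1, max(vals))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Table 3 validation-cohort pattern: 10 desert concordant, 18 excluded of
# which 3 predicted inflamed, 5 inflamed concordant
validation_cohort <- function() {
  truth <- c(rep("desert", 10), rep("excluded", 18), rep("inflamed", 5))
  pred <- c(rep("desert", 10), rep("excluded", 15), rep("inflamed", 3),
            rep("inflamed", 5))
  list(truth = truth, predicted = pred)
}
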