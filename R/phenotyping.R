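# Density computation and the immune-diagnosis decision algorithm.
# The diagnosis uses only the two tumor-center densities: intratumoral CD8+
# density (iCD8) and stromal CD8+ density (sCD8). The invasive margin is
# computed and reported when available but never required -- biopsies
# without a captured margin are still diagnosable.

#' Compute compartment CD8+ densities
#'
#' `density = (# CD8+ cells in compartment) / compartment area (um^2)` for
#' iTC, sTC and IM. CD8- cells and cells in excluded/outside compartments
#' are ignored. A slide with zero iTC or sTC area cannot be diagnosed and
#' raises an error; a zero IM area (no margin captured) simply yields an
#' absent (`NA`) imCD8.
#'
#' @param cells Cell table with `cd8` and `compartment` columns (see
#'   [assign_cells()]).
#' @param mask A `compartment_mask`.
#' @return A `density_profile`: list with `icd8`, `scd8`, `imcd8`
#'   (cells/um^2), areas `area_itc`, `area_stc`, `area_im` (um^2) and counts
#'   `n_itc`, `n_stc`, `n_im`.
#' @export
compute_densities <- function(cells, mask) {
  stopifnot(inherits(mask, "compartment_mask"))
  a <- mask$areas
  if (a[["iTC"]] <= 0 || a[["sTC"]] <= 0) {
    stop("slide is unscorable: both tumor-center sub-compartments (iTC, sTC) need positive area",
         call. = FALSE)
  }
  cd8 <- !is.na(cells$cd8) & cells$cd8
  cnt <- function(comp) sum(cd8 & cells$compartment == comp)
  n_itc <- cnt("iTC"); n_stc <- cnt("sTC"); n_im <- cnt("IM")
  structure(list(
    icd8 = n_itc / a[["iTC"]],
    scd8 = n_stc / a[["sTC"]],
    imcd8 = if (a[["IM"]] > 0) n_im / a[["IM"]] else NA_real_,
    area_itc = unname(a[["iTC"]]), area_stc = unname(a[["sTC"]]),
    area_im = unname(a[["IM"]]),
    n_itc = n_itc, n_stc = n_stc, n_im = n_im
  ), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("CD8+ densities (cells/um^2): iCD8 %.3g (%d / %.3g um^2), sCD8 %.3g (%d / %.3g um^2), imCD8 %s\n",
              x$icd8, x$n_itc, x$area_itc, x$scd8, x$n_stc, x$area_stc,
              if (is.na(x$imcd8)) "absent (no margin)" else sprintf("%.3g (%d / %.3g um^2)", x$imcd8, x$n_im, x$area_im)))
  invisible(x)
}

#' Density cut-off pair for the diagnostic algorithm
#'
#' The shipped defaults are geometric midpoints between adjacent phenotype
#' class means of the discovery-cohort presets (see [phenotype_preset()]);
#' they are calibration defaults of this package, not published clinical
#' cut-offs, and should be re-derived with [derive_cutoffs()] for any new
#' cohort.
#'
#' @param c_i Intratumoral (iCD8) cut-off, cells/um^2 (> 0).
#' @param c_s Stromal (sCD8) cut-off, cells/um^2 (> 0).
#' @return A `cutoff_config` object.
#' @export
cutoff_config <- function(c_i = sqrt(2e-4 * 6e-4), c_s = sqrt(2e-4 * 2e-3)) {
  if (!is.finite(c_i) || !is.finite(c_s) || c_i <= 0 || c_s <= 0) {
    stop("cut-offs must be finite and > 0", call. = FALSE)
  }
  structure(list(c_i = c_i, c_s = c_s), class = "cutoff_config")
}

#' @export
print.cutoff_config <- function(x, ...) {
  cat(sprintf("Cut-offs (cells/um^2): iCD8 >= %.4g -> inflamed; else sCD8 >= %.4g -> excluded; else desert\n",
              x$c_i, x$c_s))
  invisible(x)
}

#' Read / write cut-offs as YAML
#' @param path YAML file path.
#' @param cutoffs A [cutoff_config()].
#' @return A `cutoff_config` (read) or invisibly `path` (write).
#' @export
read_cutoffs <- function(path) {
  y <- yaml::read_yaml(path)
  cutoff_config(y$c_i, y$c_s)
}

#' @rdname read_cutoffs
#' @export
write_cutoffs <- function(cutoffs, path) {
  yaml::write_yaml(list(c_i = cutoffs$c_i, c_s = cutoffs$c_s), path)
  invisible(path)
}

#' Translate a density profile into an immune diagnosis
#'
#' Decision tree: `icd8 >= c_i` gives `inflamed`; otherwise `scd8 >= c_s`
#' gives `excluded`; otherwise `desert`. Thresholds are inclusive, every
#' non-negative input maps to exactly one category, and the invasive margin
#' is never consulted.
#'
#' @param profile A `density_profile` (or any list with `icd8`, `scd8`).
#' @param cutoffs A [cutoff_config()].
#' @return An `immune_diagnosis`: list with `category`, `cutoffs_used`,
#'   `profile`.
#' @export
classify_phenotype <- function(profile, cutoffs = cutoff_config()) {
  stopifnot(inherits(cutoffs, "cutoff_config"))
  icd8 <- profile$icd8; scd8 <- profile$scd8
  if (!is.finite(icd8) || !is.finite(scd8) || icd8 < 0 || scd8 < 0) {
    stop("profile needs finite non-negative icd8 and scd8", call. = FALSE)
  }
  category <- if (icd8 >= cutoffs$c_i) "inflamed"
  else if (scd8 >= cutoffs$c_s) "excluded"
  else "desert"
  structure(list(category = category, cutoffs_used = cutoffs,
                 profile = profile),
            class = "immune_diagnosis")
}

#' @export
print.immune_diagnosis <- function(x, ...) {
  cat(sprintf("Immune diagnosis: %s (iCD8 %.3g vs c_i %.3g; sCD8 %.3g vs c_s %.3g)\n",
              x$category, x$profile$icd8, x$cutoffs_used$c_i,
              x$profile$scd8, x$cutoffs_used$c_s))
  invisible(x)
}

profiles_to_df <- function(profiles) {
  if (is.data.frame(profiles)) return(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(icd8 = p$icd8, scd8 = p$scd8,
               imcd8 = if (is.null(p$imcd8)) NA_real_ else p$imcd8)
  }))
}

#' Derive diagnostic cut-offs from a labeled cohort
#'
#' Exhaustive grid search over candidate cut-off pairs. Candidates for each
#' axis are the midpoints of adjacent sorted observed density values,
#' extended by one candidate below the minimum and one above the maximum so
#' the search can place a cut-off outside the observed range. The pair
#' maximizing the objective of [classify_phenotype()] against the labels
#' wins; ties are broken by the smallest `c_i`, then smallest `c_s`.
#'
#' @param profiles List of `density_profile`s or a data.frame with columns
#'   `icd8`, `scd8` (>= 5 profiles).
#' @param labels Character vector of reference diagnoses (>= 2 distinct).
#' @param objective `"balanced_accuracy"` (mean per-class recall) or
#'   `"accuracy"`.
#' @return A [cutoff_config()] with attributes `objective_value` and
#'   `objective`.
#' @export
derive_cutoffs <- function(profiles, labels,
                           objective = c("balanced_accuracy", "accuracy")) {
  objective <- match.arg(objective)
  df <- profiles_to_df(profiles)
  labels <- as.character(labels)
  stopifnot(nrow(df) == length(labels))
  if (nrow(df) < 5) stop("need at least 5 profiles to derive cut-offs", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("degenerate cohort: need at least 2 distinct diagnosis labels", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("desert", "excluded", "inflamed"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)

  candidates <- function(v) {
    u <- sort(unique(v))
    mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
    lo <- if (u[1] > 0) u[1] / 2 else min(c(mids[mids > 0], 1e-9)) / 2
    hi <- max(u) * 1.01 + 1e-12
    out <- unique(c(lo, mids, hi))
    out[out > 0]
  }
  ci_cand <- candidates(df$icd8)
  cs_cand <- candidates(df$scd8)

  score <- function(pred) {
    if (objective == "accuracy") return(mean(pred == labels))
    mean(vapply(unique(labels), function(k) mean(pred[labels == k] == k), numeric(1)))
  }
  best <- NULL; best_score <- -Inf
  for (ci in sort(ci_cand)) {
    inflamed <- df$icd8 >= ci
    for (cs in sort(cs_cand)) {
      pred <- ifelse(inflamed, "inflamed", ifelse(df$scd8 >= cs, "excluded", "desert"))
      sc <- score(pred)
      if (sc > best_score + 1e-12) { best_score <- sc; best <- c(ci, cs) }
    }
  }
  out <- cutoff_config(best[1], best[2])
  attr(out, "objective_value") <- best_score
  attr(out, "objective") <- objective
  out
}
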