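# Diagnostic-accuracy evaluation and cohort statistics: per-class confusion
# matrix (rows = predicted, columns = reference pathologist diagnosis),
# one-vs-rest sensitivity / specificity / precision, Holm-Sidak step-down
# multiple-comparison adjustment, pairwise density comparisons between
# phenotypes, and correlation / linear regression of repeated scorings.

DIAGNOSIS_LEVELS <- c("desert", "excluded", "inflamed")

#' Cross-tabulate predicted against reference diagnoses
#'
#' @param predicted,truth Equal-length vectors of diagnoses from the closed
#'   set desert / excluded / inflamed.
#' @return A `confusion_matrix`: 3x3 integer table, rows = predicted,
#'   columns = reference ("pathologist") diagnosis.
#' @export
cross_tabulate <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(predicted, truth)), DIAGNOSIS_LEVELS)
  if (length(bad)) stop("unknown diagnosis categories: ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(predicted, levels = DIAGNOSIS_LEVELS),
                  factor(truth, levels = DIAGNOSIS_LEVELS))
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(predicted = DIAGNOSIS_LEVELS,
                              truth = DIAGNOSIS_LEVELS))
  structure(list(classes = DIAGNOSIS_LEVELS, counts = m),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = pathologist diagnosis):\n")
  print(x$counts)
  invisible(x)
}

#' Render a confusion matrix as a plain-text table
#' @param cm A `confusion_matrix`.
#' @return Character vector of text lines.
#' @export
format_confusion <- function(cm) {
  c("Confusion matrix (rows = predicted, columns = pathologist diagnosis)",
    utils::capture.output(print(cm$counts)))
}

# display rounding used for percentages: integer percent except exact
# halves, which keep one decimal (e.g. 62.5)
display_pct <- function(p) {
  pct <- 100 * p
  half <- which(abs(pct * 2 - round(pct * 2)) < 1e-9 &
                  abs(pct - round(pct)) > 1e-9)
  out <- round(pct)
  out[half] <- round(pct[half] * 2) / 2
  out
}

#' One-vs-rest per-class diagnostic metrics
#'
#' For each class, TP/TN/FP/FN treating that class as positive, plus
#' sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)` and precision
#' (positive predictive value) `TP/(TP+FP)`. Ratios with zero denominator
#' are reported as `NA` (not applicable), never as 0. Display columns carry
#' the rounded percentages (integer percent except exact halves); raw
#' ratios stay unrounded.
#'
#' @param cm A `confusion_matrix` from [cross_tabulate()].
#' @return A `class_metrics` data.frame (one row per class) with columns
#'   `class`, `tp`, `tn`, `fp`, `fn`, `sensitivity`, `specificity`,
#'   `precision` and `*_pct` display columns; macro averages are attached as
#'   attribute `"macro"`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$counts
  total <- sum(m)
  rows <- lapply(seq_along(cm$classes), function(k) {
    tp <- m[k, k]
    fp <- sum(m[k, ]) - tp
    fn <- sum(m[, k]) - tp
    tn <- total - tp - fp - fn
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    data.frame(class = cm$classes[k], tp = tp, tn = tn, fp = fp, fn = fn,
               sensitivity = ratio(tp, tp + fn),
               specificity = ratio(tn, tn + fp),
               precision = ratio(tp, tp + fp))
  })
  out <- do.call(rbind, rows)
  out$sensitivity_pct <- display_pct(out$sensitivity)
  out$specificity_pct <- display_pct(out$specificity)
  out$precision_pct <- display_pct(out$precision)
  attr(out, "macro") <- c(sensitivity = mean(out$sensitivity, na.rm = TRUE),
                          specificity = mean(out$specificity, na.rm = TRUE),
                          precision = mean(out$precision, na.rm = TRUE))
  class(out) <- c("class_metrics", "data.frame")
  out
}

#' Holm-Sidak step-down p-value adjustment
#'
#' Sorts the m raw p-values ascending and sets
#' `adjusted_(k) = max_{j <= k} (1 - (1 - p_(j))^(m - j + 1))`, clipped at
#' 1, returned in the input order. With m = 1 this is the identity.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
holm_sidak_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise phenotype comparisons of compartment densities
#'
#' For each compartment (iCD8, sCD8, imCD8) and each pair of phenotype
#' groups, a Welch two-sample t-test on the densities; the whole family of
#' comparisons is Holm-Sidak adjusted. Profiles lacking a margin (`NA`
#' imCD8) are dropped from the imCD8 comparisons.
#'
#' @param profiles List of `density_profile`s or data.frame with columns
#'   `icd8`, `scd8`, `imcd8`.
#' @param labels Phenotype label per profile; every group entering a
#'   comparison needs >= 2 observations.
#' @return A `comparison_result` data.frame with columns `compartment`,
#'   `group1`, `group2`, `mean_diff`, `p_raw`, `p_adj`.
#' @export
compare_density_groups <- function(profiles, labels) {
  df <- profiles_to_df(profiles)
  labels <- as.character(labels)
  stopifnot(nrow(df) == length(labels))
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 phenotype groups", call. = FALSE)
  small <- names(which(table(labels) < 2))
  if (length(small)) {
    stop("group(s) with fewer than 2 observations: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (comp in c("icd8", "scd8", "imcd8")) {
    v <- df[[comp]]
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      a <- v[labels == groups[i] & !is.na(v)]
      b <- v[labels == groups[j] & !is.na(v)]
      if (length(a) < 2 || length(b) < 2) next
      p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        stats::t.test(a, b)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = comp, group1 = groups[i], group2 = groups[j],
        mean_diff = mean(a) - mean(b), p_raw = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- holm_sidak_adjust(out$p_raw)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Correlation and linear regression of two scorings
#'
#' Ordinary least-squares fit of `score_b` on `score_a` plus the Pearson
#' correlation; used to compare repeated pathologist scorings or digital
#' vs. pathologist diagnoses (ordinal coding desert = 1, excluded = 2,
#' inflamed = 3 via [code_diagnosis()]). Zero variance in either vector
#' makes the correlation undefined (`NA`).
#'
#' @param score_a,score_b Equal-length numeric vectors.
#' @return List with `slope`, `intercept`, `r`, `r_squared`, `n`.
#' @export
correlate_scorings <- function(score_a, score_b) {
  score_a <- as.numeric(score_a); score_b <- as.numeric(score_b)
  if (length(score_a) != length(score_b)) stop("scorings must have equal length", call. = FALSE)
  ok <- is.finite(score_a) & is.finite(score_b)
  a <- score_a[ok]; b <- score_b[ok]
  if (length(a) < 2 || stats::sd(a) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r_squared = NA_real_, n = length(a)))
  }
  fit <- stats::lm(b ~ a)
  r <- if (stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = if (is.na(r)) NA_real_ else r^2, n = length(a))
}

#' Ordinal coding of immune diagnoses
#'
#' desert = 1, excluded = 2, inflamed = 3.
#'
#' @param x Character vector of diagnoses.
#' @return Integer vector.
#' @export
code_diagnosis <- function(x) {
  out <- match(as.character(x), DIAGNOSIS_LEVELS)
  if (any(is.na(out) & !is.na(x))) stop("unknown diagnosis category", call. = FALSE)
  out
}
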