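test_that("cross-tabulation counts predicted-vs-reference pairs", {
  # perfect agreement -> diagonal
  cm <- cross_tabulate(rep(c("desert", "excluded", "inflamed"), c(3, 4, 3)),
                       rep(c("desert", "excluded", "inflamed"), c(3, 4, 3)))
  expect_equal(sum(diag(cm$counts)), 10)
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)

  # validation-cohort pattern: inflamed row picks up 3 excluded cases
  vc <- validation_cohort()
  cmv <- cross_tabulate(vc$predicted, vc$truth)
  expect_equal(unname(cmv$counts["inflamed", ]), c(0, 3, 5))
  expect_equal(unname(cmv$counts["desert", ]), c(10, 0, 0))
  expect_equal(sum(cmv$counts), 33)

  expect_error(cross_tabulate("desert", c("desert", "inflamed")), "equal length")
  expect_error(cross_tabulate("hot", "desert"), "unknown diagnosis")
})

test_that("cross-tabulation equals brute-force pair counting on shuffled input", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    pred <- sample(c("desert", "excluded", "inflamed"), n, replace = TRUE)
    truth <- sample(c("desert", "excluded", "inflamed"), n, replace = TRUE)
    expect_equal(cross_tabulate(pred, truth)$counts, oracle_crosstab(pred, truth),
                 ignore_attr = TRUE)
  }
})

test_that("per-class metrics reproduce the validation-cohort table", {
  vc <- validation_cohort()
  met <- class_metrics(cross_tabulate(vc$predicted, vc$truth))
  des <- met[met$class == "desert", ]
  exc <- met[met$class == "excluded", ]
  inf <- met[met$class == "inflamed", ]
  expect_equal(c(des$tp, des$tn, des$fp, des$fn), c(10, 23, 0, 0))
  expect_equal(c(des$sensitivity_pct, des$specificity_pct, des$precision_pct),
               c(100, 100, 100))
  expect_equal(c(exc$tp, exc$tn, exc$fp, exc$fn), c(15, 15, 0, 3))
  expect_equal(c(exc$sensitivity_pct, exc$specificity_pct, exc$precision_pct),
               c(83, 100, 100))
  expect_equal(c(inf$tp, inf$tn, inf$fp, inf$fn), c(5, 25, 3, 0))
  expect_equal(c(inf$sensitivity_pct, inf$specificity_pct, inf$precision_pct),
               c(100, 89, 62.5))
  # integer identities
  expect_equal(met$sensitivity * (met$tp + met$fn), met$tp)
  expect_equal(sum(met$tp), sum(diag(cross_tabulate(vc$predicted, vc$truth)$counts)))
  expect_true(all(met$tp + met$tn + met$fp + met$fn == 33))
})

test_that("metrics with zero denominators are not-applicable, never zero", {
  cm <- cross_tabulate(rep("desert", 5), rep("desert", 5))
  met <- class_metrics(cm)
  inf <- met[met$class == "inflamed", ]
  expect_true(is.na(inf$sensitivity))     # no true inflamed cases
  expect_true(is.na(inf$precision))       # no predicted inflamed cases
  expect_equal(inf$specificity, 1)
})

test_that("Holm-Sidak adjustment matches the direct step-down formula", {
  expect_equal(holm_sidak_adjust(0.05), 0.05)   # m = 1 is the identity
  expect_equal(holm_sidak_adjust(c(0, 0, 0)), c(0, 0, 0))
  p3 <- c(0.01, 0.04, 0.03)
  expect_equal(holm_sidak_adjust(p3), oracle_holm_sidak(p3))
  set.seed(21)
  for (rep in 1:30) {
    p <- runif(sample(2:12, 1))
    adj <- holm_sidak_adjust(p)
    expect_equal(adj, oracle_holm_sidak(p))
    expect_true(all(adj >= p - 1e-12))           # adjusted >= raw
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone along step-down order
  }
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("group density comparisons find the expected separations", {
  # identical groups -> adjusted p ~ 1
  df0 <- data.frame(icd8 = rep(c(1e-4, 1.1e-4, 0.9e-4), 2),
                    scd8 = rep(c(1e-3, 1.1e-3, 0.9e-3), 2),
                    imcd8 = NA_real_)
  r0 <- compare_density_groups(df0, rep(c("desert", "excluded"), each = 3))
  expect_true(all(r0$p_adj > 0.9))

  # cohort at preset means with small noise: sCD8 separates desert from excluded
  set.seed(31)
  n <- 30
  mk <- function(ph) {
    p <- phenotype_preset(ph)
    data.frame(icd8 = pmax(0, rnorm(n, p$icd8_density, 0.3 * p$icd8_density)),
               scd8 = pmax(0, rnorm(n, p$scd8_density, 0.3 * p$scd8_density)),
               imcd8 = pmax(0, rnorm(n, p$imcd8_density, 0.3 * p$imcd8_density)))
  }
  df <- rbind(mk("desert"), mk("excluded"), mk("inflamed"))
  lab <- rep(c("desert", "excluded", "inflamed"), each = n)
  res <- compare_density_groups(df, lab)
  sde <- res[res$compartment == "scd8" & res$group1 == "desert" &
               res$group2 == "excluded", ]
  expect_lt(sde$p_adj, 0.05)
  expect_lt(sde$mean_diff, 0)            # desert has the lower stromal density
  expect_error(compare_density_groups(df[1:31, ], lab[1:31]), "fewer than 2")
})

test_that("permuted labels rarely reach significance", {
  set.seed(41)
  df <- data.frame(icd8 = rlnorm(60, log(2e-4), 0.5),
                   scd8 = rlnorm(60, log(2e-3), 0.5),
                   imcd8 = NA_real_)
  hits <- vapply(1:40, function(i) {
    lab <- sample(rep(c("desert", "excluded", "inflamed"), each = 20))
    any(compare_density_groups(df, lab)$p_adj < 0.05)
  }, logical(1))
  expect_lt(mean(hits), 0.15)
})

test_that("scoring correlation handles exact, collinear and degenerate input", {
  r1 <- correlate_scorings(1:10, 1:10)
  expect_equal(c(r1$slope, r1$r), c(1, 1))
  r2 <- correlate_scorings(c(1, 2, 3), c(2, 4, 6))
  expect_equal(c(r2$slope, r2$intercept, r2$r), c(2, 0, 1))
  # random vectors match the closed-form OLS solution
  set.seed(51)
  a <- rnorm(40); b <- 0.7 * a + rnorm(40, sd = 0.3)
  r3 <- correlate_scorings(a, b)
  expect_equal(r3$slope, cov(a, b) / var(a))
  expect_equal(r3$intercept, mean(b) - r3$slope * mean(a))
  expect_equal(r3$r, cor(a, b))
  expect_equal(r3$r_squared, cor(a, b)^2)
  # zero variance -> undefined, not zero
  r4 <- correlate_scorings(rep(2, 5), 1:5)
  expect_true(is.na(r4$r))
  # ordinal coding of diagnoses
  expect_equal(code_diagnosis(c("desert", "inflamed", "excluded")), c(1, 3, 2))
  expect_error(code_diagnosis("lukewarm"), "unknown")
})
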