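test_that("Welch from summary matches stats::t.test on the raw samples", {
  set.seed(61)
  for (k in 1:20) {
    a <- rnorm(sample(5:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:20, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    ref <- stats::t.test(a, b, var.equal = FALSE)
    w <- welch_from_samples(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p_raw, ref$p.value, tolerance = 1e-12)
    # definitional equality with the summary route
    ws <- welch_from_summary(mean(a), sd(a), length(a),
                             mean(b), sd(b), length(b))
    expect_equal(ws, w, tolerance = 1e-12)
  }
})

test_that("Welch edge cases: equal means, degenerate variances, df bounds", {
  w <- welch_from_summary(5, 1, 11, 5, 2, 11)
  expect_equal(w$t, 0)
  expect_equal(w$p_raw, 1)
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  expect_equal(welch_from_samples(a, b)$t, 0)
  expect_error(welch_from_summary(1, 0, 5, 2, 0, 5), "zero")
  expect_error(welch_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
  set.seed(67)
  for (k in 1:10) {
    na <- sample(3:15, 1); nb <- sample(3:15, 1)
    w <- welch_from_summary(rnorm(1), runif(1, 0.1, 2), na,
                            rnorm(1), runif(1, 0.1, 2), nb)
    expect_gt(w$df, 0)
    expect_lte(w$df, na + nb - 2 + 1e-9)
  }
})

test_that("Welch p agrees with a permutation oracle for normal n=11 data", {
  set.seed(71)
  a <- rnorm(11, 0.5); b <- rnorm(11)
  w <- welch_from_samples(a, b)
  pooled <- c(a, b)
  n <- 11L; N <- 22L; B <- 1e5L
  picks <- replicate(B, sample.int(N, n))
  xa <- matrix(pooled[picks], nrow = n)
  sum_all <- sum(pooled); ss_all <- sum(pooled^2)
  sa <- colSums(xa); ssa <- colSums(xa^2)
  ma <- sa / n; mb <- (sum_all - sa) / n
  va <- (ssa - n * ma^2) / (n - 1)
  vb <- ((ss_all - ssa) - n * mb^2) / (n - 1)
  t_perm <- (ma - mb) / sqrt(va / n + vb / n)
  p_perm <- mean(abs(t_perm) >= abs(w$t))
  expect_lt(abs(p_perm - w$p_raw), 0.03)
})

test_that("Shapiro screen behaves under the null and detects skewed data", {
  set.seed(73)
  null_p <- replicate(500, normality_check(rnorm(11))$p)
  expect_gte(mean(null_p > 0.05), 0.90)
  exp_p <- replicate(300, normality_check(rexp(50))$p)
  expect_gte(mean(exp_p < 0.05), 0.80)
  expect_error(normality_check(c(1, 2)), "at least 3")
  expect_error(normality_check(rep(2, 10)), "zero variance")
})

test_that("uncapped Bonferroni multiplies without truncation", {
  expect_equal(bonferroni_uncapped(0.05, 4), 0.2)
  expect_equal(bonferroni_uncapped(0.25, 4), 1.0)
  expect_equal(bonferroni_uncapped(0.99, 4), 3.96)
  expect_error(bonferroni_uncapped(0, 4), "p_raw")
  expect_error(bonferroni_uncapped(0.5, 0), "m")
  # monotone in both arguments
  p <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(bonferroni_uncapped(p, 4)) > 0))
  expect_true(all(bonferroni_uncapped(0.3, 1:6) == 0.3 * (1:6)))
})

test_that("comparison table on two identical groups gives adjusted values of 4", {
  set.seed(79)
  vals <- rnorm(11, 5)
  et <- rbind(
    data.frame(patient_id = paste0("A", 1:11), group = "PBI_CTL",
               organ = "thyroid", ear = vals),
    data.frame(patient_id = paste0("B", 1:11), group = "PBI_MRL",
               organ = "thyroid", ear = vals))
  cmp <- build_comparison_table(et, pairs = list(c("PBI_CTL", "PBI_MRL")),
                                m = 4)
  expect_equal(cmp$comparisons$p_adjusted, 4)
  expect_false(cmp$comparisons$significant)
})

test_that("significance flags are invariant to the orientation of a pair", {
  cfg <- cohort_config(83, n_per_group = 6L, n_voxels = 600L)
  et <- cohort_ear_table(generate_cohort(cfg))
  fwd <- build_comparison_table(et, pairs = list(c("PBI_CTL", "PBI_MRL")), m = 4)
  rev <- build_comparison_table(et, pairs = list(c("PBI_MRL", "PBI_CTL")), m = 4)
  expect_equal(fwd$comparisons$significant, rev$comparisons$significant)
  expect_equal(fwd$comparisons$p_adjusted, rev$comparisons$p_adjusted)
  expect_equal(fwd$comparisons$t, -rev$comparisons$t)
  # deterministic organ ordering follows the reporting order
  expect_equal(unique(fwd$comparisons$organ),
               intersect(oar_organs(), unique(et$organ)))
})

test_that("missing groups and undersized groups are hard errors", {
  et <- data.frame(patient_id = c("A1", "A2"), group = "PBI_CTL",
                   organ = "thyroid", ear = c(1, 2))
  expect_error(build_comparison_table(et,
                                      pairs = list(c("PBI_CTL", "WBI_CTL"))),
               "WBI_CTL")
  et2 <- rbind(et, data.frame(patient_id = "B1", group = "WBI_CTL",
                              organ = "thyroid", ear = 1))
  expect_error(build_comparison_table(et2,
                                      pairs = list(c("PBI_CTL", "WBI_CTL"))),
               "fewer than 2")
})

test_that("auxiliary comparisons: PTV volumes are statistically indistinguishable", {
  set.seed(89)
  ptv_mrl <- sample_ptv_volumes("PBI_MRL")
  ptv_ctl <- sample_ptv_volumes("PBI_CTL")
  res <- auxiliary_compare(ptv_mrl, ptv_ctl, m = 1)
  expect_gt(res$p_adjusted, 0.05)
  expect_equal(res$p_adjusted, res$p_raw)  # m = 1 leaves p unchanged
  same <- auxiliary_compare(ptv_mrl, ptv_mrl)
  expect_equal(same$p_raw, 1)
  res3 <- auxiliary_compare(ptv_mrl, ptv_ctl, m = 3)
  expect_equal(res3$p_adjusted, 3 * res3$p_raw)
})
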