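test_that("cohort generation is reproducible and insensitive to nothing but the seed", {
  cfg <- cohort_config(101, n_per_group = 3L, n_voxels = 500L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c_ <- generate_cohort(cohort_config(102, n_per_group = 3L, n_voxels = 500L))
  expect_false(identical(a, c_))
  # generation does not disturb the caller's RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(generate_cohort(cfg)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("default configuration yields 11 patients per group with valid six-organ records", {
  recs <- generate_cohort(cohort_config(7))
  expect_length(recs, 33L)
  expect_equal(as.vector(table(vapply(recs, function(p) p$group, ""))),
               c(11L, 11L, 11L))
  p <- recs[[1]]
  expect_setequal(names(p$dvhs), oar_organs())
  for (d in p$dvhs) expect_silent(validate_dvh(d))
  # union invariant holds exactly for generated lungs
  expect_equal(p$dvhs$lungs_both$total_volume,
               p$dvhs$lung_ipsilateral$total_volume +
                 p$dvhs$lung_contralateral$total_volume,
               tolerance = 1e-9)
})

test_that("single-organ sampling: conservation, determinism and degenerate profiles", {
  prof <- default_profiles()
  pr <- prof[prof$organ == "thyroid" & prof$group == "WBI_CTL", ]
  d1 <- sample_patient_dvh(pr, seed = 11)
  d2 <- sample_patient_dvh(pr, seed = 11)
  expect_identical(d1, d2)
  expect_gte(d1$total_volume, 10)
  expect_equal(sum(d1$bin_volumes), d1$total_volume, tolerance = 1e-9)

  # degenerate profile: all mass in the first bin, mean at the bin center
  dead <- organ_dose_profile("thyroid", "PBI_MRL", 0, 0, 0, 1e-9, 18, 5, 0.3)
  dz <- sample_patient_dvh(dead, seed = 3, bin_width = 0.1)
  expect_lte(mean_dose(dz), 0.05)
  expect_lte(max_dose(dz), 0.1)
})

test_that("generated doses respect the prescription cap and p_high clipping", {
  prof <- organ_dose_profile("lung_ipsilateral", "WBI_CTL",
                             p_high = 0.8, high_mean = 60, high_sd = 20,
                             bath_scale = 2, organ_volume_mean = 1400,
                             organ_volume_sd = 250, patient_sd_log = 0.5)
  d <- sample_patient_dvh(prof, seed = 5, multiplier = 3)  # clips p at 0.9
  expect_lte(max_dose(d), 1.1 * 40.05 + 0.1)
  expect_error(organ_dose_profile("thyroid", "PBI_MRL", 1.2, 0, 0, 1, 18, 5, 0.3),
               "p_high")
})

test_that("configurations demand full group x organ profile coverage", {
  prof <- default_profiles()
  prof <- prof[!(prof$organ == "esophagus" & prof$group == "WBI_CTL"), ]
  err <- tryCatch(cohort_config(1, profiles = prof), error = conditionMessage)
  expect_match(err, "WBI_CTL")
  expect_match(err, "esophagus")
})

test_that("shipped profiles reproduce the reference group dosimetry", {
  # pool a few replicates to beat 11-patient noise
  ear <- NULL; dmax <- NULL
  for (s in 1:6) {
    recs <- generate_cohort(cohort_config(300 + s))
    ear <- rbind(ear, cohort_ear_table(recs))
    dmax <- rbind(dmax, do.call(rbind, lapply(recs, function(p)
      data.frame(group = p$group,
                 dmax = max_dose(p$dvhs$breast_contralateral)))))
  }
  ref <- reference_ear_summary()
  for (g in treatment_groups()) {
    for (o in oar_organs()) {
      sim <- mean(ear$ear[ear$group == g & ear$organ == o])
      tgt <- ref$mean[ref$group == g & ref$organ == o]
      expect_lt(abs(sim - tgt) / tgt, 0.10)
    }
    # contralateral-breast maximum dose within the calibration tolerance
    dref <- reference_dmax_summary()
    expect_lt(abs(mean(dmax$dmax[dmax$group == g]) -
                    dref$mean[dref$group == g]) / dref$mean[dref$group == g],
              0.20)
  }
})

test_that("calibration tracks a shifted target in the low-dose regime", {
  # doubling a low-dose organ's target mean should roughly double the
  # calibrated bath scale (RED is linear down there)
  tg <- reference_ear_summary()
  tg <- tg[tg$group == "PBI_MRL" & tg$organ == "thyroid", ]
  base <- initial_profiles()
  base <- base[base$organ == "thyroid" & base$group == "PBI_MRL", ]
  prof_all <- initial_profiles()
  cal1 <- calibrate_profiles(tg, profiles = prof_all, seed = 5,
                             n_rep = 4L, max_iter = 15L)
  tg2 <- tg; tg2$mean <- 2 * tg$mean; tg2$sd <- 2 * tg$sd
  cal2 <- calibrate_profiles(tg2, profiles = prof_all, seed = 5,
                             n_rep = 4L, max_iter = 15L)
  b1 <- cal1$bath_scale[cal1$organ == "thyroid" & cal1$group == "PBI_MRL"]
  b2 <- cal2$bath_scale[cal2$organ == "thyroid" & cal2$group == "PBI_MRL"]
  expect_equal(b2 / b1, 2, tolerance = 0.25)
  expect_error(calibrate_profiles(transform(tg, mean = -1)), "positive")
})

test_that("synthetic PTV volumes match the published means and spread", {
  set.seed(91)
  v <- replicate(200, mean(sample_ptv_volumes("PBI_MRL")))
  expect_equal(mean(v), 265.3, tolerance = 0.1)
  expect_error(sample_ptv_volumes("WBI_CTL"), "WBI_CTL")
})
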