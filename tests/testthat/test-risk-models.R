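test_that("RED kernels match their closed forms", {
  lin <- dose_response("linear")
  lexp <- dose_response("linear_exponential", alpha = 0.25)
  plat <- dose_response("plateau", delta = 0.1)

  expect_equal(red(0, lin), 0)
  expect_equal(red(0, lexp), 0)
  expect_equal(red(0, plat), 0)
  expect_equal(red(2, lexp), 2 * exp(-0.5))
  expect_equal(red(2, lexp), 1.21306, tolerance = 1e-5)
  expect_equal(red(c(1, 5, 40), lin), c(1, 5, 40))
  expect_equal(red(3, plat), (1 - exp(-0.3)) / 0.1)
  # suppression: linear-exponential never exceeds the dose
  expect_true(all(red(seq(0, 44, by = 0.5), lexp) <=
                    seq(0, 44, by = 0.5)))
  expect_error(red(-1, lin), "non-negative")
  expect_error(dose_response("linear_exponential"), "alpha")
  expect_error(dose_response("plateau", delta = 0), "delta")
})

test_that("the linear-exponential RED peaks at dose 1/alpha", {
  for (a in c(0.129, 0.033, 0.274, 0.25)) {
    m <- dose_response("linear_exponential", alpha = a)
    peak <- stats::optimize(function(D) red(D, m), c(0, 60),
                            maximum = TRUE)$maximum
    expect_equal(peak, 1 / a, tolerance = 1e-4)
  }
})

test_that("OED closed forms: uniform dose and the linear kernel", {
  uni2 <- dvh_differential("breast_contralateral", c(1.95, 2.05), 600)
  expect_equal(oed(uni2, dose_response("linear_exponential", alpha = 0.25)),
               2 * exp(-0.5), tolerance = 1e-12)
  set.seed(19)
  for (k in 1:10) {
    d <- random_dvh()
    expect_equal(oed(d, dose_response("linear")), mean_dose(d),
                 tolerance = 1e-12)
  }
})

test_that("OED is monotone non-increasing in alpha and recovers the mean dose as alpha -> 0", {
  set.seed(29)
  d <- random_dvh(n_bins = 60)
  alphas <- c(0, 1e-12, 0.01, 0.05, 0.129, 0.274, 0.5, 1)
  oeds <- vapply(alphas, function(a)
    oed(d, dose_response("linear_exponential", alpha = a)), numeric(1))
  expect_true(all(diff(oeds) <= 0))
  expect_equal(oeds[1], mean_dose(d), tolerance = 1e-12)
  expect_equal(oeds[2], mean_dose(d), tolerance = 1e-9)
})

test_that("OED of a volume-weighted DVH mixture is the volume-weighted mean of the OEDs", {
  set.seed(37)
  m <- dose_response("linear_exponential", alpha = 0.129)
  for (k in 1:10) {
    a <- random_dvh(n_bins = sample(10:60, 1), organ = "lung_ipsilateral")
    b <- random_dvh(n_bins = sample(10:60, 1), organ = "lung_ipsilateral")
    u <- combine_dvh(a, b)
    expect_equal(oed(u, m),
                 (oed(a, m) * a$total_volume + oed(b, m) * b$total_volume) /
                   u$total_volume,
                 tolerance = 1e-9)
  }
})

test_that("OED equals the voxel-sampling Monte-Carlo oracle", {
  set.seed(41)
  for (k in 1:10) {
    d <- random_dvh(n_bins = 50)
    m <- dose_response("linear_exponential", alpha = runif(1, 0.02, 0.3))
    mc <- oed_mc_oracle(d, m, n = 2e5)
    expect_lt(abs(oed(d, m) - mc$estimate), 3 * mc$se)
  }
})

test_that("EAR is mu times OED with the default coefficient table", {
  expect_equal(ear_from_oed(0, "lung_ipsilateral"), 0)
  expect_equal(ear_from_oed(1, "lungs_both"), 9.47)
  expect_equal(ear_from_oed(1, "thyroid"), 0.86)
  expect_equal(ear_from_oed(1, "esophagus"), 1.9)
  expect_equal(ear_from_oed(1, "breast_contralateral"), 2.49)
  expect_equal(ear_from_oed(2.5, "thyroid"), 2.5 * 0.86)
  err <- tryCatch(ear_from_oed(1, "stomach"), error = conditionMessage)
  expect_match(err, "stomach")
  expect_match(err, "thyroid")  # error lists the known labels
  expect_error(ear_from_oed(-1, "thyroid"), "non-negative")
})

test_that("excess cases follow the per-10,000-person-years unit definition", {
  expect_equal(excess_cases(1, 10000, 1), 1)
  expect_equal(excess_cases(1, 1000, 10), 1)
  expect_equal(excess_cases(0, 500, 30), 0)
  expect_equal(excess_cases(2.5, 2000, 5), 2.5)
  expect_error(excess_cases(-1, 10, 10), "non-negative")
})

test_that("patient risk profiles chain OED and EAR per organ", {
  p <- fixture_patient()
  pr <- patient_risk_profile(p)
  expect_equal(pr$organ, oar_organs())
  expect_equal(pr$ear, pr$oed * mu_defaults()[organ_site(pr$organ)],
               ignore_attr = TRUE, tolerance = 1e-12)

  # uniform 2 Gy thyroid: EAR = mu * 2 * exp(-2 alpha)
  q <- patient_record("U", "PBI_MRL", list(
    thyroid = dvh_differential("thyroid", c(1.95, 2.05), 18)))
  pu <- patient_risk_profile(q)
  expect_equal(pu$ear, 0.86 * 2 * exp(-0.066), tolerance = 1e-12)
  expect_equal(pu$ear, 1.6101, tolerance = 1e-4)

  # all-zero dose gives zero risk everywhere
  z <- patient_record("Z", "WBI_CTL", list(
    thyroid = dvh_differential("thyroid", c(0, 1e-9), 18),
    esophagus = dvh_differential("esophagus", c(0, 1e-9), 35)))
  expect_true(all(patient_risk_profile(z)$ear < 1e-8))

  # missing organ errors name organ and patient
  err <- tryCatch(patient_risk_profile(q, organs = "esophagus"),
                  error = conditionMessage)
  expect_match(err, "esophagus")
  expect_match(err, "U")
})

test_that("risk profiles are invariant to DVH rebinning within 0.5%", {
  p <- patient_record("S", "PBI_CTL", list(
    lung_ipsilateral = smooth_dvh(0.1)))
  p_fine <- patient_record("S", "PBI_CTL", list(
    lung_ipsilateral = smooth_dvh(0.01)))
  e1 <- patient_risk_profile(p)$ear
  e2 <- patient_risk_profile(p_fine)$ear
  expect_lt(abs(e1 - e2) / e2, 0.005)
})

test_that("dose scaling is linear only at low dose; cell killing suppresses at 40 Gy scale", {
  m <- dose_response("linear_exponential", alpha = 0.129)
  low <- dvh_differential("t", c(0, 0.1), 10)       # ~0.05 Gy
  low2 <- dvh_differential("t", c(0.05, 0.15), 10)  # doubled
  expect_equal(oed(low2, m) / oed(low, m), 2, tolerance = 0.02)
  hi <- dvh_differential("t", c(19.5, 20.5), 10)
  hi2 <- dvh_differential("t", c(39.5, 40.5), 10)
  expect_lt(oed(hi2, m) / oed(hi, m), 2)  # doubling dose must not double risk
  expect_lt(oed(hi2, m), oed(hi, m))      # beyond the peak it even decreases
})
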