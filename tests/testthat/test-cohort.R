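test_that("cohort sampling is deterministic per seed and heterogeneous", {
  c1 <- sample_cohort(10, seed = 5)
  c2 <- sample_cohort(10, seed = 5)
  expect_equal(c1$ability, c2$ability)
  expect_identical(c1$profile[[3]]$c, c2$profile[[3]]$c)

  # packaged default-style seeds give a mixed cohort
  expect_true(any(c1$ambulatory) && any(!c1$ambulatory))
  expect_true(all(c1$fac >= 0 & c1$fac <= 5))
  # non-ambulatory implies low FAC
  expect_true(all(c1$fac[!c1$ambulatory] <= 2))

  expect_error(sample_cohort(0), class = "adaptgait_error_invalid_parameter")
})

test_that("impairment scales with (1 - ability) and vanishes for able patients", {
  coh <- sample_cohort(30, seed = 8)
  # every impairment non-negative; forces non-negative
  for (p in coh$profile) {
    expect_true(all(p$c >= 0))
    expect_true(all(p$force_capacity >= 0))
  }
  # an able-bodied profile has zero impairment by construction
  expect_true(all(patient_profile(0)$c == 0))

  # initial swing carries the largest impairment weight per joint
  p <- coh$profile[[which.min(coh$ability)]]
  phases <- as.character(window_subphases())
  is_c <- mean(p$c[2, 1, phases == "IS"])
  expect_gt(is_c, mean(p$c[2, 1, phases == "MS"]))
  expect_gt(is_c, mean(p$c[2, 1, phases == "TS"]))
  expect_gt(is_c, mean(p$c[2, 1, phases == "stance"]))
})

test_that("tracking error follows the linear partial-support model", {
  p <- uniform_patient(20)
  expect_equal(simulate_tracking_error(p, "knee", "left", 0:29, k = 1),
               rep(0, 30))
  expect_equal(simulate_tracking_error(p, "knee", "left", 0, k = 0.5), 10)
  expect_equal(simulate_tracking_error(zero_error_patient(), "hip", "right",
                                       0:5, k = 0.2), rep(0, 6))
  # noisy deviations are truncated at zero and seeded
  pn <- uniform_patient(5, variability = 2)
  d1 <- simulate_tracking_error(pn, "knee", "left", 0:29, k = 0, seed = 3)
  d2 <- simulate_tracking_error(pn, "knee", "left", 0:29, k = 0, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 0))
  expect_error(simulate_tracking_error(p, "knee", "left", 0, k = 1.5),
               class = "adaptgait_error_invalid_parameter")
})

test_that("clinical test generator reproduces its closed-form couplings", {
  p <- patient_profile(5, body_weight = 50, force_capacity = c(0.5, 0.5))

  quiet <- clinical_params(beta0 = 0.9, sigma_speed = 0, run_jitter_sd = 0,
                           sigma_tug = 0, lforce_jitter_sd = 0, alpha0 = 10)
  rec <- simulate_clinical_tests(p, 1, k_knee_is = 5, params = quiet)
  expect_equal(rec$tenmwt_run1_s, 10 / 0.7, tolerance = 1e-12)
  expect_equal(rec$tenmwt_run2_s, 10 / 0.7, tolerance = 1e-12)

  rec2 <- simulate_clinical_tests(p, 2, k_knee_is = 2, params = quiet)
  expect_equal(rec2$tug_run1_s, 10 + 3.38 * 2, tolerance = 1e-12)

  # raw torque = capacity * body weight at zero jitter
  expect_equal(rec$lforce_left_hip_flex, 0.5 * 50)

  # non-ambulatory: walking fields absent, force fields present
  pna <- patient_profile(20, ambulatory = FALSE, fac = 1)
  rec3 <- simulate_clinical_tests(pna, 1, k_knee_is = 40, seed = 1)
  expect_true(is.na(rec3$tenmwt_run1_s) && is.na(rec3$tug_run1_s))
  expect_false(anyNA(rec3[paste0("lforce_left_", c("hip_flex", "knee_ext"))]))
})

test_that("patients with larger impairment plateau at higher support", {
  # averaged over seeds, plateau K is monotone in the impairment magnitude
  plateaus <- sapply(c(8, 16, 30), function(cdeg) {
    mean(sapply(1:20, function(s) {
      blk <- run_adaptive_block(uniform_patient(cdeg, variability = 0.1),
                                duration_min = 2, seed = s)
      mean(blk$final_k)
    }))
  })
  expect_true(all(diff(plateaus) > 0))
})

test_that("ambulatory patients out-force non-ambulatory ones at low noise", {
  coh <- sample_cohort(40, seed = 31,
                       params = cohort_params(force_noise_sd = 0.005))
  fmean <- (coh$force_left + coh$force_right) / 2
  expect_gt(min(fmean[coh$ambulatory]), max(fmean[!coh$ambulatory]))
  # the non-ambulatory stay below the clinical 0.4 Nm/kg threshold
  expect_lt(max(fmean[!coh$ambulatory]), 0.4)
})
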