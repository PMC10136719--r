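test_that("error metric clips at the deadband and scales linearly", {
  expect_equal(error_metric(rep(2, 10), deadband = 4, error_scale = 10), 0)
  expect_equal(error_metric(rep(6, 10), deadband = 4, error_scale = 10), 0.2)
  # boundary inclusive: mean |dev| exactly at the deadband gives zero
  expect_equal(error_metric(c(0, 8), deadband = 4, error_scale = 10), 0)
  expect_error(error_metric(numeric(0)), class = "adaptgait_error_insufficient_data")
  expect_error(error_metric(1:3, error_scale = 0), class = "adaptgait_error_invalid_parameter")

  # monotone non-decreasing in deviation magnitude
  f <- sapply(seq(0, 20, by = 0.5), function(d) error_metric(rep(d, 5), 4, 10))
  expect_true(all(diff(f) >= 0))
})

test_that("impedance update follows the forgetting-factor law with clamping", {
  cfg <- controller_config()
  st <- impedance_state(cfg)
  nw <- 30L

  # zero error: pure decay by gamma
  st$k[, "left", ] <- 0.5
  st1 <- update_impedance(st, cycle_error(matrix(0, 2, nw)), cfg, "left")
  expect_equal(unname(st1$k["hip", "left", 1]), 0.475)
  expect_equal(st1$cycle_index, 1L)
  # inactive leg untouched
  expect_equal(unname(st1$k["hip", "right", 1]), 1)

  # affine rise from the floor: 0.95*0.04 + 0.5*0.2 = 0.138
  st$k[, "left", ] <- 0.04
  e <- matrix(6, 2, nw) # f = 0.2
  st2 <- update_impedance(st, cycle_error(e), cfg, "left")
  expect_equal(unname(st2$k["knee", "left", 5]), 0.138)

  # ceiling clamp: 0.95*0.98 + 0.1 = 1.031 -> 1
  st$k[, "left", ] <- 0.98
  st3 <- update_impedance(st, cycle_error(e), cfg, "left")
  expect_equal(unname(st3$k["hip", "left", 1]), 1)
})

test_that("configuration invariants are enforced", {
  expect_error(controller_config(gamma_k = 1), class = "adaptgait_error_invalid_parameter")
  expect_error(controller_config(gain_k = -1), class = "adaptgait_error_invalid_parameter")
  expect_error(controller_config(k_min = 0), class = "adaptgait_error_invalid_parameter")
  expect_error(controller_config(k_min = 0.5, k_init = 0.4),
               class = "adaptgait_error_invalid_parameter")
})

test_that("zero-error closed form holds exactly over a whole block", {
  blk <- run_adaptive_block(zero_error_patient(), duration_min = 2.5)
  kc <- block_cycles(blk)
  for (w in c(0L, 10L, 29L)) {
    for (j in c("hip", "knee")) {
      kv <- kc$k[kc$joint == j & kc$window == w]
      s <- seq_along(kv)
      expect_equal(kv, pmax(0.04, 0.95^(s - 1)), tolerance = 1e-12)
    }
  }
  # the floor is first reached by the update after cycle 63:
  # 0.95^63 <= 0.04 < 0.95^62, so cycle 64 is the first run *at* the floor
  kv <- kc$k[kc$joint == "knee" & kc$window == 0]
  expect_equal(min(which(kv <= 0.04 + 1e-15)), 64L)
  expect_gt(kv[63], 0.04)
})

test_that("deterministic impaired patient converges to the analytic fixed point", {
  blk <- run_adaptive_block(uniform_patient(20), duration_min = 5)
  expect_equal(unname(blk$final_k[1, 1]), 8 / 10.5, tolerance = 1e-6)
  # grid of impairment magnitudes vs K* = g(c-d)/(scale(1-gamma)+gc);
  # the linearized loop is a contraction while |gamma - g*c/scale| < 1
  for (cdeg in c(5, 8, 12, 20, 30)) {
    blk <- run_adaptive_block(uniform_patient(cdeg), duration_min = 5)
    kstar <- 0.5 * (cdeg - 4) / (10 * 0.05 + 0.5 * cdeg)
    expect_equal(unname(blk$final_k[2, 15]), kstar, tolerance = 1e-3,
                 label = sprintf("plateau at c = %g", cdeg))
    expect_equal(fixed_point_stiffness(cdeg), kstar, tolerance = 1e-12)
  }
  # beyond that the loop limit-cycles tightly around the fixed point
  blk45 <- run_adaptive_block(uniform_patient(45), duration_min = 5)
  expect_equal(unname(blk45$final_k[2, 15]), fixed_point_stiffness(45),
               tolerance = 0.025)
  # below-deadband impairment decays to the floor
  expect_equal(fixed_point_stiffness(3), 0.04)
  blk <- run_adaptive_block(uniform_patient(3), duration_min = 5)
  expect_equal(unname(blk$final_k[1, 1]), 0.04)
})

test_that("impedance stays within bounds under random error sequences", {
  cfg <- controller_config()
  set.seed(11)
  st <- impedance_state(cfg)
  for (s in 1:50) {
    e <- matrix(runif(60, 0, 40), 2, 30)
    ed <- matrix(runif(60, 0, 200), 2, 30)
    st <- update_impedance(st, cycle_error(e, ed, cfg), cfg,
                           active_leg = sample(c("left", "right"), 1))
    expect_true(all(st$k >= cfg$k_min - 1e-15 & st$k <= cfg$k_max + 1e-15))
    expect_true(all(st$b >= cfg$b_min - 1e-15 & st$b <= cfg$b_max + 1e-15))
  }
})

test_that("larger errors never produce smaller stiffness", {
  cfg <- controller_config()
  set.seed(21)
  for (rep in 1:10) {
    k0 <- matrix(runif(60, 0.04, 1), 2, 30)
    e1 <- matrix(runif(60, 0, 25), 2, 30)
    e2 <- e1 + matrix(runif(60, 0, 10), 2, 30)
    st1 <- impedance_state(cfg); st1$k[, "left", ] <- k0
    st2 <- impedance_state(cfg); st2$k[, "left", ] <- k0
    st1 <- update_impedance(st1, cycle_error(e1, config = cfg), cfg, "left")
    st2 <- update_impedance(st2, cycle_error(e2, config = cfg), cfg, "left")
    expect_true(all(st2$k[, "left", ] >= st1$k[, "left", ] - 1e-15))
  }
})

test_that("the inactive leg is logged at constant full support", {
  blk <- run_adaptive_block(uniform_patient(15), duration_min = 0.5,
                            active_leg = "left")
  log <- session_log(blk, sample_ms = 50)
  right <- log[log$leg == "right", ]
  expect_true(all(right$k_hip == 1 & right$k_knee == 1))
  expect_true(all(right$b_hip == 1 & right$b_knee == 1))
  expect_true(all(log$active_leg == "left"))
  # and the mirrored protocol
  blk2 <- run_adaptive_block(uniform_patient(15), duration_min = 0.5,
                             active_leg = "right")
  log2 <- session_log(blk2, sample_ms = 50)
  expect_true(all(log2$k_hip[log2$leg == "left"] == 1))
})

test_that("conventional blocks hold the guidance force for both legs", {
  p <- uniform_patient(10, variability = 0)
  blk <- run_conventional_block(p, guidance_force = 0.6, duration_min = 5)
  log <- session_log(blk, sample_ms = 100)
  expect_true(all(log$k_hip == 0.6 & log$k_knee == 0.6))
  expect_equal(mean(c(log$k_hip, log$k_knee)), 0.6)

  # full support: actual trajectory identical to the reference
  blk2 <- run_conventional_block(p, guidance_force = 1, duration_min = 1)
  log2 <- session_log(blk2, sample_ms = 100)
  expect_equal(log2$hip_act_deg, log2$hip_ref_deg)
  expect_equal(log2$knee_act_deg, log2$knee_ref_deg)

  expect_error(run_conventional_block(p, guidance_force = 0),
               class = "adaptgait_error_invalid_parameter")
  expect_error(run_conventional_block(p, guidance_force = 1.2),
               class = "adaptgait_error_invalid_parameter")
})

test_that("adaptive blocks are reproducible given a seed", {
  p <- uniform_patient(15, variability = 0.1)
  b1 <- run_adaptive_block(p, duration_min = 1, seed = 99)
  b2 <- run_adaptive_block(p, duration_min = 1, seed = 99)
  expect_identical(b1$k, b2$k)
  expect_identical(b1$b, b2$b)
})
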