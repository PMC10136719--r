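test_that("warm-up exclusion removes exactly the first-minute cycles", {
  series <- tibble::tibble(cycle = 1:200, value = runif(200))
  attr(series, "cadence") <- 40
  out <- discard_warmup(series, cadence = 40, exclusion_min = 1)
  expect_equal(nrow(out), 160)
  expect_equal(min(out$cycle), 41)
  # identity at zero exclusion
  out0 <- discard_warmup(series, cadence = 40, exclusion_min = 0)
  expect_equal(nrow(out0), 200)
  # a 45-second series cannot survive a 1-minute exclusion
  short <- tibble::tibble(cycle = 1:30, value = runif(30))
  expect_error(discard_warmup(short, cadence = 40, exclusion_min = 1),
               class = "adaptgait_error_insufficient_data")
})

test_that("per-cycle subphase means partition the impedance channels", {
  blk <- run_conventional_block(uniform_patient(10), guidance_force = 0.3,
                                duration_min = 0.5)
  log <- session_log(blk, sample_ms = 25)
  series <- per_cycle_subphase_means(log)
  expect_true(all(series$value == 0.3))
  expect_setequal(as.character(unique(series$subphase)), c("IS", "MS", "TS"))

  # a log with distinct IS-window values separates cleanly
  log2 <- log[log$leg == "left", ]
  phases <- window_subphases(window_grid(30))
  is_rows <- phases[log2$window + 1] == "IS"
  log2$k_knee[is_rows] <- 0.2
  log2$k_knee[!is_rows] <- 0.6
  s2 <- per_cycle_subphase_means(log2)
  kk <- s2[s2$joint == "knee" & s2$quantity == "K", ]
  expect_true(all(kk$value[kk$subphase == "IS"] == 0.2))
  expect_true(all(kk$value[kk$subphase != "IS"] == 0.6))
})

test_that("subphase means equal a naive row-grouping recomputation", {
  p <- uniform_patient(18, variability = 0.15)
  blk <- run_adaptive_block(p, duration_min = 0.25, seed = 13)
  log <- session_log(blk, sample_ms = 12)
  log <- log[log$leg == "left", ]

  series <- per_cycle_subphase_means(log)
  oracle <- naive_subphase_means(as.data.frame(log))
  oracle$quantity <- ifelse(substr(oracle$channel, 1, 1) == "k", "K", "B")
  oracle$joint <- substr(oracle$channel, 3, 6)

  for (i in seq_len(nrow(oracle))) {
    got <- series$value[series$joint == oracle$joint[i] &
                          series$quantity == oracle$quantity[i] &
                          series$subphase == oracle$subphase[i] &
                          series$cycle == oracle$cycle[i]]
    expect_equal(got, oracle$value[i], tolerance = 1e-12)
  }
})

test_that("decay fitting recovers generative parameters and flags plateaus", {
  s <- 0:199
  fit <- fit_decay(0.5 * exp(-0.05 * s) + 0.1, cycles = s)
  expect_equal(fit$plateau, 0.1, tolerance = 1e-4)
  expect_equal(fit$rate, 0.05, tolerance = 1e-3)
  expect_true(fit$plateau_detected)

  # constant series: plateau equals the constant
  fitc <- fit_decay(rep(0.3, 50))
  expect_equal(fitc$plateau, 0.3, tolerance = 1e-9)
  expect_lt(fitc$amplitude, 1e-6)

  # strictly linear decrease over a 5-minute block: no plateau
  lin <- seq(1, 0.2, length.out = 200)
  fitl <- fit_decay(lin, cycles = 0:199)
  expect_false(fitl$plateau_detected)

  expect_error(fit_decay(c(1, NA, 3, rep(1, 10))), class = "adaptgait_error_data")
  expect_error(fit_decay(1:5), class = "adaptgait_error_insufficient_data")
})

test_that("decay fit agrees with an independent nonlinear least-squares fit", {
  set.seed(17)
  s <- 0:159
  y <- 0.7 * exp(-0.08 * s) + 0.15 + rnorm(160, 0, 0.01)
  fit <- fit_decay(y, cycles = s)
  ref <- minpack.lm::nlsLM(y ~ A * exp(-l * s) + C,
                           start = list(A = 0.5, l = 0.05, C = 0.1),
                           lower = c(0, 0, -Inf), upper = c(Inf, 2, Inf))
  cf <- coef(ref)
  expect_equal(fit$plateau, unname(cf["C"]), tolerance = 1e-4)
  expect_equal(fit$rate, unname(cf["l"]), tolerance = 1e-3)
  expect_equal(fit$amplitude, unname(cf["A"]), tolerance = 1e-3)
})

test_that("session features reach the floor for an able-bodied patient", {
  blkL <- run_adaptive_block(zero_error_patient(), duration_min = 5, active_leg = "left")
  blkR <- run_adaptive_block(zero_error_patient(), duration_min = 5, active_leg = "right")
  log <- session_log(blkL, blkR, sample_ms = 20)
  feats <- extract_session_features(log)
  expect_equal(nrow(feats), 24)
  expect_true(all(abs(feats$value - 0.04) < 1e-3))
})

test_that("features of a constant-guidance log equal the guidance", {
  blk <- run_conventional_block(uniform_patient(8), guidance_force = 0.55,
                                duration_min = 5)
  log <- session_log(blk, sample_ms = 40)
  feats <- extract_session_features(log[log$leg == "left", ])
  expect_true(all(abs(feats$value - 0.55) < 1e-9))
})

test_that("impaired-patient features match the analytic fixed point", {
  p <- uniform_patient(20)
  blkL <- run_adaptive_block(p, duration_min = 5, active_leg = "left")
  blkR <- run_adaptive_block(p, duration_min = 5, active_leg = "right")
  log <- session_log(blkL, blkR, sample_ms = 20)
  feats <- extract_session_features(log)
  kstar <- 8 / 10.5
  kf <- feats[feats$quantity == "K", ]
  expect_true(all(abs(kf$value - kstar) < 0.02))
})

test_that("forced fallback reproduces the last-4-minute mean", {
  p <- uniform_patient(12, variability = 0.05)
  blk <- run_adaptive_block(p, duration_min = 5, active_leg = "left", seed = 2)
  # impossible rmse cap forces the fallback branch everywhere
  cfg <- feature_config(plateau_rmse = -1)
  feats <- extract_session_features(blk_session(blk), cfg)
  expect_true(all(feats$method == "last-4-min-mean"))

  phases <- window_subphases(window_grid(30))
  wins <- which(phases == "IS")
  last <- which((seq_len(blk$n_cycles) - 1) / blk$cadence >= 1)
  manual <- mean(blk$k[2, wins, last])
  got <- feats$value[feats$leg == "left" & feats$quantity == "K" &
                       feats$joint == "knee" & feats$subphase == "IS"]
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("features are invariant to the log sampling rate", {
  p <- uniform_patient(16)
  blk <- run_adaptive_block(p, duration_min = 5, active_leg = "left")
  f4 <- extract_session_features(session_log(blk, sample_ms = 4))
  f8 <- extract_session_features(session_log(blk, sample_ms = 8))
  merged <- merge(as.data.frame(f4), as.data.frame(f8),
                  by = c("leg", "quantity", "joint", "subphase"))
  expect_true(all(abs(merged$value.x - merged$value.y) < 1e-3))
  # and the array route agrees with the sampled-log route
  fb <- extract_session_features(blk_session(blk))
  merged2 <- merge(as.data.frame(f4), as.data.frame(fb),
                   by = c("leg", "quantity", "joint", "subphase"))
  expect_true(all(abs(merged2$value.x - merged2$value.y) < 1e-3))
})

test_that("leg aggregation averages elementwise and flags missing legs", {
  feats <- tibble::tibble(
    leg = rep(c("left", "right"), each = 2),
    quantity = rep(c("K", "B"), 2),
    joint = "knee", subphase = "IS",
    value = c(0.2, 0.3, 0.4, 0.5), method = "plateau-fit"
  )
  agg <- aggregate_over_legs(feats)
  expect_equal(agg$value[agg$quantity == "K"], 0.3)
  expect_equal(agg$value[agg$quantity == "B"], 0.4)

  one <- feats[feats$leg == "left", ]
  expect_warning(agg1 <- aggregate_over_legs(one), "left leg")
  m1 <- merge(as.data.frame(agg1), as.data.frame(one),
              by = c("quantity", "joint", "subphase"))
  expect_equal(m1$value.x, m1$value.y)

  # random features: equals a brute-force mean
  set.seed(4)
  rnd <- tibble::tibble(
    leg = rep(c("left", "right"), each = 12),
    quantity = rep(rep(c("K", "B"), each = 6), 2),
    joint = rep(rep(c("knee", "hip"), each = 3), 4),
    subphase = rep(c("IS", "MS", "TS"), 8),
    value = runif(24), method = "plateau-fit"
  )
  agg2 <- aggregate_over_legs(rnd)
  for (i in seq_len(nrow(agg2))) {
    sel <- rnd$quantity == agg2$quantity[i] & rnd$joint == agg2$joint[i] &
      rnd$subphase == agg2$subphase[i]
    expect_equal(agg2$value[i], mean(rnd$value[sel]))
  }
})
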