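test_that("reference curves honour ROM, periodicity and determinism", {
  ref <- gait_reference(cadence = 40, rom_hip = 40, rom_knee = 60,
                        offset_hip = 0, offset_knee = 0)
  frac <- seq(0, 1, length.out = 100001)[-100001]

  hip <- ref$hip_angle(frac)
  knee <- ref$knee_angle(frac)
  expect_lt(abs((max(hip) - min(hip)) - 40), 1e-6)
  expect_lt(abs((max(knee) - min(knee)) - 60), 1e-6)

  # periodic: value just before 1 equals value at 0
  expect_lt(abs(ref$hip_angle(0) - ref$hip_angle(1 - 1e-12)), 1e-6)
  expect_lt(abs(ref$knee_angle(0) - ref$knee_angle(1 - 1e-12)), 1e-6)

  # deterministic across construction
  ref2 <- gait_reference(cadence = 40, rom_hip = 40, rom_knee = 60,
                         offset_hip = 0, offset_knee = 0)
  p <- seq(0, 1, length.out = 1000)
  expect_identical(ref$hip_angle(p), ref2$hip_angle(p))
  expect_identical(ref$knee_angle(p), ref2$knee_angle(p))
})

test_that("reference curves are smooth with plausible peak placement", {
  ref <- gait_reference()
  frac <- seq(0, 1, length.out = 20001)[-20001]
  knee <- ref$knee_angle(frac)
  hip <- ref$hip_angle(frac)
  # knee flexion peaks during swing, hip flexion near terminal swing
  expect_gt(frac[which.max(knee)], 0.625)
  expect_lt(frac[which.max(knee)], 0.9)
  expect_gt(frac[which.max(hip)], 0.8)
  # numerically C1: second differences of the sampled curve stay small
  d2 <- diff(diff(knee))
  expect_lt(max(abs(d2)), 1e-4)
})

test_that("invalid reference parameters error", {
  expect_error(gait_reference(cadence = 0), class = "adaptgait_error_invalid_parameter")
  expect_error(gait_reference(rom_hip = -5), class = "adaptgait_error_invalid_parameter")
})

test_that("reference_curve exports the sampling table", {
  tb <- reference_curve(gait_reference(), n = 16)
  expect_named(tb, c("fraction", "hip_deg", "knee_deg"))
  expect_equal(nrow(tb), 16)
  expect_equal(tb$fraction[1], 0)
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tb, tmp)
  expect_equal(as.data.frame(readr::read_csv(tmp, show_col_types = FALSE)),
               as.data.frame(tb))
})

test_that("subphase map conserves the full cycle and segments correctly", {
  map <- subphase_map()
  expect_identical(
    map$stance_fraction + map$is_fraction + map$ms_fraction + map$ts_fraction,
    1
  )
  expect_equal(map$stance_fraction, 0.625)

  expect_equal(as.character(segment_subphase(0.50, map)), "stance")
  expect_equal(as.character(segment_subphase(0.70, map)), "IS")
  expect_equal(as.character(segment_subphase(0.99, map)), "TS")
  expect_equal(as.character(segment_subphase(0.0, map)), "stance")
  # boundary points belong to the later phase
  expect_equal(as.character(segment_subphase(0.625, map)), "IS")
  expect_equal(as.character(segment_subphase(0.730, map)), "MS")
  expect_equal(as.character(segment_subphase(0.870, map)), "TS")

  expect_error(segment_subphase(1.0, map), class = "adaptgait_error_domain")
  expect_error(segment_subphase(-0.1, map), class = "adaptgait_error_domain")

  # piecewise constant with exactly 4 pieces over a fine sweep
  lab <- as.character(segment_subphase(seq(0, 0.9999, by = 1e-4), map))
  expect_equal(sum(lab[-1] != lab[-length(lab)]) + 1L, 4L)
})

test_that("window indexing floors fractions onto the grid", {
  grid <- window_grid(30)
  expect_equal(window_of(0.0, grid), 0L)
  expect_equal(window_of(0.5, grid), 15L)
  expect_equal(window_of(0.999, grid), 29L)
  expect_error(window_of(1, grid), class = "adaptgait_error_domain")

  # every window index used exactly once per uniform sweep
  idx <- window_of(seq(0, 1 - 1e-9, length.out = 3000), grid)
  expect_setequal(unique(idx), 0:29)
})

test_that("window-to-subphase assignment is total and majority-based", {
  for (nw in c(7, 13, 30, 50)) {
    lab <- window_subphases(window_grid(nw))
    expect_length(lab, nw)
    expect_false(anyNA(lab))
  }
  # with 30 windows the straddling windows 18, 21 and 26 resolve by majority
  lab30 <- as.character(window_subphases(window_grid(30)))
  expect_equal(lab30[19], "stance") # window 18: [0.600, 0.633), mostly stance
  expect_equal(lab30[22], "IS")     # window 21: [0.700, 0.733), mostly IS
  expect_equal(lab30[27], "TS")     # window 26: [0.867, 0.900), mostly TS
  expect_equal(sum(lab30 == "stance"), 19L)
})

test_that("subphase fractions always sum to one", {
  for (seed in 1:10) {
    set.seed(seed)
    f <- runif(3, 0.02, 0.2)
    map <- subphase_map(f[1], f[2], f[3])
    expect_equal(map$stance_fraction + sum(f), 1)
  }
})
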