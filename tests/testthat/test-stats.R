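test_that("paired comparison reports the t-test and flags degenerate variance", {
  df <- tibble::tibble(a = c(0.25, 0.31, 0.22, 0.4), c = c(0.6, 0.72, 0.55, 0.8))
  res <- compare_support_paired(df, a, c)
  ref <- t.test(df$a, df$c, paired = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$estimate, mean(df$a - df$c))
  expect_false(res$degenerate)

  dfd <- tibble::tibble(a = c(0.2, 0.3, 0.1), c = c(0.6, 0.7, 0.5))
  expect_warning(resd <- compare_support_paired(dfd, a, c), "degenerate")
  expect_true(resd$degenerate)
  expect_true(is.na(resd$p_value))
  expect_equal(resd$estimate, -0.4)

  expect_error(compare_support_paired(dfd[1:2, ], a, c),
               class = "adaptgait_error_insufficient_data")
})

test_that("paired-test rejection rate is near alpha under the null", {
  set.seed(101)
  n_rep <- 500
  rejections <- replicate(n_rep, {
    conv <- runif(10, 0.3, 0.8)
    ags <- conv + rnorm(10, 0, 0.05)
    df <- tibble::tibble(a = ags, c = conv)
    compare_support_paired(df, a, c)$p_value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("forward selection finds an exactly collinear response first", {
  set.seed(42)
  X <- as.data.frame(matrix(rnorm(20 * 12), 20,
                            dimnames = list(NULL, paste0("x", 1:12))))
  X$y <- 2 * X$x1
  # lm warns about essentially perfect fits; the exactness is the point here
  sel <- suppressWarnings(forward_select(X, y, predictors = paste0("x", 1:12)))
  expect_equal(sel$steps$variable[1], "x1")
  expect_equal(unname(coef(sel$model)["x1"]), 2, tolerance = 1e-8)
  expect_gt(sel$r_squared, 0.999)
})

test_that("forward selection on pure noise is usually empty, sometimes fooled", {
  set.seed(77)
  n_rep <- 100
  any_false <- replicate(n_rep, {
    X <- as.data.frame(matrix(rnorm(20 * 12), 20,
                              dimnames = list(NULL, paste0("x", 1:12))))
    X$y <- rnorm(20)
    sel <- forward_select(X, y, predictors = paste0("x", 1:12))
    length(sel$selected) > 0
  })
  # twelve uncorrected entry tests: P(any entry) ~ 1 - 0.95^12 = 0.46
  expect_lt(abs(mean(any_false) - (1 - 0.95^12)), 0.10)
})

test_that("collinear candidates are skipped with a warning", {
  df <- tibble::tibble(y = rnorm(10), x1 = rnorm(10))
  df$x2 <- df$x1 # duplicate
  df$y <- 3 * df$x1 + rnorm(10, 0, 0.01)
  expect_warning(sel <- forward_select(df, y, predictors = c("x1", "x2")),
                 "collinear")
  expect_equal(sel$selected, "x1")
})

test_that("elastic-net frequency flags a strong signal and is seed-stable", {
  set.seed(9)
  X <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, paste0("x", 1:6)))
  df <- as.data.frame(X)
  df$y <- 2 * df$x1 + rnorm(30, 0, 0.3)
  fr <- elastic_net_selection_frequency(df, y, predictors = paste0("x", 1:6),
                                        runs = 20, seed = 4)
  expect_equal(fr$frequency[fr$variable == "x1"], 1)

  # pure noise: nothing is selected reliably
  df$y <- rnorm(30)
  frn <- elastic_net_selection_frequency(df, y, predictors = paste0("x", 1:6),
                                         runs = 20, seed = 4)
  expect_lt(max(frn$frequency), 0.5)

  # determinism given the fold seed
  f1 <- elastic_net_selection_frequency(df, y, predictors = paste0("x", 1:6),
                                        runs = 1, seed = 11)
  f2 <- elastic_net_selection_frequency(df, y, predictors = paste0("x", 1:6),
                                        runs = 1, seed = 11)
  expect_identical(f1$frequency, f2$frequency)

  expect_error(
    elastic_net_selection_frequency(df[1:2, ], y, predictors = paste0("x", 1:6)),
    class = "adaptgait_error_invalid_parameter"
  )
})

test_that("first-to-last change matches simple subtraction", {
  expect_equal(percent_change_first_last(c(20.0, 18, 16.6)), -3.4)
  expect_equal(percent_change_first_last(c(10, 12, 18.7)), 8.7)
  expect_equal(percent_change_first_last(c(5, 5)), 0)
  # ordering by session index
  expect_equal(percent_change_first_last(c(16.6, 20.0), sessions = c(3, 1)), -3.4)
  expect_error(percent_change_first_last(5),
               class = "adaptgait_error_insufficient_data")
})

test_that("rank reliability reproduces textbook Spearman values", {
  expect_equal(spearman_relative_reliability(c(1, 3, 7, 9), c(1, 3, 7, 9)), 1)
  expect_equal(spearman_relative_reliability(1:5, 5:1), -1)
  expect_equal(spearman_relative_reliability(1:4, c(1, 2, 4, 3)), 0.8)
  expect_warning(r <- spearman_relative_reliability(rep(2, 4), 1:4), "constant")
  expect_true(is.na(r))
})

test_that("Bland-Altman limits match hand-computed bias and SD", {
  a <- c(10, 12, 14); b <- c(11, 11, 15)
  res <- bland_altman_loa(a, b)
  d <- a - b
  expect_equal(res$bias, mean(d))
  expect_equal(res$sd_diff, sd(d))
  expect_equal(res$half_width, 1.96 * sd(d))
  expect_equal(res$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(res$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(res$loa_pct_of_mean, 100 * 1.96 * sd(d) / mean((a + b) / 2))

  # identical sessions: zero bias and zero-width limits
  res0 <- bland_altman_loa(a, a)
  expect_equal(res0$bias, 0)
  expect_equal(res0$loa_low, 0)
  expect_equal(res0$loa_high, 0)

  # constant offset: bias 1, zero SD
  res1 <- bland_altman_loa(a, a - 1)
  expect_equal(res1$bias, 1)
  expect_equal(res1$sd_diff, 0)
  expect_equal(res1$loa_low, 1)
  expect_equal(res1$loa_high, 1)

  expect_warning(bland_altman_loa(c(1, -1), c(-1, 1)), "zero")
})

test_that("the reliability pair is the closest pair in the second half", {
  df <- tibble::tibble(
    patient_id = rep(1:2, each = 5),
    day = c(2, 10, 30, 34, 50, 4, 12, 29, 44, 46),
    value = 1:10
  )
  pairs <- reliability_session_pair(df, day, value, midpoint = 25)
  expect_equal(pairs$day_a[pairs$patient_id == 1], 30)
  expect_equal(pairs$day_b[pairs$patient_id == 1], 34)
  expect_equal(pairs$day_a[pairs$patient_id == 2], 44)
  expect_equal(pairs$day_b[pairs$patient_id == 2], 46)

  # tie in gaps: the earlier pair wins
  df2 <- tibble::tibble(patient_id = 1, day = c(30, 34, 40, 44), value = 1:4)
  p2 <- reliability_session_pair(df2, day, value, midpoint = 25)
  expect_equal(c(p2$day_a, p2$day_b), c(30, 34))

  # too few sessions after the midpoint: falls back with a warning
  df3 <- tibble::tibble(patient_id = 1, day = c(5, 9, 30), value = 1:3)
  expect_warning(p3 <- reliability_session_pair(df3, day, value, midpoint = 25),
                 "fewer than 2")
  expect_equal(c(p3$day_a, p3$day_b), c(9, 30))
})

test_that("force-versus-control clustering partitions the plane", {
  df <- tibble::tibble(
    lforce = c(0.3, 0.8, 0.3, 0.4, 0.39),
    k = c(80, 10, 10, 50, 30)
  )
  out <- cluster_force_vs_control(df, lforce, k)
  expect_equal(as.character(out$cluster),
               c("low-force/high-K", "high-force/low-K", "low-force/low-K",
                 "high-force/high-K", "low-force/high-K"))
  expect_false(anyNA(out$cluster))

  # boundary values go to the high side
  b <- cluster_force_vs_control(tibble::tibble(f = 0.4, k = 30), f, k)
  expect_equal(as.character(b$cluster), "high-force/high-K")

  # exhaustive partition over a random scatter
  set.seed(3)
  rnd <- tibble::tibble(f = runif(200, 0, 1), k = runif(200, 0, 100))
  lab <- cluster_force_vs_control(rnd, f, k)$cluster
  expect_false(anyNA(lab))
})

test_that("cohort summary reports mean/min/max session counts", {
  s <- cohort_summary(c(16, 12, 8, 8, 10, 8, 8, 8, 13, 8))
  expect_equal(s$mean, 9.9)
  expect_equal(s$min, 8)
  expect_equal(s$max, 16)
  expect_equal(cohort_summary(c(8, 8))$mean, 8)
  expect_equal(cohort_summary(8)$mean, 8)
})
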