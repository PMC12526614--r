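# Feature formulas against hand-computed oracles, labeling, and the dataset
# tensor contract.

test_that("knee shakiness matches hand evaluation in both modes", {
  dt <- 1 / 60
  n <- 10
  x_lk <- 0.01 * (0:(n - 1)) # advancing 0.01 m/step -> Vl = 0.6 m/s
  x_rk <- 0.02 * (0:(n - 1)) # Vr = 1.2 m/s
  expect_equal(knee_shakiness(x_lk, x_rk, dt, "magnitude"), rep(1.8, n))
  expect_equal(knee_shakiness(x_lk, x_rk, dt, "signed"), rep(1.8, n))
  # antiphase +0.01 / -0.01 m/step: signed cancels, magnitude does not
  x_rk2 <- -0.01 * (0:(n - 1))
  expect_equal(knee_shakiness(x_lk, x_rk2, dt, "signed"), rep(0, n))
  expect_equal(knee_shakiness(x_lk, x_rk2, dt, "magnitude"), rep(1.2, n))
  # stationary knees
  expect_equal(knee_shakiness(rep(0.2, n), rep(-0.2, n), dt), rep(0, n))
  expect_error(knee_shakiness(x_lk, x_rk, dt = 0), "dt")
})

test_that("knee distance is the absolute ML separation", {
  expect_equal(knee_distance(0.30, 0.10), 0.20)
  expect_equal(knee_distance(c(0.1, 0.2), c(0.1, 0.2)), c(0, 0))
  expect_equal(knee_distance(0.10, 0.30), knee_distance(0.30, 0.10))
  expect_equal(knee_distance(0.10, 0.30, signed = TRUE), -0.20)
  expect_error(knee_distance(1:3, 1:2), "length")
})

test_that("squat depth uses the positive-depth convention", {
  y <- c(1.0, 0.8, 0.6, 0.8, 1.0)
  d <- squat_depth(y, y_t1 = 1.0)
  expect_equal(d$scalar, 0.4)
  expect_equal(d$series, c(0, 0.2, 0.4, 0.2, 0))
  expect_equal(squat_depth(y, 1.0, as_printed = TRUE)$scalar, -0.4)
  expect_equal(squat_depth(rep(1, 5), 1)$scalar, 0)
  expect_gt(squat_depth(c(1, 0.5, 1), 1)$scalar, d$scalar)
})

test_that("sway velocity follows the 3-4-5 hypotenuse oracle", {
  cx <- c(0, 0.003); cy <- c(0, 0.004); dt <- 0.02
  expect_equal(sway_velocity(cx, cy, dt), rep(0.25, 2))
  expect_equal(sway_velocity(cx, cy, dt, as_printed = TRUE), rep(1e-4, 2))
  expect_equal(sway_velocity(rep(0.1, 5), rep(0.2, 5), dt), rep(0, 5))
  # 1/dt scaling: doubling dt halves the default output
  expect_equal(sway_velocity(cx, cy, 2 * dt), sway_velocity(cx, cy, dt) / 2)
})

test_that("sway area matches the inscribed-square shoelace oracle", {
  ang <- seq(0, 2 * pi, by = pi / 2)
  sa <- sway_area(cos(ang), sin(ang), dt = 0.02)
  expect_equal(sum(sa$series), 2.0)
  expect_equal(sa$series[1], 0) # no area swept at onset
  # collinear with the origin: zero increments
  ray <- sway_area(c(1, 2, 3), c(2, 4, 6), dt = 0.02)
  expect_equal(ray$series, c(0, 0, 0))
  expect_equal(sway_area(rep(0, 4), rep(0, 4), 0.02)$scalar, 0)
  # as-printed multiplies increments by dt
  expect_equal(sway_area(cos(ang), sin(ang), 0.02, as_printed = TRUE)$scalar,
               2.0 * 0.02)
})

test_that("the instability label threshold is boundary inclusive", {
  expect_equal(label_squat(c(0.01, 0.029))$label, 0L)
  expect_equal(label_squat(c(0.01, 0.03))$label, 1L)
  expect_equal(label_squat(rep(0, 20))$label, 0L)
  expect_equal(label_squat(c(-0.05, 0.01))$label, 1L) # magnitude of ks
  expect_equal(label_squat(c(0.02, 0.06), stat = "mean")$label, 1L)
  expect_error(label_squat(numeric(0)), "empty")
})

test_that("features are scale equivariant and behave under time reversal", {
  withr::with_seed(8, {
    x_lk <- cumsum(rnorm(30, sd = 0.01)) + 0.15
    x_rk <- cumsum(rnorm(30, sd = 0.01)) - 0.15
    cx <- cumsum(rnorm(30, sd = 0.002))
    cy <- cumsum(rnorm(30, sd = 0.002))
  })
  dt <- 0.02
  c_ <- 2.5
  expect_equal(knee_shakiness(c_ * x_lk, c_ * x_rk, dt),
               c_ * knee_shakiness(x_lk, x_rk, dt))
  expect_equal(knee_distance(c_ * x_lk, c_ * x_rk), c_ * knee_distance(x_lk, x_rk))
  expect_equal(squat_depth(c_ * x_lk, c_ * max(x_lk))$series,
               c_ * squat_depth(x_lk, max(x_lk))$series)
  expect_equal(sway_velocity(c_ * cx, c_ * cy, dt), c_ * sway_velocity(cx, cy, dt))
  expect_equal(sway_area(c_ * cx, c_ * cy, dt)$series,
               c_^2 * sway_area(cx, cy, dt)$series)
  # time reversal: KD/SD reverse; SA total and peak |KS| invariant
  expect_equal(knee_distance(rev(x_lk), rev(x_rk)), rev(knee_distance(x_lk, x_rk)))
  expect_equal(squat_depth(rev(x_lk), max(x_lk))$series,
               rev(squat_depth(x_lk, max(x_lk))$series))
  expect_equal(sway_area(rev(cx), rev(cy), dt)$scalar, sway_area(cx, cy, dt)$scalar)
  expect_equal(max(abs(knee_shakiness(rev(x_lk), rev(x_rk), dt))),
               max(abs(knee_shakiness(x_lk, x_rk, dt))))
})

test_that("the dataset tensor has the fixed channel order and pre-normalization labels", {
  cfg <- tiny_config(n_subjects = 2L, squats_per_subject = 10L,
                     instability_prevalence = 0.3, seed = 13L)
  ds <- cohort_dataset(cfg)
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(dim(ds$x), c(20L, 20L, 5L))
  expect_equal(dimnames(ds$x)[[3]], c("ks", "kd", "sd", "sv", "sa"))
  expect_true(all(ds$labels %in% 0:1))
  expect_true(all(ds$x >= 0 & ds$x <= 1))
  # labels equal the threshold rule applied to the stored physical statistic
  expect_equal(ds$labels, as.integer(ds$ks_stat >= 0.03))
  expect_length(ds$labels, 20L)
})

test_that("label agreement with generator truth is high at calibrated amplitudes", {
  cfg <- tiny_config(n_subjects = 3L, squats_per_subject = 25L,
                     instability_prevalence = 0.065, seed = 21L)
  ds <- cohort_dataset(cfg)
  expect_gte(mean(ds$labels == as.integer(ds$truth), na.rm = TRUE), 0.95)
})

test_that("generator oscillation amplitude injects monotonically into ks_stat", {
  cfg <- tiny_config(n_subjects = 2L, squats_per_subject = 30L,
                     instability_prevalence = 0.5, seed = 17L)
  feats <- list(); amps <- c()
  for (s in 1:2) {
    sess <- generate_session(cfg, s)
    fl <- lowpass(synchronize(sess$camera, sess$plate, subject = s))
    b <- detect_squats(fl)
    for (i in seq_len(nrow(b))) {
      cyc <- extract_window(fl, b[i, ], y_t1 = attr(b, "y_t1"), squat = i)
      feats[[length(feats) + 1L]] <- squat_features(cyc)
      amps <- c(amps, sess$ground_truth$osc_amp_m[i])
    }
  }
  ds <- build_dataset(feats)
  expect_gte(spearman_rho(amps, ds$ks_stat), 0.9)
})

test_that("dataset CSV serialization keeps the channel-order contract", {
  cfg <- tiny_config(n_subjects = 1L, squats_per_subject = 5L)
  ds <- cohort_dataset(cfg)
  ff <- withr::local_tempfile(fileext = ".csv")
  lf <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, ff, lf)
  feats <- utils::read.csv(ff)
  labs <- utils::read.csv(lf)
  expect_named(feats, c("subject", "squat", "row", "ks", "kd", "sd", "sv", "sa"))
  expect_named(labs, c("subject", "squat", "label", "ks_stat"))
  expect_equal(nrow(feats), 5L * 20L)
  expect_equal(feats$ks[feats$squat == 2], ds$x[2, , "ks"])
})
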