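# Squat detection, window extraction, time and amplitude normalization.

raised_cosine_session <- function(depth = 0.4, duration = 4, fs = 50,
                                  lead = 3, standing = 1.0) {
  t <- seq(0, duration + 2 * lead, by = 1 / fs)
  prof <- squatstab:::squat_profile(t, lead, duration, 0.3)
  make_session(t, y_torso = standing - depth * prof)
}

test_that("a flat torso trace yields no cycles", {
  s <- make_session((0:499) / 50, y_torso = rep(1, 500))
  b <- detect_squats(s)
  expect_equal(nrow(b), 0L)
})

test_that("a constructed raised-cosine dip is detected with its depth", {
  s <- raised_cosine_session(depth = 0.4, duration = 4)
  b <- detect_squats(s)
  expect_equal(nrow(b), 1L)
  expect_equal(b$peak_depth, 0.4, tolerance = 0.01)
  expect_equal(b$t_off - b$t_on, 4, tolerance = 0.3)
})

test_that("shallow dips are rejected and counted", {
  s <- raised_cosine_session(depth = 0.05, duration = 4)
  b <- detect_squats(s)
  expect_equal(nrow(b), 0L)
  expect_equal(attr(b, "n_rejected"), 1L)
})

test_that("cycles outside the duration bounds are rejected", {
  s <- raised_cosine_session(depth = 0.4, duration = 12)
  b <- detect_squats(s, dur_bounds = c(1, 10))
  expect_equal(nrow(b), 0L)
  expect_equal(attr(b, "n_rejected"), 1L)
})

test_that("extract_window slices all channels and records the baseline", {
  s <- raised_cosine_session(depth = 0.4, duration = 4)
  b <- detect_squats(s)
  cyc <- extract_window(s, b[1, ], y_t1 = attr(b, "y_t1"), squat = 1L)
  len <- b$end[1] - b$onset[1] + 1L
  for (nm in names(cyc$channels)) expect_length(cyc$channels[[nm]], len)
  expect_equal(max(cyc$y_t1 - cyc$channels$y_torso), 0.4, tolerance = 0.01)
  expect_error(extract_window(s, data.frame(onset = 0, end = 10)), "index error")
})

test_that("windows of non-overlapping boundaries share no sample", {
  t <- seq(0, 24, by = 1 / 50)
  prof <- squatstab:::squat_profile(t, 3, 4, 0.3) +
    squatstab:::squat_profile(t, 12, 4, 0.3)
  s <- make_session(t, y_torso = 1 - 0.4 * prof)
  b <- detect_squats(s)
  expect_equal(nrow(b), 2L)
  expect_lt(b$end[1], b$onset[2])
})

test_that("time normalization is exact on affine channels and keeps endpoints", {
  s <- raised_cosine_session()
  b <- detect_squats(s)
  cyc <- extract_window(s, b[1, ], y_t1 = attr(b, "y_t1"))
  cyc$channels$cop_x <- 3 * cyc$t # affine probe channel
  norm <- time_normalize(cyc, 20L)
  expect_equal(norm$n_samples, 20L)
  expect_equal(norm$channels$cop_x, 3 * norm$t, tolerance = 1e-12)
  expect_equal(norm$t[1], cyc$t[1])
  expect_equal(norm$t[20], cyc$t[length(cyc$t)])
  expect_equal(norm$dt, (cyc$t[length(cyc$t)] - cyc$t[1]) / 19)
  # monotone channels stay monotone under linear interpolation
  cyc$channels$cop_y <- cumsum(abs(sin(cyc$t)))
  expect_true(all(diff(time_normalize(cyc, 20L)$channels$cop_y) >= 0))
})

test_that("time normalization of an already 20-sample uniform window is identity", {
  grid <- seq(0, 1, length.out = 20)
  cyc <- structure(list(subject = 1L, squat = 1L, t = grid,
                        dt = grid[2] - grid[1],
                        channels = list(x_lk = sin(grid)), y_t1 = 1,
                        t_on = 0, t_off = 1, n_samples = 20L),
                   class = "squat_cycle")
  out <- time_normalize(cyc, 20L)
  expect_equal(out$channels$x_lk, sin(grid), tolerance = 1e-12)
})

test_that("min-max normalization maps ranges to [0,1] per scope group", {
  x <- array(0, c(4, 5, 1))
  x[1:2, , 1] <- seq(-2, 2, length.out = 10)   # subject 1
  x[3:4, , 1] <- seq(10, 30, length.out = 10)  # subject 2
  subj <- c(1, 1, 2, 2)
  per <- minmax_normalize(x, subj, "per_subject")
  for (g in 1:2) {
    v <- per$x[subj == g, , 1]
    expect_equal(range(v), c(0, 1))
  }
  # affine map: a value of 0 in subject 1's [-2, 2] range lands at 0.5
  expect_equal(per$x[1:2, , 1], matrix((seq(-2, 2, length.out = 10) + 2) / 4,
                                       2, 5))
  glob <- minmax_normalize(x, subj, "global")
  expect_equal(range(glob$x), c(0, 1))
  expect_equal(min(glob$x[3:4, , 1]), (10 + 2) / 32) # pooled extrema -2..30
})

test_that("constant channels normalize to zero with a warning", {
  x <- array(1, c(2, 5, 1))
  expect_warning(out <- minmax_normalize(x, c(1, 1)), "constant")
  expect_true(all(out$x == 0))
})

test_that("the stored normalization record inverts exactly", {
  withr::with_seed(5, x <- array(rnorm(4 * 20 * 3), c(4, 20, 3)))
  subj <- c(1, 1, 2, 2)
  nrm <- minmax_normalize(x, subj, "per_subject")
  back <- minmax_invert(nrm$x, subj, nrm$record, nrm$scope)
  expect_equal(back, x, tolerance = 1e-9)
})

test_that("segmentation recovers the generated cohort at zero noise", {
  cfg <- noiseless_config(n_subjects = 2L, squats_per_subject = 10L)
  for (s in 1:2) {
    sess <- generate_session(cfg, s)
    fl <- lowpass(synchronize(sess$camera, sess$plate))
    b <- detect_squats(fl)
    expect_equal(nrow(b), 10L)
    expect_lt(max(abs(b$t_on - sess$ground_truth$t_on)), 0.2)
    expect_lt(max(abs(b$t_off - sess$ground_truth$t_off)), 0.2)
  }
})
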