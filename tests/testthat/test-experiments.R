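test_that("saccade metrics recover the analytic crossings of a triangular profile", {
  # speed rises linearly to 400 deg/s at t = 0.1 then falls linearly to 0
  # at t = 0.2; with threshold 40 deg/s the crossings are exact:
  # onset at t = 0.01, offset at the first sample below 40 after the peak
  dt <- 1e-3
  grid <- seq(0, 0.3, by = dt)
  v <- ifelse(grid <= 0.1, 4000 * grid,
              ifelse(grid <= 0.2, 4000 * (0.2 - grid), 0))
  theta <- cumsum(v) * dt
  rec <- stub_record(grid, theta, v, target = 40, threshold = 40)
  m <- saccade_metrics(rec, speed_threshold = 40)
  expect_false(m$degenerate)
  expect_equal(m$onset_time, 0.01)
  expect_equal(m$time_of_peak_speed, 0.1)
  expect_equal(m$peak_speed, 400)
  expect_equal(m$offset_time, 0.191)  # first sample with v < 40 after peak
  expect_equal(m$duration, 0.181)
  expect_equal(m$amplitude, theta[length(theta)])
  expect_equal(m$endpoint_error, 40 - theta[length(theta)])
})

test_that("a motionless record yields degenerate metrics", {
  grid <- seq(0, 0.3, by = 1e-3)
  rec <- stub_record(grid, rep(0, length(grid)), rep(0, length(grid)),
                     target = 10)
  m <- saccade_metrics(rec)
  expect_true(m$degenerate)
  expect_true(is.na(m$peak_speed))
})

test_that("main sequence tabulates one row per target", {
  fx <- tiny_fixture()
  ms <- main_sequence(fx$config, fx$weights, targets = c(8, 14, 20))
  expect_equal(nrow(ms), 3)
  expect_equal(ms$target, c(8, 14, 20))
  expect_true(all(!ms$degenerate))
  expect_true(all(diff(ms$peak_speed) > 0))
})

test_that("zero perturbation makes intact and clamped trials identical", {
  fx <- tiny_fixture()
  ve <- variability_experiment(fx$config, fx$weights, target = 15,
                               burst_reduction = 0)
  expect_equal(ve$intact$dysmetria, ve$clamped$dysmetria, tolerance = 1e-9)
  expect_equal(ve$intact$peak_speed_reduction_pct, 0, tolerance = 1e-9)
  expect_equal(ve$clamped$peak_speed_reduction_pct, 0, tolerance = 1e-9)
  expect_false(ve$intact$late_bulge_present)
  expect_false(ve$clamped$late_bulge_present)
})

test_that("the encoding analysis needs at least three usable trials", {
  fx <- tiny_fixture()
  expect_error(pc_encoding_analysis(fx$config, fx$weights, targets = c(10, 15)),
               "fewer than 3")
})
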