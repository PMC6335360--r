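test_that("compiled and reference engines agree to floating-point accuracy", {
  fx <- tiny_fixture()
  a <- simulate_trial(fx$config, fx$weights, 15, engine = "cpp")
  b <- simulate_trial(fx$config, fx$weights, 15, engine = "r")
  for (sig in c("time", "u", "D", "mf_target", "mf_burst", "y_pc_contra",
                "y_pc_ipsi", "ycfn_contra", "ycfn_ipsi", "y_c", "theta",
                "theta_dot")) {
    expect_equal(a[[sig]], b[[sig]], tolerance = 1e-10)
  }
  expect_equal(a$z_contra, b$z_contra, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(a$onset_time, b$onset_time)
  expect_identical(a$hold_time, b$hold_time)

  # and with a perturbed, clamped trial
  ac <- simulate_trial(fx$config, fx$weights, 15, 0.84, clamp_yc = a$y_c,
                       engine = "cpp")
  bc <- simulate_trial(fx$config, fx$weights, 15, 0.84, clamp_yc = a$y_c,
                       engine = "r")
  expect_equal(ac$theta, bc$theta, tolerance = 1e-10)
})

test_that("a trial is deterministic and its records are internally consistent", {
  fx <- tiny_fixture()
  a <- simulate_trial(fx$config, fx$weights, 12)
  b <- simulate_trial(fx$config, fx$weights, 12)
  expect_identical(a[names(a) != "config"], b[names(b) != "config"])

  ns <- round(fx$config$trial_duration / fx$config$dt) + 1
  for (sig in c("time", "u", "theta", "theta_dot", "y_c", "mf_target",
                "mf_burst")) {
    expect_length(a[[sig]], ns)
  }
  expect_equal(dim(a$z_contra), c(ns, fx$config$N))
  expect_true(all(a$u >= 0))
  expect_true(all(a$u < fx$config$A))
  expect_true(all(is.finite(a$theta)))
})

test_that("the hold switch freezes the eye and silences brainstem and inputs", {
  fx <- tiny_fixture()
  tr <- simulate_trial(fx$config, fx$weights, 15)
  expect_false(tr$degenerate)
  post <- tr$time > tr$hold_time + 1e-9
  expect_true(any(post))
  expect_true(all(tr$u[post] == 0))
  expect_true(all(tr$mf_target[post] == 0))
  expect_true(all(tr$mf_burst[post] == 0))
  final <- tr$theta[length(tr$theta)]
  expect_true(all(abs(tr$theta[post] - final) < 1e-12))
  expect_true(all(tr$theta_dot[post] == 0))
})

test_that("replaying a trial's own cerebellar output reproduces it", {
  fx <- tiny_fixture()
  a <- simulate_trial(fx$config, fx$weights, 15)
  b <- simulate_trial(fx$config, fx$weights, 15, clamp_yc = a$y_c)
  expect_lt(max(abs(a$theta - b$theta)), 1e-9)
  expect_lt(max(abs(a$u - b$u)), 1e-9)
})

test_that("without cerebellar output the eye overshoots every target", {
  fx <- make_fixture("default", seed = 5)
  for (tg in c(10, 12, 15, 18, 20)) {
    tr <- simulate_trial(fx$config, fx$weights, tg, record = FALSE)
    expect_gt(max(tr$theta) - tg, 0)
    expect_gt(tr$theta[length(tr$theta)] - tg, 0)
  }
})

test_that("a perfect displacement integrator slows the eye", {
  fx <- make_fixture("default", seed = 5)
  cfg_k1 <- fx$config
  cfg_k1$k <- 1
  peak <- function(cfg) {
    tr <- simulate_trial(cfg, fx$weights, 15, record = FALSE)
    max(tr$theta_dot)
  }
  expect_lt(peak(cfg_k1), peak(fx$config))
})

test_that("open-loop integrator settles on the command while the eye overshoots", {
  # cerebellum silent, onset never detected (threshold unreachable), so
  # the hold never fires: the displacement-integrator readout converges
  # to the command y_d while the eye transiently exceeds the target.
  fx <- make_fixture("default", seed = 5)
  cfg <- fx$config
  cfg$onset_speed_threshold <- 1e6
  for (tg in c(10, 15, 20)) {
    tr <- simulate_trial(cfg, fx$weights, tg, record = FALSE)
    expect_true(tr$degenerate)
    expect_lt(abs(tr$D[length(tr$D)] - tg), 0.5)
    expect_gt(max(tr$theta), tg)
  }
})

test_that("malformed simulation inputs are rejected", {
  fx <- tiny_fixture()
  expect_error(simulate_trial(fx$config, fx$weights, -4), "positive")
  expect_error(simulate_trial(fx$config, fx$weights, 10, motivation_scale = 1.2),
               "motivation_scale")
  expect_error(simulate_trial(fx$config, fx$weights, 10, clamp_yc = c(1, 2, 3)),
               "time grid")
})
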