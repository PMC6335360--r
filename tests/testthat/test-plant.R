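test_that("plant rests at equilibrium and reaches the m/k3 steady state", {
  disc <- plant_discretization(0.003, 0.6, 4, 1e-3)
  x <- c(0, 0)
  for (i in 1:10) x <- plant_step(x, 0, disc)
  expect_equal(x, c(0, 0))
  # constant drive m = 4 settles at theta = m / k3 = 1 degree
  for (i in 1:3000) x <- plant_step(x, 4, disc)
  expect_equal(x[1], 1, tolerance = 1e-6)
  expect_equal(x[2], 0, tolerance = 1e-4)
})

test_that("default plant is overdamped: monotone step response, no ringing", {
  # characteristic roots of 0.003 s^2 + 0.6 s + 4 via the polynomial oracle
  roots <- sort(Re(polyroot(c(4, 0.6, 0.003))))
  expect_true(all(abs(Im(polyroot(c(4, 0.6, 0.003)))) < 1e-9))
  expect_equal(roots[1], -193.095, tolerance = 1e-3)
  expect_equal(roots[2], -6.905, tolerance = 1e-3)
  disc <- plant_discretization(0.003, 0.6, 4, 1e-3)
  x <- c(0, 0)
  theta <- numeric(400)
  for (i in 1:400) {
    x <- plant_step(x, 4, disc)
    theta[i] <- x[1]
  }
  expect_true(all(diff(theta) >= -1e-12))
  expect_true(all(theta <= 1 + 1e-9))
})

test_that("exact discretization agrees with a fine-step Euler oracle", {
  # 150 ms pulse drive, exact steps at 1 ms against a fine-step Euler
  # oracle. A single Euler run at dt/100 carries a first-order bias of
  # about 1e-4 deg, so the oracle pairs dt/100 with dt/200 and removes
  # that bias by Richardson extrapolation, leaving agreement below
  # 1e-6 deg.
  dt <- 1e-3
  disc <- plant_discretization(0.003, 0.6, 4, dt)
  drive <- function(t) if (t < 0.15) 300 else 0
  x <- c(0, 0)
  for (i in 1:250) x <- plant_step(x, drive((i - 1) * dt), disc)
  euler_end <- function(refine) {
    xe <- c(0, 0)
    h <- dt / refine
    for (i in seq_len(250 * refine)) {
      xe <- plant_step_euler(xe, drive(floor((i - 1) / refine) * dt),
                             0.003, 0.6, 4, h)
    }
    xe[1]
  }
  e1 <- euler_end(100)
  e2 <- euler_end(200)
  expect_lt(abs(x[1] - e1), 5e-4)
  expect_lt(abs(x[1] - (2 * e2 - e1)), 1e-6)
})

test_that("plant response is linear in the drive", {
  disc <- plant_discretization(0.003, 0.6, 4, 1e-3)
  m <- sin(seq(0, 3, length.out = 120)) * 200
  run <- function(scale) {
    x <- c(0, 0)
    for (i in seq_along(m)) x <- plant_step(x, scale * m[i], disc)
    x
  }
  expect_equal(run(3.5), 3.5 * run(1), tolerance = 1e-12)
})

test_that("position clamp zeroes velocity and is idempotent", {
  expect_equal(clamp_position(c(12.3, 250)), c(12.3, 0))
  expect_equal(clamp_position(clamp_position(c(12.3, 250))),
               clamp_position(c(12.3, 250)))
})
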