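test_that("target mossy fiber builds up, plateaus, and is silenced by the hold", {
  lam <- 2
  y_d <- 10
  t_on <- 0.05
  alpha <- 0.015
  expect_equal(mf_target_rate(t_on, t_on, y_d, lam, alpha), lam * y_d)
  expect_equal(mf_target_rate(t_on - alpha, t_on, y_d, lam, alpha),
               lam * y_d * exp(-1))
  expect_equal(mf_target_rate(t_on + 0.1, t_on, y_d, lam, alpha), lam * y_d)
  expect_equal(mf_target_rate(0.2, t_on, y_d, lam, alpha, hold_active = TRUE), 0)
  # buildup is symmetric in time around t_on and vanishing far before it
  expect_lt(mf_target_rate(0, t_on, y_d, lam, alpha), 1e-3)
})

test_that("burst mossy fiber relays the efference copy until the hold", {
  expect_equal(mf_burst_rate(784.9), 784.9)
  expect_equal(mf_burst_rate(784.9, hold_active = TRUE), 0)
  expect_equal(mf_burst_rate(0), 0)
  expect_equal(mf_normalize(40, 1100, lam = 2, A = 1100), c(1, 1))
})

test_that("frozen-drive granule dynamics follow the discrete leaky-integrator closed form", {
  # With rho = 0 and constant mossy input, each unit sees a constant
  # drive S and the Euler recursion has the exact solution
  # z_k = S * (1 - (1 - dt/tau)^k).
  N <- 6
  set.seed(3)
  w_mf <- matrix(runif(2 * N, -3, 3), N, 2)
  w_rec <- matrix(0, N, N)
  mf <- c(0.4, 0.2)
  tau <- 0.02
  dt <- 1e-3
  S <- logistic_rate(as.numeric(w_mf %*% mf))
  z <- numeric(N)
  for (k in 1:30) {
    z <- reservoir_step(z, mf, w_mf, w_rec, tau, rho = 0.5, dt = dt)
    expect_equal(z, S * (1 - (1 - dt / tau)^k), tolerance = 1e-12)
  }
})

test_that("without recurrence units are decoupled", {
  fx <- tiny_fixture()
  N <- fx$config$N
  w_rec0 <- matrix(0, N, N)
  mf <- c(0.5, 0.1)
  z1 <- rep(0.2, N)
  z2 <- z1
  z2[3] <- 0.9  # perturb one unit only
  s1 <- reservoir_step(z1, mf, fx$weights$w_mf_grc_contra, w_rec0,
                       0.02, 0, 1e-3)
  s2 <- reservoir_step(z2, mf, fx$weights$w_mf_grc_contra, w_rec0,
                       0.02, 0, 1e-3)
  expect_equal(s1[-3], s2[-3])
  expect_false(isTRUE(all.equal(s1[3], s2[3])))
})

test_that("resting baseline solves the fixed-point equation and attracts the dynamics", {
  fx <- tiny_fixture()
  w_rec <- fx$weights$w_rec_contra
  rho <- 0.5
  z_star <- reservoir_baseline(w_rec, rho)
  # algebraic route: residual of z = f(-rho W z)
  resid <- z_star - logistic_rate(-rho * as.numeric(w_rec %*% z_star))
  expect_lt(max(abs(resid)), 1e-10)
  # dynamic route: relaxing the ODE from zero input converges to the same point
  z <- rep(0, nrow(w_rec))
  w_mf0 <- fx$weights$w_mf_grc_contra * 0
  for (i in 1:4000) z <- reservoir_step(z, c(0, 0), w_mf0, w_rec, 0.02, rho, 1e-3)
  expect_equal(z, z_star, tolerance = 1e-6)
})

test_that("Purkinje readout is the plain population projection", {
  z <- c(0.1, 0.4, 0.3)
  expect_equal(pc_population_activity(z, c(0, 0, 0)), 0)
  expect_equal(pc_population_activity(z, c(0, 1, 0)), 0.4)
  expect_equal(pc_population_activity(rep(0.25, 10), rep(1, 10)), 2.5)
  expect_error(pc_population_activity(z, c(1, 2)), "length")
})

test_that("fastigial combination and net output follow their signed arithmetic", {
  expect_equal(cfn_activity(0, 300, 20, 0.5), 150)
  expect_equal(cfn_activity(1, 40, 20, 0.5), 0)   # inhibition balances drive
  expect_lt(cfn_activity(0.5, 0, 20, 0.5), 0)
  expect_equal(net_cerebellar_output(87, 87, 0.02, -0.02), 0)
  expect_equal(net_cerebellar_output(100, 0, 0.02, -0.02), 2)
  expect_equal(net_cerebellar_output(0, 100, 0.02, -0.02), -2)
})

test_that("reservoir activity stays bounded over long horizons for many draws", {
  cfg <- default_config()
  cfg$N <- 12L
  cfg$recurrent_density <- 0.3
  n_steps <- 10 * round(cfg$trial_duration / 1e-3)  # 10 trial durations
  for (seed in 1:20) {
    w <- init_weights(cfg, seed = seed)
    z <- reservoir_baseline(w$w_rec_contra, cfg$rho)
    zmax <- 0
    for (i in seq_len(n_steps)) {
      mf <- c(0.5 * (1 + sin(i / 40)), 0.3 * (1 + cos(i / 23)))
      z <- reservoir_step(z, mf, w$w_mf_grc_contra, w$w_rec_contra,
                          cfg$tau, cfg$rho, 1e-3)
      zmax <- max(zmax, max(z))
    }
    expect_true(is.finite(zmax))
    expect_lte(zmax, cfg$f_max + 1e-9)
  }
})

test_that("reservoir trajectories forget their initial state under shared input", {
  fx <- tiny_fixture()
  w <- fx$weights
  set.seed(11)
  z_a <- runif(fx$config$N)
  z_b <- runif(fx$config$N)
  dist <- numeric(300)
  for (i in 1:300) {
    mf <- c(0.5 * (1 + sin(i / 30)), 0.4 * abs(cos(i / 17)))
    z_a <- reservoir_step(z_a, mf, w$w_mf_grc_contra, w$w_rec_contra,
                          0.02, 0.5, 1e-3)
    z_b <- reservoir_step(z_b, mf, w$w_mf_grc_contra, w$w_rec_contra,
                          0.02, 0.5, 1e-3)
    dist[i] <- sqrt(sum((z_a - z_b)^2))
  }
  expect_lt(dist[300], 1e-4 * dist[1])
  # contraction after a short transient
  expect_true(all(diff(dist[10:300]) <= 1e-12))
})

test_that("the two granular layers show matching response-magnitude profiles", {
  # The layers share their inputs but have independent random weights,
  # so unit-by-unit traces differ while the distribution of response
  # magnitudes matches: compare per-unit peak deviations from rest,
  # rank-matched across sides.
  fx <- make_fixture("default", seed = 2)
  tr <- simulate_trial(fx$config, fx$weights, 15)
  mag <- function(z) apply(abs(sweep(z, 2, z[1, ])), 2, max)
  m_c <- sort(mag(tr$z_contra))
  m_i <- sort(mag(tr$z_ipsi))
  expect_gt(stats::cor(m_c, m_i), 0.95)
  expect_lt(abs(mean(m_c) - mean(m_i)), 0.2 * max(mean(m_c), mean(m_i)))
})
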