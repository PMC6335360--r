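test_that("trial cost matches hand-computed integrals", {
  grid <- seq(0, 0.4, by = 1e-3)
  perfect <- list(target = 10, theta = rep(10, length(grid)), time = grid)
  expect_equal(trial_cost(perfect, numeric(5), numeric(5), 1e-4), 0)

  # constant 1-degree error over 0.4 s integrates to 0.4
  off <- list(target = 10, theta = rep(9, length(grid)), time = grid)
  expect_equal(trial_cost(off, numeric(5), numeric(5), 1e-4), 0.4)

  # pure regularization: ||w||^2 = 100 at gamma = 1e-4 costs 0.01
  w <- rep(sqrt(100 / 10), 10)
  expect_equal(trial_cost(perfect, w, numeric(10), 1e-4), 0.01)

  # a linear ramp error integrates to its triangle area
  ramp <- list(target = 1, theta = grid / 0.4, time = grid)
  expect_equal(trial_cost(ramp, numeric(2), numeric(2), 0), 0.2,
               tolerance = 1e-12)

  # dt-refinement invariance of the trapezoidal sum
  grid2 <- seq(0, 0.4, by = 5e-4)
  off2 <- list(target = 10, theta = rep(9, length(grid2)), time = grid2)
  expect_equal(trial_cost(off2, numeric(5), numeric(5), 1e-4),
               trial_cost(off, numeric(5), numeric(5), 1e-4))
})

test_that("training is reproducible and reduces the cost on a small model", {
  fx <- tiny_fixture(seed = 3)
  r1 <- train_omv(fx$config, fx$weights, seed = 9, max_epochs = 3,
                  inner_maxit = 3, probe_targets = c(6, 12, 18))
  r2 <- train_omv(fx$config, fx$weights, seed = 9, max_epochs = 3,
                  inner_maxit = 3, probe_targets = c(6, 12, 18))
  expect_identical(r1$cost_history, r2$cost_history)
  expect_identical(r1$weights, r2$weights)
  expect_lt(min(r1$cost_history), r1$cost_history[1] + 1e-12)
  # training touched only the plastic readouts
  expect_identical(r1$weights$w_rec_contra, fx$weights$w_rec_contra)
  expect_identical(r1$weights$w_mf_grc_ipsi, fx$weights$w_mf_grc_ipsi)
})

test_that("stronger regularization shrinks the learned readout norm", {
  fx <- tiny_fixture(seed = 3)
  cfg_hi <- fx$config
  cfg_hi$gamma <- 100
  lo <- train_omv(fx$config, fx$weights, seed = 4, max_epochs = 3,
                  inner_maxit = 3, probe_targets = c(8, 16))
  hi <- train_omv(cfg_hi, fx$weights, seed = 4, max_epochs = 3,
                  inner_maxit = 3, probe_targets = c(8, 16))
  norm2 <- function(w) sum(w$w_pf_pc_contra^2) + sum(w$w_pf_pc_ipsi^2)
  expect_lt(norm2(hi$weights), norm2(lo$weights))
})
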