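#' Cumulative gaze-error cost of one trial
#'
#' The learning criterion: time-integrated absolute gaze error plus
#' squared-norm regularization of the plastic readout weights,
#' `J = integral |y_d - theta(t)| dt + gamma * (||w_contra||^2 +
#' ||w_ipsi||^2)`. The time term is evaluated by the trapezoidal rule on
#' the trial's grid, so `J` is invariant under `dt` refinement. Both the
#' desired and executed displacements are measured from the trial start
#' (the eye starts at 0 deg, so they equal the target and `theta(t)`).
#'
#' @param record an [simulate_trial()] result.
#' @param w_pf_pc_contra,w_pf_pc_ipsi the plastic readout vectors the
#'   trial was run with.
#' @param gamma regularization coefficient.
#' @return the scalar cost `J`.
#' @export
#' @examples
#' # constant 1-degree error over a 0.4 s trial, no weights -> J = 0.4
trial_cost <- function(record, w_pf_pc_contra, w_pf_pc_ipsi, gamma) {
  err <- abs(record$target - record$theta)
  t <- record$time
  n <- length(t)
  time_term <- sum(diff(t) * (err[-1] + err[-n]) / 2)
  time_term + gamma * (sum(w_pf_pc_contra^2) + sum(w_pf_pc_ipsi^2))
}

#' Train the parallel fiber to Purkinje cell weights
#'
#' Derivative-free adaptation of the bilateral plastic readouts (and
#' optionally the reservoir time constant and spectral radius) by
#' repeated minimization of the mean trial cost over batches of randomly
#' drawn targets. Each epoch draws a fresh batch of
#' `n_targets_per_iter` targets uniformly within `target_range` and runs
#' a few iterations of box-constrained quasi-Newton descent (`optim`
#' `"L-BFGS-B"`) with finite-difference gradients, warm-started from the
#' previous epoch. After every epoch the mean absolute endpoint error on
#' a fixed probe grid is evaluated; training stops when that error has
#' saturated (range below `sat_tol` over the last `patience` epochs) or
#' after `max_epochs` epochs.
#'
#' @param config a validated [default_config()] object.
#' @param weights an [init_weights()] container supplying the fixed
#'   random structure and initial readouts.
#' @param target_range numeric length-2, the training target range in
#'   degrees (default 4-20).
#' @param n_targets_per_iter targets drawn per epoch.
#' @param seed RNG seed controlling the target draws (and hence the whole
#'   run: identical seeds give identical results).
#' @param optimize_reservoir_params if `TRUE`, `tau` and `rho` are
#'   appended to the optimized vector with box constraints
#'   `tau` in \[5, 100\] ms and `rho` in (0, 1\], starting from the
#'   midpoints of their boxes.
#' @param max_epochs epoch cap.
#' @param inner_maxit L-BFGS-B iterations per epoch.
#' @param patience,sat_tol saturation rule: stop once the probe endpoint
#'   error varies by less than `sat_tol` degrees over `patience` epochs.
#' @param probe_targets fixed target grid for the stopping statistic.
#' @param grad_type `"forward"` (default, one extra cost evaluation per
#'   parameter) or `"central"` finite differences.
#' @param fd_step finite-difference step.
#' @param pc_rate_penalty optional soft physiological constraint: the
#'   time integral of negative Purkinje population-rate excursions, both
#'   sides, is added to the batch cost with this weight (a firing-rate
#'   population cannot discharge below zero). Off (0) by default, so the
#'   criterion is exactly the gaze-error-plus-regularization cost; see
#'   the methods vignette for the effect of enabling it.
#' @param verbose print per-epoch progress.
#' @return an object of class `omv_training`: the converged `weights`,
#'   `cost_history` (one batch-mean cost per epoch), `probe_history`
#'   (mean absolute probe endpoint error per epoch), `per_target_error`
#'   (named vector over `probe_targets`), `free_params` (converged
#'   `tau`/`rho` when optimized, else `NULL`), the final `config`, and
#'   the `seed`.
#' @export
train_omv <- function(config, weights, target_range = c(4, 20),
                      n_targets_per_iter = 8L, seed = 1L,
                      optimize_reservoir_params = FALSE,
                      max_epochs = 15L, inner_maxit = 6L,
                      patience = 10L, sat_tol = 0.05,
                      probe_targets = c(4, 8, 12, 16, 20),
                      grad_type = c("forward", "central"),
                      fd_step = 1e-4, pc_rate_penalty = 0,
                      verbose = FALSE) {
  config <- validate_config(config)
  validate_weights(weights, config)
  grad_type <- match.arg(grad_type)
  stopifnot(length(target_range) == 2L, target_range[1] > 0,
            target_range[2] <= 30, target_range[1] < target_range[2])
  N <- config$N

  n_w <- 2L * N
  par <- c(weights$w_pf_pc_contra, weights$w_pf_pc_ipsi)
  lower <- rep(-Inf, n_w)
  upper <- rep(Inf, n_w)
  if (optimize_reservoir_params) {
    par <- c(par, 0.0525, 0.5)  # box midpoints for (tau, rho)
    lower <- c(lower, 0.005, 1e-3)
    upper <- c(upper, 0.100, 1.0)
  }

  apply_par <- function(p) {
    w <- weights
    w$w_pf_pc_contra <- p[seq_len(N)]
    w$w_pf_pc_ipsi <- p[N + seq_len(N)]
    cfg <- config
    if (optimize_reservoir_params) {
      cfg$tau <- p[n_w + 1L]
      cfg$rho <- p[n_w + 2L]
    }
    list(cfg = cfg, w = w)
  }

  # The plant discretization and the reservoir resting state do not depend
  # on the plastic readouts, so they are hoisted out of the inner cost
  # loop; the resting state does depend on rho, hence the small cache used
  # when the reservoir parameters are free.
  disc <- plant_discretization(config$k1, config$k2, config$k3, config$dt)
  z0_cache <- new.env(parent = emptyenv())
  z0_for <- function(rho) {
    key <- sprintf("%.17g", rho)
    hit <- z0_cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- list(
      c = reservoir_baseline(weights$w_rec_contra, rho, config$f_max),
      i = reservoir_baseline(weights$w_rec_ipsi, rho, config$f_max))
    if (length(ls(z0_cache)) > 32L) rm(list = ls(z0_cache), envir = z0_cache)
    z0_cache[[key]] <- val
    val
  }

  sim_summary <- function(mw, z0, tg) {
    .sim_trial_cpp(mw$cfg,
                   mw$w$w_mf_grc_contra, mw$w$w_mf_grc_ipsi,
                   mw$w$w_rec_contra, mw$w$w_rec_ipsi,
                   mw$w$w_pf_pc_contra, mw$w$w_pf_pc_ipsi,
                   z0$c, z0$i, disc$Ad, disc$Bd,
                   tg, 1.0, NULL, 0L)
  }

  batch_cost <- function(p, targets) {
    mw <- apply_par(p)
    z0 <- z0_for(mw$cfg$rho)
    reg <- mw$cfg$gamma * sum(p[seq_len(n_w)]^2)
    total <- 0
    for (tg in targets) {
      s <- sim_summary(mw, z0, tg)
      total <- total + s$j_time + reg + pc_rate_penalty * s$j_pc_neg
    }
    total / length(targets)
  }

  fd_grad <- function(p, targets, f0) {
    g <- numeric(length(p))
    for (j in seq_along(p)) {
      h <- fd_step * max(1, abs(p[j]))
      if (grad_type == "forward") {
        pj <- p
        if (p[j] + h <= upper[j]) {
          pj[j] <- p[j] + h
          g[j] <- (batch_cost(pj, targets) - f0) / h
        } else {  # at the upper box bound: one-sided backward step
          pj[j] <- p[j] - h
          g[j] <- (f0 - batch_cost(pj, targets)) / h
        }
      } else {
        ph <- p
        pl <- p
        ph[j] <- min(p[j] + h, upper[j])
        pl[j] <- max(p[j] - h, lower[j])
        g[j] <- (batch_cost(ph, targets) - batch_cost(pl, targets)) /
          (ph[j] - pl[j])
      }
    }
    g
  }

  probe_errors <- function(p) {
    mw <- apply_par(p)
    z0 <- z0_for(mw$cfg$rho)
    vapply(probe_targets, function(tg) {
      tg - sim_summary(mw, z0, tg)$theta_end
    }, numeric(1))
  }

  old_rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_rng)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_rng, envir = globalenv())
  })
  set.seed(as.integer(seed))

  cost_history <- numeric(0)
  probe_history <- numeric(0)
  # reference cost on the fixed probe grid: the random per-epoch batches
  # are not comparable across epochs
  untrained_cost <- batch_cost(par, probe_targets)
  stalled <- 0L

  for (epoch in seq_len(max_epochs)) {
    targets <- stats::runif(n_targets_per_iter, target_range[1], target_range[2])
    fit <- stats::optim(
      par,
      fn = function(p) batch_cost(p, targets),
      gr = function(p) fd_grad(p, targets, batch_cost(p, targets)),
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = inner_maxit)
    )
    moved <- max(abs(fit$par - par))
    par <- fit$par
    cost_history <- c(cost_history, fit$value)
    probe <- mean(abs(probe_errors(par)))
    probe_history <- c(probe_history, probe)
    if (verbose) {
      message(sprintf("epoch %3d: batch cost %.4f, probe |err| %.4f deg",
                      epoch, fit$value, probe))
    }
    if (length(probe_history) >= patience) {
      recent <- utils::tail(probe_history, patience)
      if (max(recent) - min(recent) < sat_tol) break
    }
    # stationary point for several distinct batches: fully saturated
    stalled <- if (moved < 1e-9) stalled + 1L else 0L
    if (stalled >= 3L) break
  }

  final_cost <- batch_cost(par, probe_targets)
  if (final_cost >= untrained_cost) {
    cond <- simpleError(sprintf(
      "training failed to reduce the cost below its untrained value (%.4f -> %.4f)",
      untrained_cost, final_cost))
    cond$cost_history <- cost_history
    stop(cond)
  }

  mw <- apply_par(par)
  per_target <- probe_errors(par)
  names(per_target) <- as.character(probe_targets)
  res <- list(
    weights = mw$w,
    config = mw$cfg,
    cost_history = cost_history,
    probe_history = probe_history,
    per_target_error = per_target,
    free_params = if (optimize_reservoir_params) {
      c(tau = mw$cfg$tau, rho = mw$cfg$rho)
    } else NULL,
    seed = as.integer(seed),
    epochs = length(cost_history)
  )
  class(res) <- "omv_training"
  res
}

#' @export
print.omv_training <- function(x, ...) {
  cat("<omv_training>\n")
  cat(sprintf("  %d epochs (seed %d); batch cost %.4f -> %.4f\n",
              x$epochs, x$seed, x$cost_history[1],
              utils::tail(x$cost_history, 1)))
  cat(sprintf("  probe |endpoint error|: %.3f deg (targets %s)\n",
              mean(abs(x$per_target_error)),
              paste(names(x$per_target_error), collapse = ", ")))
  if (!is.null(x$free_params)) {
    cat(sprintf("  converged tau = %.4f s, rho = %.3f\n",
                x$free_params["tau"], x$free_params["rho"]))
  }
  invisible(x)
}
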