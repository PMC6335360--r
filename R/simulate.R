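#' Simulate one closed-loop saccade trial
#'
#' Wires the brainstem burst generator, the bilateral cerebellar vermis,
#' and the oculomotor plant into a single closed loop and integrates it at
#' a fixed step. Per step, in order: (1) mossy-fiber rates from the clock
#' and the previous burst output (one-step efference-copy delay); (2) one
#' reservoir step per side; (3) Purkinje, fastigial, and net cerebellar
#' output (or the clamped replay value); (4) burst output using that
#' correction; (5) displacement-integrator step; (6) plant step (position
#' clamp once the eye-hold switch has fired). Movement onset is detected
#' online as the first crossing of `onset_speed_threshold`; the hold
#' switch fires `cutoff_after_onset` later and silences the brainstem and
#' all vermal inputs for the rest of the trial.
#'
#' @param config a validated [default_config()] object.
#' @param weights an [init_weights()] container (possibly trained).
#' @param target desired rightward displacement (deg), > 0.
#' @param motivation_scale multiplier on the burst amplitude in (0, 1].
#' @param clamp_yc optional numeric vector covering the full time grid:
#'   the cerebellar output is replayed from it instead of being computed,
#'   emulating a vermis blind to ongoing variability.
#' @param engine `"cpp"` (compiled fast path, default) or `"r"`
#'   (reference implementation composed of the exported step functions;
#'   equivalent output to floating-point accuracy, used for
#'   cross-checking).
#' @param record keep the full granule activity history (`TRUE`) or only
#'   the scalar signal traces (`FALSE`, used inside training loops).
#' @return an object of class `omv_trial`: time grid plus the traces
#'   `u`, `D`, `mf_target`, `mf_burst`, `y_pc_contra/ipsi`,
#'   `ycfn_contra/ipsi`, `y_c`, `theta`, `theta_dot`; granule histories
#'   `z_contra`, `z_ipsi` (samples x N) when recorded; the detected
#'   `onset_time`, `hold_time`, a `degenerate` flag (no onset detected),
#'   and the trial inputs (`target`, `motivation_scale`, `clamped`).
#' @export
#' @examples
#' cfg <- make_fixture("tiny")$config
#' w <- make_fixture("tiny")$weights
#' tr <- simulate_trial(cfg, w, target = 15)
#' max(tr$theta)
simulate_trial <- function(config, weights, target, motivation_scale = 1,
                           clamp_yc = NULL, engine = c("cpp", "r"),
                           record = TRUE) {
  engine <- match.arg(engine)
  config <- validate_config(config)
  validate_weights(weights, config)
  if (length(target) != 1L || !is.finite(target) || target <= 0) {
    stop("target must be a single positive displacement in degrees")
  }
  sc_command(target)
  if (motivation_scale <= 0 || motivation_scale > 1) {
    stop("motivation_scale must lie in (0, 1]")
  }
  ns <- round(config$trial_duration / config$dt) + 1L
  if (!is.null(clamp_yc) && length(clamp_yc) != ns) {
    stop("clamp_yc must cover the full time grid (", ns, " samples)")
  }
  disc <- plant_discretization(config$k1, config$k2, config$k3, config$dt)
  z0_c <- reservoir_baseline(weights$w_rec_contra, config$rho, config$f_max)
  z0_i <- reservoir_baseline(weights$w_rec_ipsi, config$rho, config$f_max)
  raw <- if (engine == "cpp") {
    .sim_trial_cpp(config, weights$w_mf_grc_contra, weights$w_mf_grc_ipsi,
                   weights$w_rec_contra, weights$w_rec_ipsi,
                   weights$w_pf_pc_contra, weights$w_pf_pc_ipsi,
                   z0_c, z0_i, disc$Ad, disc$Bd,
                   target, motivation_scale, clamp_yc,
                   if (record) 2L else 1L)
  } else {
    sim_trial_r(config, weights, z0_c, z0_i, disc,
                target, motivation_scale, clamp_yc, record)
  }
  raw$target <- target
  raw$motivation_scale <- motivation_scale
  raw$clamped <- !is.null(clamp_yc)
  raw$config <- config
  class(raw) <- "omv_trial"
  raw
}

# Reference engine: the same loop, composed of the exported step
# functions. Agreement with the compiled engine (to floating-point
# accuracy) is asserted in the test suite.
sim_trial_r <- function(config, weights, z0_c, z0_i, disc,
                        target, motivation_scale, clamp_yc, record) {
  cfg <- config
  n <- round(cfg$trial_duration / cfg$dt)
  ns <- n + 1L
  N <- cfg$N
  eps <- 1e-12
  clamped <- !is.null(clamp_yc)

  time <- u <- D <- mft <- mfb <- y_pc_c <- y_pc_i <-
    ycfn_c <- ycfn_i <- y_c <- theta <- theta_dot <- numeric(ns)
  if (record) {
    z_hist_c <- matrix(0, ns, N)
    z_hist_i <- matrix(0, ns, N)
  }

  z_c <- z0_c
  z_i <- z0_i
  Dcur <- 0
  ucur <- 0
  x <- c(0, 0)

  y_pc_c[1] <- pc_population_activity(z_c, weights$w_pf_pc_contra)
  y_pc_i[1] <- pc_population_activity(z_i, weights$w_pf_pc_ipsi)
  ycfn_c[1] <- cfn_activity(y_pc_c[1], 0, cfg$w_pc_cfn_contra, cfg$w_mf_cfn_contra)
  ycfn_i[1] <- cfn_activity(y_pc_i[1], 0, cfg$w_pc_cfn_ipsi, cfg$w_mf_cfn_ipsi)
  y_c[1] <- if (clamped) clamp_yc[1] else
    net_cerebellar_output(ycfn_c[1], ycfn_i[1], cfg$r1, cfg$r2)
  mft[1] <- mf_target_rate(0, cfg$t_on, target, cfg$lam, cfg$alpha)
  if (record) {
    z_hist_c[1, ] <- z_c
    z_hist_i[1, ] <- z_i
  }

  onset_seen <- FALSE
  hold <- FALSE
  onset_time <- NA_real_

  for (i in seq_len(n)) {
    t_next <- i * cfg$dt
    if (!hold && hold_switch(onset_time, t_next + eps, cfg$cutoff_after_onset)) {
      hold <- TRUE
    }

    mf_t <- mf_target_rate(t_next, cfg$t_on, target, cfg$lam, cfg$alpha,
                           hold_active = hold)
    mf_b <- mf_burst_rate(ucur, hold_active = hold)
    mf <- mf_normalize(mf_t, mf_b, cfg$lam, cfg$A)

    z_c <- reservoir_step(z_c, mf, weights$w_mf_grc_contra,
                          weights$w_rec_contra, cfg$tau, cfg$rho, cfg$dt,
                          cfg$f_max)
    z_i <- reservoir_step(z_i, mf, weights$w_mf_grc_ipsi,
                          weights$w_rec_ipsi, cfg$tau, cfg$rho, cfg$dt,
                          cfg$f_max)

    ypc_c <- pc_population_activity(z_c, weights$w_pf_pc_contra)
    ypc_i <- pc_population_activity(z_i, weights$w_pf_pc_ipsi)
    yf_c <- cfn_activity(ypc_c, mf_b, cfg$w_pc_cfn_contra, cfg$w_mf_cfn_contra)
    yf_i <- cfn_activity(ypc_i, mf_b, cfg$w_pc_cfn_ipsi, cfg$w_mf_cfn_ipsi)
    yc <- if (clamped) clamp_yc[i + 1L] else
      net_cerebellar_output(yf_c, yf_i, cfg$r1, cfg$r2)

    # before t_on the omnipause gate keeps the brainstem silent and the
    # eye still; after the cutoff the eye-hold switch does the same
    gated <- hold || t_next < cfg$t_on - eps
    y_d <- if (gated) 0 else sc_command(target)
    unew <- burst_output(y_d, yc, Dcur, cfg$A, cfg$sigma, motivation_scale,
                         hold_active = gated)
    Dcur <- integrator_step(Dcur, unew, cfg$k, cfg$dt)

    if (gated) {
      x <- clamp_position(x)
    } else {
      x <- plant_step(x, unew, disc)
    }

    s <- i + 1L
    time[s] <- t_next
    u[s] <- unew
    D[s] <- Dcur
    mft[s] <- mf_t
    mfb[s] <- mf_b
    y_pc_c[s] <- ypc_c
    y_pc_i[s] <- ypc_i
    ycfn_c[s] <- yf_c
    ycfn_i[s] <- yf_i
    y_c[s] <- yc
    theta[s] <- x[1]
    theta_dot[s] <- x[2]
    if (record) {
      z_hist_c[s, ] <- z_c
      z_hist_i[s, ] <- z_i
    }
    ucur <- unew

    if (!onset_seen && !hold && x[2] >= cfg$onset_speed_threshold) {
      onset_seen <- TRUE
      onset_time <- t_next
    }
  }

  if (any(!is.finite(theta))) {
    stop("numerical divergence: non-finite eye position")
  }
  out <- list(time = time, u = u, D = D, mf_target = mft, mf_burst = mfb,
              y_pc_contra = y_pc_c, y_pc_ipsi = y_pc_i,
              ycfn_contra = ycfn_c, ycfn_ipsi = ycfn_i, y_c = y_c,
              theta = theta, theta_dot = theta_dot,
              onset_time = onset_time,
              hold_time = if (onset_seen) onset_time + cfg$cutoff_after_onset else NA_real_,
              degenerate = !onset_seen)
  if (record) {
    out$z_contra <- z_hist_c
    out$z_ipsi <- z_hist_i
  }
  out
}

#' @export
print.omv_trial <- function(x, ...) {
  cat("<omv_trial>\n")
  cat(sprintf("  target %g deg, motivation %g%s\n", x$target,
              x$motivation_scale, if (x$clamped) ", clamped vermal output" else ""))
  cat(sprintf("  %d samples, dt = %g s\n", length(x$time), x$config$dt))
  if (x$degenerate) {
    cat("  degenerate: no movement onset detected\n")
  } else {
    cat(sprintf("  onset %.3f s, hold %.3f s, endpoint %.3f deg, peak speed %.1f deg/s\n",
                x$onset_time, x$hold_time, x$theta[length(x$theta)],
                max(x$theta_dot)))
  }
  invisible(x)
}

#' Coerce a trial record to a data frame
#'
#' One row per timestep, one column per scalar signal. Granule histories
#' are omitted (export them separately; see [write_trial_csv()]).
#'
#' @param x an `omv_trial`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return a `data.frame`.
#' @export
as.data.frame.omv_trial <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = x$time, u = x$u, D = x$D,
             mf_target = x$mf_target, mf_burst = x$mf_burst,
             y_pc_contra = x$y_pc_contra, y_pc_ipsi = x$y_pc_ipsi,
             ycfn_contra = x$ycfn_contra, ycfn_ipsi = x$ycfn_ipsi,
             y_c = x$y_c, theta = x$theta, theta_dot = x$theta_dot)
}

#' Export a trial record to CSV
#'
#' Writes the scalar signals to `<prefix>.csv` and, when granule
#' histories were recorded, the per-side activities to wide companion
#' files `<prefix>_z_contra.csv` / `<prefix>_z_ipsi.csv`.
#'
#' @param trial an `omv_trial`.
#' @param prefix output path prefix.
#' @return the paths written, invisibly.
#' @export
write_trial_csv <- function(trial, prefix) {
  main <- paste0(prefix, ".csv")
  utils::write.csv(as.data.frame(trial), main, row.names = FALSE)
  paths <- main
  for (side in c("contra", "ipsi")) {
    zname <- paste0("z_", side)
    if (!is.null(trial[[zname]])) {
      zpath <- paste0(prefix, "_", zname, ".csv")
      zdf <- as.data.frame(trial[[zname]])
      names(zdf) <- sprintf("z%03d", seq_len(ncol(zdf)))
      utils::write.csv(cbind(time = trial$time, zdf), zpath,
                       row.names = FALSE)
      paths <- c(paths, zpath)
    }
  }
  invisible(paths)
}
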