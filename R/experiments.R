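#' Kinematic metrics of one saccade trial
#'
#' Onset is the first up-crossing of the speed threshold, offset the
#' first drop back below it after peak speed (falling back to the hold
#' time, then the trial end, if the speed never drops). Amplitude is the
#' net displacement over the trial and the endpoint error is signed,
#' `target - final position`.
#'
#' @param record an [simulate_trial()] result.
#' @param speed_threshold onset/offset criterion (deg/s); defaults to the
#'   trial's configured threshold.
#' @return a list of class `omv_metrics`: `onset_time`, `offset_time`,
#'   `duration`, `amplitude`, `peak_speed`, `time_of_peak_speed`,
#'   `endpoint_error`, `degenerate`. A record whose speed never crosses
#'   the threshold yields `degenerate = TRUE` and `NA` metrics.
#' @export
saccade_metrics <- function(record,
                            speed_threshold = record$config$onset_speed_threshold) {
  v <- record$theta_dot
  t <- record$time
  up <- which(v >= speed_threshold)
  if (length(up) == 0L) {
    out <- list(onset_time = NA_real_, offset_time = NA_real_,
                duration = NA_real_, amplitude = NA_real_,
                peak_speed = NA_real_, time_of_peak_speed = NA_real_,
                endpoint_error = NA_real_, degenerate = TRUE)
    class(out) <- "omv_metrics"
    return(out)
  }
  onset_idx <- up[1]
  peak_idx <- which.max(v)
  after <- which(v < speed_threshold & seq_along(v) > peak_idx)
  offset_idx <- if (length(after) > 0L) after[1] else length(v)
  out <- list(
    onset_time = t[onset_idx],
    offset_time = t[offset_idx],
    duration = t[offset_idx] - t[onset_idx],
    amplitude = record$theta[length(record$theta)] - record$theta[1],
    peak_speed = v[peak_idx],
    time_of_peak_speed = t[peak_idx],
    endpoint_error = record$target - record$theta[length(record$theta)],
    degenerate = FALSE
  )
  class(out) <- "omv_metrics"
  out
}

#' @export
print.omv_metrics <- function(x, ...) {
  if (x$degenerate) {
    cat("<omv_metrics> degenerate (no threshold crossing)\n")
  } else {
    cat(sprintf(
      "<omv_metrics> amplitude %.2f deg, peak %.1f deg/s @ %.3f s, duration %.0f ms, error %.3f deg\n",
      x$amplitude, x$peak_speed, x$time_of_peak_speed, 1000 * x$duration,
      x$endpoint_error))
  }
  invisible(x)
}

#' Main-sequence table
#'
#' Simulates one trial per target and tabulates amplitude, peak speed,
#' time of peak speed, duration, and endpoint error - the stereotyped
#' speed-amplitude and duration-amplitude relations of saccades.
#'
#' @param config,weights model and (typically trained) weights.
#' @param targets target displacements (deg).
#' @return a `data.frame` with one row per target.
#' @export
main_sequence <- function(config, weights, targets = seq(4, 20, by = 2)) {
  rows <- lapply(targets, function(tg) {
    tr <- simulate_trial(config, weights, tg, record = FALSE)
    m <- saccade_metrics(tr)
    data.frame(target = tg, amplitude = m$amplitude,
               peak_speed = m$peak_speed, duration = m$duration,
               time_of_peak_speed = m$time_of_peak_speed,
               endpoint_error = m$endpoint_error,
               degenerate = m$degenerate)
  })
  do.call(rbind, rows)
}

# baseline-subtracted population trace over the pre-buildup window
population_trace <- function(time, activity, baseline_window = 0.020,
                             until = NULL) {
  base_idx <- which(time <= baseline_window)
  baseline <- mean(activity[base_idx])
  delta <- activity - baseline
  search <- if (is.null(until) || is.na(until)) seq_along(delta) else
    which(time <= until)
  pk <- search[which.max(abs(delta[search]))]
  list(time = time, delta_activity = delta, baseline_value = baseline,
       peak_change = abs(delta[pk]), peak_change_signed = delta[pk],
       time_of_peak = time[pk])
}

#' Purkinje-population encoding of saccade kinematics
#'
#' For each target, simulates a trial, baseline-subtracts the selected
#' Purkinje-layer population trace (baseline = mean over the first 20 ms,
#' before the mossy-fiber buildup), and extracts the peak change and its
#' time (restricted to before the hold cutoff). Ordinary least squares
#' then relates the peak change to the trial's peak eye speed and to its
#' amplitude. In the model the ipsilateral layer is the population whose
#' climbing-fiber tuning is opposite to the movement direction (CS-off),
#' the contralateral layer the CS-on one.
#'
#' @param config,weights model and trained weights.
#' @param targets at least 3 target displacements (deg).
#' @param side `"ipsi"` (CS-off, default) or `"contra"` (CS-on).
#' @return a list: `per_target` data frame (peak change, its time, peak
#'   speed and its time, amplitude), `traces` (one baseline-subtracted
#'   population trace per target), `fit_speed` and `fit_amplitude` (each
#'   `list(slope, intercept, r_squared)`), and `side`.
#' @export
pc_encoding_analysis <- function(config, weights, targets = seq(4, 20, by = 2),
                                 side = c("ipsi", "contra")) {
  side <- match.arg(side)
  signal_name <- paste0("y_pc_", side)
  rows <- list()
  traces <- list()
  for (tg in targets) {
    tr <- simulate_trial(config, weights, tg, record = FALSE)
    m <- saccade_metrics(tr)
    if (m$degenerate) next
    pt <- population_trace(tr$time, tr[[signal_name]], until = tr$hold_time)
    traces[[as.character(tg)]] <- pt
    rows[[as.character(tg)]] <- data.frame(
      target = tg, peak_change = pt$peak_change,
      time_of_peak_pc = pt$time_of_peak,
      peak_speed = m$peak_speed, time_of_peak_speed = m$time_of_peak_speed,
      amplitude = m$amplitude)
  }
  if (length(rows) < 3L) {
    stop("fewer than 3 non-degenerate trials; cannot fit the encoding relation")
  }
  per_target <- do.call(rbind, rows)
  ols <- function(x, y) {
    fit <- stats::lm(y ~ x)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared)
  }
  list(per_target = per_target, traces = traces,
       fit_speed = ols(per_target$peak_speed, per_target$peak_change),
       fit_amplitude = ols(per_target$amplitude, per_target$peak_change),
       side = side)
}

# first above/below-baseline excursion ordering of a baseline-subtracted
# trace; excursions smaller than frac * max|delta| are ignored
excursion_pattern <- function(delta, frac = 0.05) {
  eps <- frac * max(abs(delta))
  first_pos <- which(delta > eps)[1]
  first_neg <- which(delta < -eps)[1]
  if (is.na(first_pos) && is.na(first_neg)) return("flat")
  if (is.na(first_neg) || (!is.na(first_pos) && first_pos < first_neg)) {
    "positive_first"
  } else {
    "negative_first"
  }
}

#' Fastigial burst-pause pattern analysis
#'
#' Baseline-subtracts the bilateral fastigial traces (baseline = resting
#' value over the first 20 ms) and classifies each side's excursion
#' order. Post-adaptation, the contralateral nucleus should burst before
#' it pauses (drive then release) and the ipsilateral nucleus pause
#' before it bursts (release then brake), with the early-phase magnitude
#' growing with target size. The early phase is a fixed peri-onset
#' window (10 ms before to 15 ms after the detected movement onset),
#' where the movement-related discharge is concentrated.
#'
#' @param config,weights model and trained weights.
#' @param targets target displacements (deg).
#' @return a list: `per_target` data frame with the pattern labels
#'   (`contra_pattern`, `ipsi_pattern`), early-phase peak magnitudes
#'   (`contra_early_peak`, `ipsi_early_peak`), and the boolean
#'   `contra_burst_before_pause` / `ipsi_pause_before_burst`; plus the
#'   baseline-subtracted `traces` per target and side.
#' @export
cfn_pattern_analysis <- function(config, weights, targets = seq(5, 20, by = 3)) {
  rows <- list()
  traces <- list()
  for (tg in targets) {
    tr <- simulate_trial(config, weights, tg, record = FALSE)
    until <- if (is.na(tr$hold_time)) max(tr$time) else tr$hold_time
    keep <- tr$time <= until
    pt_c <- population_trace(tr$time[keep], tr$ycfn_contra[keep])
    pt_i <- population_trace(tr$time[keep], tr$ycfn_ipsi[keep])
    pat_c <- excursion_pattern(pt_c$delta_activity)
    pat_i <- excursion_pattern(pt_i$delta_activity)
    onset <- if (is.na(tr$onset_time)) cfg_onset_fallback(tr) else tr$onset_time
    early <- tr$time[keep] >= onset - 0.010 & tr$time[keep] <= onset + 0.015
    traces[[as.character(tg)]] <- list(contra = pt_c, ipsi = pt_i)
    rows[[as.character(tg)]] <- data.frame(
      target = tg,
      contra_pattern = pat_c, ipsi_pattern = pat_i,
      contra_burst_before_pause = pat_c == "positive_first",
      ipsi_pause_before_burst = pat_i == "negative_first",
      contra_early_peak = max(pt_c$delta_activity[early]),
      ipsi_early_peak = max(-pt_i$delta_activity[early]))
  }
  list(per_target = do.call(rbind, rows), traces = traces)
}

cfg_onset_fallback <- function(tr) tr$config$t_on

# contiguous excess of one speed trace over a reference after a given
# time; a bulge needs a run of at least min_width seconds
late_bulge <- function(time, speed, reference_speed, after_time,
                       min_width = 0.005, tol = 1e-9) {
  sel <- time > after_time
  excess <- (speed - reference_speed) > tol
  runs <- rle(sel & excess)
  dt <- time[2] - time[1]
  any(runs$values & runs$lengths * dt >= min_width - 1e-12)
}

#' Variability-compensation experiment
#'
#' Probes whether the trained vermis compensates online for a reduced
#' burst amplitude (a drop in motivational drive) without any further
#' learning. Three trials are run at the same target: (a) unperturbed,
#' (b) perturbed with the vermal loop intact, and (c) perturbed with the
#' vermal output clamped to the replayed time course of trial (a), i.e. a
#' vermis blind to the perturbation. For (b) and (c) the dysmetria
#' (absolute endpoint error), the percent reduction in peak speed
#' relative to (a), and the presence of a late corrective bulge are
#' reported. A bulge is a contiguous window of at least 5 ms, after the
#' perturbed trial's peak speed, in which the trial's speed exceeds the
#' clamped trace - the signature of the late vermal correction.
#'
#' @param config,weights model and trained weights.
#' @param target target displacement (deg).
#' @param burst_reduction fractional reduction of the burst amplitude in
#'   (0, 1); the perturbed trials run at `motivation_scale =
#'   1 - burst_reduction`.
#' @return a list with elements `intact` and `clamped`, each
#'   `list(dysmetria, peak_speed_reduction_pct, late_bulge_present,
#'   endpoint_error)`, plus `normal_peak_speed`, `target`,
#'   `burst_reduction`, and the three trial records (`trial_normal`,
#'   `trial_intact`, `trial_clamped`).
#' @export
variability_experiment <- function(config, weights, target = 15,
                                   burst_reduction = 0.16) {
  stopifnot(burst_reduction >= 0, burst_reduction < 1)
  scale <- 1 - burst_reduction
  tr_a <- simulate_trial(config, weights, target, motivation_scale = 1,
                         record = FALSE)
  tr_b <- simulate_trial(config, weights, target, motivation_scale = scale,
                         record = FALSE)
  tr_c <- simulate_trial(config, weights, target, motivation_scale = scale,
                         clamp_yc = tr_a$y_c, record = FALSE)
  m_a <- saccade_metrics(tr_a)
  m_b <- saccade_metrics(tr_b)
  m_c <- saccade_metrics(tr_c)
  summarize <- function(tr, m) {
    list(
      dysmetria = abs(m$endpoint_error),
      endpoint_error = m$endpoint_error,
      peak_speed_reduction_pct = 100 * (1 - m$peak_speed / m_a$peak_speed),
      late_bulge_present = late_bulge(tr$time, tr$theta_dot, tr_c$theta_dot,
                                      after_time = m$time_of_peak_speed)
    )
  }
  list(intact = summarize(tr_b, m_b),
       clamped = summarize(tr_c, m_c),
       normal_peak_speed = m_a$peak_speed,
       normal_endpoint_error = m_a$endpoint_error,
       target = target, burst_reduction = burst_reduction,
       trial_normal = tr_a, trial_intact = tr_b, trial_clamped = tr_c)
}
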