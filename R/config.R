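#' Default model configuration
#'
#' Returns the full parameter set of the saccade control loop: brainstem
#' burst generator, displacement integrator, bilateral cerebellar vermis,
#' oculomotor plant, and the numerical settings of the fixed-step
#' integration.
#'
#' The physiological constants follow the monkey oculomotor literature:
#' burst amplitude `A` = 1100 Hz with slope constant `sigma` = 16 and an
#' imperfect displacement-integrator gain `k` = 0.72; a second-order
#' overdamped plant `k1` = 0.003 s^2, `k2` = 0.6 s, `k3` = 4; mossy-fiber
#' target gain `lam` = 2 Hz/deg with a 15 ms pre-movement buildup spread
#' `alpha`; granular-layer time constant `tau` = 20 ms and spectral radius
#' `rho` = 0.5; Purkinje-to-fastigial strength 20 on both sides and
#' fastigial responsibility gains `r1` = 0.02, `r2` = -0.02; weight
#' regularization `gamma` = 1e-4.
#'
#' @return An object of class `omv_config` (a named list). Fields:
#' \describe{
#'   \item{A}{burst-generator amplitude (Hz).}
#'   \item{k}{displacement-integrator gain, in \[0, 1\].}
#'   \item{sigma}{burst-generator slope constant (drive units).}
#'   \item{k1, k2, k3}{plant coefficients (s^2, s, dimensionless).}
#'   \item{lam}{target mossy-fiber gain (Hz per degree).}
#'   \item{alpha}{target mossy-fiber buildup spread (s).}
#'   \item{rho}{reservoir spectral radius, in (0, 1].}
#'   \item{tau}{granule-cell time constant (s).}
#'   \item{r1, r2}{contra/ipsi fastigial responsibility gains.}
#'   \item{w_pc_cfn_contra, w_pc_cfn_ipsi}{Purkinje-to-fastigial strengths.}
#'   \item{w_mf_cfn_contra, w_mf_cfn_ipsi}{mossy-fiber-to-fastigial strengths.}
#'   \item{gamma}{weight-regularization coefficient of the learning cost.}
#'   \item{N}{granule units per side.}
#'   \item{recurrent_density}{fraction of nonzero recurrent connections.}
#'   \item{f_max}{saturation level of the granule activation function.}
#'   \item{dt}{integration step (s).}
#'   \item{trial_duration}{total simulated time per trial (s).}
#'   \item{cutoff_after_onset}{eye-hold switch delay after movement onset (s).}
#'   \item{t_on}{movement-initiation time within the trial (s).}
#'   \item{onset_speed_threshold}{speed criterion for movement onset (deg/s).}
#'   \item{seed}{default RNG seed for weight initialization.}
#' }
#' @seealso [validate_config()], [load_config()], [init_weights()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$k
#' cfg$r2
default_config <- function() {
  cfg <- list(
    A = 1100,
    k = 0.72,
    sigma = 16,
    k1 = 0.003,
    k2 = 0.6,
    k3 = 4,
    lam = 2,
    alpha = 0.015,
    rho = 0.5,
    tau = 0.020,
    r1 = 0.02,
    r2 = -0.02,
    w_pc_cfn_contra = 20,
    w_pc_cfn_ipsi = 20,
    w_mf_cfn_contra = 0.5,
    w_mf_cfn_ipsi = 0.5,
    gamma = 1e-4,
    N = 50L,
    recurrent_density = 0.1,
    f_max = 1,
    dt = 1e-3,
    trial_duration = 0.4,
    cutoff_after_onset = 0.150,
    t_on = 0.050,
    onset_speed_threshold = 30,
    seed = 1L
  )
  class(cfg) <- "omv_config"
  cfg
}

#' Validate a model configuration
#'
#' Checks the structural invariants of an [default_config()] object:
#' positivity of `A`, `sigma`, `tau`, `dt`, `k` within \[0, 1\], `rho`
#' within (0, 1\], `dt < tau`, at least one granule unit, connection
#' density in (0, 1\], and a trial long enough to contain the
#' movement-initiation time plus the hold cutoff.
#'
#' @param cfg an `omv_config` object (or a plain named list with the same
#'   fields).
#' @return `cfg`, invisibly, with class `omv_config`; errors on the first
#'   violated invariant, naming the offending field.
#' @export
validate_config <- function(cfg) {
  expected <- names(default_config())
  unknown <- setdiff(names(cfg), expected)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(expected, names(cfg))
  if (length(missing) > 0L) {
    stop("missing configuration key(s): ", paste(missing, collapse = ", "))
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid configuration: ", msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in expected) chk(num1(cfg[[f]]), paste0(f, " must be a finite scalar"))
  chk(cfg$A > 0, "A must be > 0")
  chk(cfg$sigma > 0, "sigma must be > 0")
  chk(cfg$k >= 0 && cfg$k <= 1, "k must lie in [0, 1]")
  chk(cfg$tau > 0, "tau must be > 0")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(cfg$dt < cfg$tau, "dt must be smaller than tau")
  chk(cfg$N >= 1, "N must be >= 1")
  chk(cfg$rho > 0 && cfg$rho <= 1, "rho must lie in (0, 1]")
  chk(cfg$recurrent_density > 0 && cfg$recurrent_density <= 1,
      "recurrent_density must lie in (0, 1]")
  chk(cfg$f_max > 0, "f_max must be > 0")
  chk(cfg$alpha > 0, "alpha must be > 0")
  chk(cfg$trial_duration >= cfg$t_on + cfg$cutoff_after_onset,
      "trial_duration must be >= t_on + cutoff_after_onset")
  chk(cfg$onset_speed_threshold > 0, "onset_speed_threshold must be > 0")
  cfg$N <- as.integer(cfg$N)
  class(cfg) <- "omv_config"
  invisible(cfg)
}

#' Load a configuration from a YAML or JSON file
#'
#' Reads a flat key/value document, fills every omitted key from
#' [default_config()], rejects unknown keys, and validates the result.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file. An empty document
#'   yields the default configuration.
#' @return a validated `omv_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (length(vals) > 0L && is.null(names(vals))) {
    stop("configuration file must be a mapping of key: value pairs")
  }
  cfg <- default_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  validate_config(cfg)
  cfg
}

#' Write a configuration to disk
#'
#' Serializes with full numeric precision so that a write/load round trip
#' reproduces every field exactly.
#'
#' @param cfg an `omv_config`.
#' @param path output path; format chosen by extension (`.json` or YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                         digits = I(17))
  } else {
    yaml::write_yaml(unclass(cfg), path, precision = 17L)
  }
  invisible(path)
}

#' @export
print.omv_config <- function(x, ...) {
  cat("<omv_config>\n")
  cat(sprintf("  burst: A=%g Hz, sigma=%g, k=%g\n", x$A, x$sigma, x$k))
  cat(sprintf("  plant: k1=%g, k2=%g, k3=%g\n", x$k1, x$k2, x$k3))
  cat(sprintf("  vermis: N=%d/side, tau=%g s, rho=%g, density=%g\n",
              x$N, x$tau, x$rho, x$recurrent_density))
  cat(sprintf("  trial: dt=%g s, duration=%g s, t_on=%g s, cutoff=%g s\n",
              x$dt, x$trial_duration, x$t_on, x$cutoff_after_onset))
  invisible(x)
}
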