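#' Initialize the network weight containers
#'
#' Draws the fixed random connectivity of the bilateral granular layer and
#' allocates the plastic parallel fiber to Purkinje cell readout vectors.
#' Per side:
#' \itemize{
#'   \item `w_mf_grc` (N x 2): mossy-fiber projections onto granule units,
#'     uniform on \[-30, 30\] (one column per mossy-fiber channel:
#'     target, burst efference copy).
#'   \item `w_rec` (N x N): sparse nonnegative recurrent strengths, drawn
#'     uniform on \[0, 0.2\] at density `recurrent_density`, then rescaled
#'     so the spectral radius is exactly 1. The recurrent term enters the
#'     granule dynamics with a minus sign, so these connections are
#'     inhibitory despite the nonnegative entries, and `rho * w_rec` has
#'     spectral radius `rho`.
#'   \item `w_pf_pc` (length N): plastic readout weights, initialized to 0.
#' }
#'
#' The draw is fully determined by `seed` (the global RNG state is left
#' untouched), and the seed is stored in the returned object: the random
#' structure is part of the model identity.
#'
#' @param config a validated [default_config()] object.
#' @param seed integer seed for the weight draw; defaults to `config$seed`.
#' @return an object of class `omv_weights` with fields
#'   `w_mf_grc_contra`, `w_mf_grc_ipsi`, `w_rec_contra`, `w_rec_ipsi`,
#'   `w_pf_pc_contra`, `w_pf_pc_ipsi`, and `seed`.
#' @export
#' @examples
#' w <- init_weights(default_config(), seed = 7)
#' max(Mod(eigen(w$w_rec_contra, only.values = TRUE)$values))  # 1
init_weights <- function(config, seed = config$seed) {
  config <- validate_config(config)
  N <- config$N
  density <- config$recurrent_density
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  draw_side <- function() {
    w_mf <- matrix(stats::runif(2L * N, -30, 30), nrow = N, ncol = 2L)
    w_rec <- draw_recurrent(N, density)
    list(w_mf = w_mf, w_rec = w_rec)
  }
  contra <- draw_side()
  ipsi <- draw_side()
  w <- list(
    w_mf_grc_contra = contra$w_mf,
    w_mf_grc_ipsi = ipsi$w_mf,
    w_rec_contra = contra$w_rec,
    w_rec_ipsi = ipsi$w_rec,
    w_pf_pc_contra = numeric(N),
    w_pf_pc_ipsi = numeric(N),
    seed = as.integer(seed)
  )
  class(w) <- "omv_weights"
  w
}

# Sparse nonnegative recurrent matrix normalized to unit spectral radius.
# A very sparse draw can be nilpotent (spectral radius 0); redraw in that
# case so normalization is well defined.
draw_recurrent <- function(N, density, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    mask <- matrix(stats::runif(N * N) < density, N, N)
    w <- matrix(stats::runif(N * N, 0, 0.2), N, N) * mask
    sr <- max(Mod(eigen(w, only.values = TRUE)$values))
    if (sr > 1e-10) return(w / sr)
  }
  stop("recurrent matrix has zero spectral radius after ", max_tries,
       " draws; increase N or recurrent_density")
}

#' Validate a weight container against a configuration
#'
#' @param weights an `omv_weights` object.
#' @param config the configuration it must match (dimension `N`).
#' @return `weights`, invisibly; errors on dimension mismatch.
#' @export
validate_weights <- function(weights, config) {
  N <- config$N
  dims_ok <- identical(dim(weights$w_rec_contra), c(N, N)) &&
    identical(dim(weights$w_rec_ipsi), c(N, N)) &&
    identical(dim(weights$w_mf_grc_contra), c(N, 2L)) &&
    identical(dim(weights$w_mf_grc_ipsi), c(N, 2L)) &&
    length(weights$w_pf_pc_contra) == N &&
    length(weights$w_pf_pc_ipsi) == N
  if (!dims_ok) {
    stop("weight dimensions do not match config N = ", N)
  }
  if (min(weights$w_rec_contra) < 0 || min(weights$w_rec_ipsi) < 0) {
    stop("recurrent weights must be nonnegative")
  }
  invisible(weights)
}

#' Write network weights to a JSON container
#'
#' One entry per array plus the generating seed, written at full numeric
#' precision so that write/read round trips are exact.
#'
#' @param weights an `omv_weights` object.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  payload <- list(
    seed = weights$seed,
    w_mf_grc_contra = weights$w_mf_grc_contra,
    w_mf_grc_ipsi = weights$w_mf_grc_ipsi,
    w_rec_contra = weights$w_rec_contra,
    w_rec_ipsi = weights$w_rec_ipsi,
    w_pf_pc_contra = weights$w_pf_pc_contra,
    w_pf_pc_ipsi = weights$w_pf_pc_ipsi
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read network weights from a JSON container
#'
#' @param path path written by [write_weights()].
#' @return an `omv_weights` object.
#' @export
read_weights <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- list(
    w_mf_grc_contra = as.matrix(p$w_mf_grc_contra),
    w_mf_grc_ipsi = as.matrix(p$w_mf_grc_ipsi),
    w_rec_contra = as.matrix(p$w_rec_contra),
    w_rec_ipsi = as.matrix(p$w_rec_ipsi),
    w_pf_pc_contra = as.numeric(p$w_pf_pc_contra),
    w_pf_pc_ipsi = as.numeric(p$w_pf_pc_ipsi),
    seed = as.integer(p$seed)
  )
  for (f in c("w_mf_grc_contra", "w_mf_grc_ipsi",
              "w_rec_contra", "w_rec_ipsi")) {
    dimnames(w[[f]]) <- NULL
    storage.mode(w[[f]]) <- "double"
  }
  class(w) <- "omv_weights"
  w
}

#' @export
print.omv_weights <- function(x, ...) {
  N <- length(x$w_pf_pc_contra)
  cat("<omv_weights>\n")
  cat(sprintf("  N = %d granule units per side (seed %d)\n", N, x$seed))
  cat(sprintf("  recurrent nonzeros: contra %d, ipsi %d\n",
              sum(x$w_rec_contra != 0), sum(x$w_rec_ipsi != 0)))
  cat(sprintf("  |w_pf_pc|: contra %.4g, ipsi %.4g\n",
              sqrt(sum(x$w_pf_pc_contra^2)), sqrt(sum(x$w_pf_pc_ipsi^2))))
  invisible(x)
}
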