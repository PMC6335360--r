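#' Ready-made configuration/weight fixtures
#'
#' Deterministic model instances for examples and tests. `"tiny"` is a
#' deliberately small, fast instance (10 granule units per side, 2 ms
#' steps, denser recurrence so the sparse draw stays non-degenerate);
#' `"default"` is the full configuration of [default_config()].
#'
#' @param kind `"tiny"` or `"default"`.
#' @param seed seed for the weight draw.
#' @return `list(config = <omv_config>, weights = <omv_weights>)`.
#' @export
make_fixture <- function(kind = c("tiny", "default"), seed = 42L) {
  kind <- match.arg(kind)
  cfg <- default_config()
  if (kind == "tiny") {
    cfg$N <- 10L
    cfg$dt <- 2e-3
    cfg$recurrent_density <- 0.3
  }
  cfg$seed <- as.integer(seed)
  cfg <- validate_config(cfg)
  list(config = cfg, weights = init_weights(cfg, seed = seed))
}
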