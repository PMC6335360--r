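# Shared fixtures. The tiny instance is used by most unit tests; the
# trained full-size model is expensive, so it is built lazily once per
# test run and shared across test files.

tiny_fixture <- function(seed = 42L) make_fixture("tiny", seed = seed)

.omv_test_cache <- new.env(parent = emptyenv())

# Full-size model trained under the study conditions (random targets
# 4-20 deg, default configuration); cached for the whole test run.
trained_model <- function() {
  if (is.null(.omv_test_cache$trained)) {
    fx <- make_fixture("default", seed = 1L)
    .omv_test_cache$trained <- train_omv(fx$config, fx$weights, seed = 1L)
  }
  .omv_test_cache$trained
}

# Build a minimal trial-record stub with known kinematics, for metric
# oracles that need exact analytic crossings.
stub_record <- function(time, theta, theta_dot, target,
                        threshold = 30) {
  cfg <- default_config()
  cfg$onset_speed_threshold <- threshold
  structure(list(time = time, theta = theta, theta_dot = theta_dot,
                 target = target, config = cfg),
            class = "omv_trial")
}
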