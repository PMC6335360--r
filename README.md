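# omvsim

Rate-based simulation of how the cerebellar oculomotor vermis (OMV)
keeps saccadic eye movements accurate. Saccades are executed without
visual feedback, so endpoint control must rely on internal signals:
a brainstem burst generator wrapped in a local displacement-integrator
feedback loop produces the velocity command, and the vermis — driven by
mossy-fiber copies of the target command and of the burst itself —
learns to inject online gain corrections through the caudal fastigial
nuclei. The package is for computational and systems neuroscientists
who want a tested, scriptable implementation of this closed loop: the
trained model reproduces main-sequence kinematics, speed encoding in
the Purkinje-cell population response, fastigial burst–pause patterns,
and online compensation for burst-amplitude variability.

## The model

Burst generation with internal feedback (all trials rightward,
1 Hz ≡ 1°):

    u(t) = A · s · (1 − exp(−(y_c + y_d − k∫u dt) / σ)),  rectified at 0

where `y_d` is the collicular step command, `y_c` the net cerebellar
correction, `k < 1` the imperfect displacement-integrator gain, and `s`
a motivation scale on the burst amplitude `A`. The eye plant is the
overdamped second-order system `k₁θ̈ + k₂θ̇ + k₃θ = u(t)`, integrated by
exact zero-order-hold discretization.

Each side of the vermis holds `N` granule rate units
(`τ ż = −z + f(W_mf m − ρ W z)`, sparse nonnegative `W` normalized to
unit spectral radius) feeding a Purkinje population readout
`y_pc = w_pf_pc · z` — the only plastic weights. Fastigial nuclei
combine PC inhibition with burst excitation,
`y_cfn = −w_pc_cfn · y_pc + w_mf_cfn · u`, and
`y_c = r₁ y_cfn_contra + r₂ y_cfn_ipsi`. Training minimizes the
cumulative gaze error `J = ∫|y_d − θ(t)| dt + γ‖w_pf_pc‖²` over random
targets (4–20°) with finite-difference quasi-Newton descent, until the
endpoint error saturates.

## A first trial

An untrained model (plastic weights at zero) shows the raw
brainstem-only behavior — the eye overshoots the target:

```r
library(omvsim)
cfg   <- default_config()          # Table of loop constants, dt = 1 ms
w     <- init_weights(cfg, seed = 1)
trial <- simulate_trial(cfg, w, target = 15)
saccade_metrics(trial)
#> <omv_metrics> amplitude 15.90 deg, peak 831.4 deg/s @ 0.060 s, duration 56 ms, error -0.896 deg
```

The 15° command lands at 15.9° (a 0.9° overshoot), with a peak speed of
831 deg/s about 10 ms after movement onset and the position held from
the cutoff 150 ms after onset. Training the parallel-fiber weights

```r
fit <- train_omv(cfg, w, seed = 1)   # a few minutes on one core
```

drives held-out endpoint errors below half a degree, after which the
experiment drivers — `main_sequence()`, `pc_encoding_analysis()`,
`cfn_pattern_analysis()`, `variability_experiment()` — characterize the
trained loop. A thin command-line front end with `simulate`, `train`
and `experiment` subcommands is installed under `inst/cli/omvsim`.

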