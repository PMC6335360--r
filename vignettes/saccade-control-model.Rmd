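---
title: "A closed-loop model of cerebellar saccade control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop model of cerebellar saccade control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omvsim)
```

## The control problem

Saccades are ballistic: they are over before visual feedback could steer
them, so accuracy must come from internal signals. The model simulated
here closes two loops around a grouped brainstem burst generator. The
first is internal to the brainstem: a displacement integrator (DI)
accumulates a scaled copy of the burst command and subtracts it from the
drive, so the burst extinguishes as the estimated displacement
approaches the commanded one. With the physiological integrator gain
below one, this loop alone is inaccurate — the eye overshoots every
target. The second loop is the cerebellar oculomotor vermis (OMV): mossy
fibers carry the target command and an efference copy of the burst into
a granular-layer reservoir, Purkinje-cell (PC) population readouts
project onto the caudal fastigial nuclei (cFN), and the net bilateral
cFN output is fed back into the burst generator as an online gain
correction. Learning in the parallel fiber to PC weights turns this
second loop into the compensator that makes saccades accurate.

## Signal path, step by step

One trial simulates `trial_duration` (0.4 s) at a fixed step `dt`
(1 ms). Per step:

1. **Mossy fibers.** The target channel builds up as a Gaussian with
   spread `alpha` (15 ms) toward its plateau `lam * target`, peaking at
   the movement-initiation time `t_on`; the burst channel relays the
   previous step's burst output (a one-step efference-copy delay that
   avoids an algebraic loop). Both channels are normalized into [0, 1]
   — the target channel by its largest plateau (`lam * 20`), the burst
   channel by the *nominal* amplitude `A`, so that a motivation-scaled
   burst looks genuinely smaller to the vermis.
2. **Granular reservoir.** Each side holds `N` leaky-integrator rate
   units, `tau * dz/dt = -z + S`, rectified at zero, with
   `S = f(W_mf m - rho W z)`: random mossy-fiber weights in [-30, 30],
   sparse nonnegative recurrent weights drawn in [0, 0.2] and rescaled
   to unit spectral radius, and `f` a logistic saturating at `f_max`.
   The minus sign makes the recurrence inhibitory; `rho <= 1` keeps the
   dynamics contracting (the suite verifies boundedness and the echo
   property directly).
3. **Readouts.** Each PC "layer" is the total population projection
   onto one cFN: a single weighted sum of the granule vector. The cFN
   combines PC inhibition with mossy-fiber excitation,
   `y_cfn = -w_pc_cfn y_pc + w_mf_cfn u`, and the net correction is
   `y_c = r1 y_cfn_contra + r2 y_cfn_ipsi` with `r1 = -r2 = 0.02`.
4. **Burst generator.** `u = A s (1 - exp(-(y_c + y_d - D)/sigma))`,
   rectified at zero, where `D` is the DI state and `s` the motivation
   scale. The DI then accumulates `k u dt`.
5. **Plant.** A second-order overdamped plant
   `k1 theta'' + k2 theta' + k3 theta = u` advanced by the exact
   zero-order-hold discretization (matrix exponential precomputed once
   per `dt`), which is unconditionally stable; a forward-Euler stepper
   exists purely as a test oracle.

Two gates bracket the movement. Before `t_on` the omnipause gate keeps
the brainstem silent and the eye still, standing in for the tonic
omnipause hold that is released by the collicular trigger; the vermis,
however, already sees the target buildup. After movement onset —
detected online as the first crossing of 30 deg/s, a standard saccade
criterion — a switch fires `cutoff_after_onset` (150 ms) later, cutting
off the brainstem and all vermal inputs and holding the eye at the
reached position. If the speed never crosses threshold the trial is
flagged degenerate and no hold fires.

## Parameters

The loop constants are the standard monkey oculomotor values: `A` =
1100 Hz, `sigma` = 16, `k` = 0.72, plant coefficients (0.003 s²,
0.6 s, 4), mossy-fiber gain `lam` = 2 Hz/deg, reservoir `tau` = 20 ms
and `rho` = 0.5, PC-to-cFN strength 20 per side, responsibility gains
±0.02, and regularization `gamma` = 1e-4. Choices this package had to
make itself:

* **`alpha` = 15 ms.** A buildup spread on the millisecond-fraction
  scale would be invisible at any feasible step size; 15 ms gives the
  long-lead buildup its intended pre-movement extent.
* **`N` = 50 units per side.** The readout dimension (2N = 100) is
  ample for the smooth one-parameter family of trajectories the model
  must correct, and the derivative-free training cost grows roughly
  with N³ (simulation cost times parameter count). Doubling N changed
  held-out endpoint errors in our exploratory runs far less than the
  seed-to-seed spread.
* **Recurrent density 10%**, a conventional sparse regime for granular
  reservoirs; the tiny test fixture uses 30% so the spectral radius of
  a 10-unit draw stays well defined.
* **`t_on` = 50 ms** into the trial, giving the target buildup room
  before movement; **trial length 0.4 s** with the 150 ms value read as
  the post-onset cutoff delay, so every trial contains its full
  movement and hold phase.
* **`w_mf_cfn` = 0.5** per side. Only the PC-to-cFN strength is
  constrained by the literature; the mossy-fiber collateral strength is
  a calibration constant that shapes the displayed cFN traces (with
  symmetric values it cancels exactly out of `y_c`, so the loop is
  insensitive to it).
* **Motivation scale multiplies `A`** and nothing else; reduced drive
  reaches the vermis only through the efference copy.

Each trial starts from rest: the DI at zero, the eye at zero, and the
granule vectors at their zero-input fixed point `z* = f(-rho W z*)`
(inter-trial intervals are long relative to `tau`). The fixed point is
found by damped iteration and verified in the suite against the
dynamics it is meant to summarize.

## Learning

The criterion is the time integral of absolute gaze error plus a
squared-norm penalty on the plastic weights, evaluated by the
trapezoidal rule so its value is invariant under `dt` refinement.
Training (`train_omv()`) minimizes the mean criterion over batches of
eight targets redrawn uniformly in 4-20 degrees each epoch, using
box-constrained quasi-Newton descent with finite-difference gradients —
the same derivative-free route a standard constrained optimization
toolbox would take. Epochs warm-start
from one another; training stops when the mean absolute endpoint error
on a fixed probe grid has saturated (range below 0.05 degrees over ten
epochs), when the iterate is stationary across three consecutive
batches, or after `max_epochs`. With the defaults a training run is a
few minutes of desk time on one core.

Optionally `tau` and `rho` join the optimized vector, boxed to
[5, 100] ms and (0, 1] and started from the box midpoints. Across most
seeds they converge near 15-20 ms and 0.5; occasionally the search
settles in a second, flatter basin near the `rho` upper bound with a
slow time constant. We report the seed average and note the
multimodality rather than hiding it — the cost surface along these two
coordinates is shallow, and nothing in the criterion forces a unique
reservoir parameterization.

`pc_rate_penalty` adds an optional soft constraint penalizing negative
PC population rates (a population firing rate cannot be negative; the
model family explicitly admits such physiological constraints as cost
terms). It is off by default so that the criterion is exactly the
gaze-error-plus-regularization cost. Enabling it yields nonnegative PC
trajectories and a slightly more linear speed encoding, at the price of
a pre-movement ramp in both readouts (the network builds headroom for
its movement-phase dip), which distorts the fastigial baseline.

## What the experiments measure

* `main_sequence()` tabulates amplitude, peak speed and duration per
  target — the stereotyped saturating speed-amplitude and increasing
  duration-amplitude relations.
* `pc_encoding_analysis()` baseline-subtracts a PC population trace
  (baseline = mean over the first 20 ms, before the buildup), takes the
  peak change before the cutoff, and regresses it against peak speed
  and against amplitude. The ipsilateral layer plays the role of the
  population whose error tuning opposes the movement direction.
* `cfn_pattern_analysis()` classifies each side's baseline-subtracted
  excursion order (burst-before-pause contralaterally,
  pause-before-burst ipsilaterally) and measures the early-phase
  magnitude in a fixed peri-onset window (-10 to +15 ms around onset).
* `variability_experiment()` reduces the burst amplitude (16% by
  default, emulating a drop in motivational drive) and compares an
  intact vermis with one whose output is clamped to the unperturbed
  trial's time course. Reported per condition: dysmetria, percent peak
  speed reduction, and the presence of a late corrective bulge — a
  contiguous window of at least 5 ms, after peak speed, in which the
  condition's speed exceeds the clamped trace.

## Numerical choices and degenerate inputs

Onset detection at 30 deg/s; holds latch once fired; a trial whose
speed never crosses threshold yields degenerate (all-`NA`) metrics
rather than fabricated ones. The compiled simulation loop is mirrored
by a pure-R engine composed of the exported step functions, and the two
are asserted to agree to floating-point accuracy — the compiled path is
an optimization, never a second model. Weight draws are seeded and the
seed is stored in the container: the random structure is part of the
model's identity, and identical seeds reproduce identical arrays.
Configurations and weights serialize to full-precision JSON/YAML so
round trips are exact.

## Known limitations

* **Degenerate readout geometry.** The net correction depends on the
  two PC readouts only through their difference, so the learning
  problem fixes `y_c(t)` but not how the sides share it; the
  regularizer then favors a minimum-norm, antisymmetric split. The
  trained corrector therefore reproduces accurate kinematics, the main
  sequence, the speed-linearity of the PC population response, and the
  contralateral burst-before-pause pattern, but the finer lateralized
  signatures — the ipsilateral pause-before-burst sequence and the PC
  population peak arriving before peak eye speed — depend on which
  solution basin the optimizer lands in and are not reliably
  reproduced by the minimum-norm solution.
* **Endpoint robustness under clamping.** The displacement-integrator
  loop self-corrects the endpoint even when the vermal output is
  replayed, so clamped-output dysmetria under burst reduction is small
  here; a regime in which the replayed correction actively truncates
  the burst would make the clamped endpoint scale with the burst
  amplitude and produce degree-scale dysmetria.
* Only rightward horizontal saccades, one amplitude dimension, no
  spiking dynamics, no Golgi population, no plant adaptation, and no
  multiple adaptation timescales: all are outside this model's scope.
* All experiments run on model-generated trajectories under the
  configured conditions; passing tests show internal consistency of
  the mechanism, not agreement with any particular animal's data.
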