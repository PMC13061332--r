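---
title: "Modelling trial-by-trial adaptation of muscle synergies"
author: "synlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trial-by-trial adaptation of muscle synergies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synlearn)
```

## The model

`synlearn` simulates error-based, trial-by-trial learning of redundant
muscle activity during isometric force reaching. The motor command for a
desired planar force $f^\ast$ is generated through a modular chain:

$$
m(f^\ast) \;=\; W\,Z\,\Phi(f^\ast),
$$

where $\Phi(f^\ast)$ is a vector of $N_\Phi = 121$ Gaussian radial basis
functions on an $11\times11$ grid covering $[-1,1]^2$ of force space,
$Z \ge 0$ ($N \times N_\Phi$) maps features to the recruitment of $N = 5$
spatial muscle synergies, and $W \ge 0$ ($M \times N$, $M = 10$ muscles)
holds the synergy vectors as columns. Signal-dependent motor noise with
standard deviation $c_v$ times each muscle's activation is added and
negative activities are clipped to zero. The environment is a linear map
$f = H\,m$ ($2 \times 10$); perturbations replace $H$ by $R(45^\circ)H$
(visuomotor rotation) or $H\,T$ (virtual surgery, an orthogonal rotation
of muscle space).

The learner holds an internal forward model $\hat H$ of the environment.
After each trial, the force error $\delta f = f - f^\ast$ is
backpropagated through $\hat H$ to update the controller:

$$
\Delta W = -\eta_W\,\hat H^{\mathsf T}\delta f\,\Phi^{\mathsf T}Z^{\mathsf T}
           - \lambda_W W,
\qquad
\Delta Z = -\eta_Z\,W^{\mathsf T}\hat H^{\mathsf T}\delta f\,\Phi^{\mathsf T}
           - \lambda_Z Z,
$$

with negative entries clipped to zero after the full increment. The
forward model itself learns from the prediction error
$\delta f_p = \hat H m - f$ of the executed (noisy) pattern:
$\Delta\hat H = -\eta_{\hat H}\,\delta f_p\,m^{\mathsf T}$, unclipped.
Within a trial, $W$ and $Z$ are updated with the forward model available
at trial start; $\hat H$ is updated afterwards, so policy learning never
uses the same trial's prediction error.

## Protocol

A cycle presents the 8 targets (radius 0.5, uniformly spaced) in random
order. A simulated experiment runs 324 unrecorded pre-training cycles in
the baseline environment, then 36 recorded baseline cycles, 36
perturbation cycles and 36 washout cycles with learning on throughout.
Recorded metrics are averaged over 4 repetitions restarting from the
same post-pre-training state under different noise streams; a study runs
16 independent model initializations, each with its own environment,
synergies, and difficulty-matched surgery pair.

Pre-training always uses the default full configuration (both controller
components and the forward model learning, regularization on). A
simulation condition — e.g. "synergies only", "no forward-model update",
"no regularization" — applies from the recorded phases onward. Two
readings of the protocol are possible here; we use this one because a
condition with a frozen policy could never establish the converged
baseline that every published condition starts from, and because it lets
all conditions of one initialization share the identical baseline state,
which is what paired contrasts require.

## Virtual surgeries

From the baseline $H$ and initial synergies $W_0$ we build orthonormal
bases of: the null space of $H$ (dimension 8); $N_c$, the intersection
of the synergy span with the null space (3); $W_{nc}$, the force-producing
complement inside the synergy span (2); and $N_{nc}$, the null directions
unreachable by synergy combinations (5). The incompatible surgery
$T_i$ rotates a random unit vector $w \in \mathrm{span}(W_{nc})$ onto a
random unit vector $n \in \mathrm{span}(N_{nc})$ by their full angle;
this collapses the baseline synergy forces onto a line
($\mathrm{rank}(H T_i W_0) = 1$, zero convex-hull area). The compatible
surgery $T_c$ rotates $w$ within $\mathrm{span}(W_{nc})$ by an angle
found by bisection on $[0^\circ, 120^\circ]$ so that its index of
difficulty — the summed absolute change of minimum-norm non-negative
activations across muscles and targets — matches the incompatible one to
5% (the search stops at 1% so the certificate holds with margin).
Both surgeries leave the individual muscles positively spanning force
space; the same $w$ serves both members of a pair.

The minimum-norm non-negative activation problem
($\min \|m\|$ s.t. $Hm = f$, $m \ge 0$) is solved by eliminating the
equality constraints (the particular solution $H^+f$ is orthogonal to
the null space) and solving the remaining least-distance program through
the classical reduction to non-negative least squares. Tests verify it
against exact active-set enumeration on small instances.

## Tunable parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `eta_Z`, `eta_W` | policy / synergy learning rates | 0.05 | 1/trial |
| `eta_Hhat` | forward-model learning rate | 0.25 | 1/trial |
| `lambda_Z`, `lambda_W` | effort regularization | 1% of the rate | 1/trial |
| `cv` | motor-noise coefficient (sd/activation) | 0.1 | unitless |
| `width` | RBF width $\sigma$ | 0.25 | force units |
| `z_init_max` | upper bound of the uniform $Z_0$ init | 0.05 | — |
| `hhat_init_max` | upper bound of the uniform $\hat H_0$ init | 0 | — |

Learning rates, regularization weights, the $Z_0$ scale, grid geometry,
target geometry and phase lengths follow the published study design.
Three parameters the study leaves open were calibrated once, on
stability and convergence evidence only, and then frozen:

* **Forward-model initialization** $\hat H_0 = 0$. An all-positive random
  initialization backpropagates errors with a systematic wrong sign
  before the forward model has learned anything, and occasionally drives
  the command norms past the stability bound of the $\hat H$ update
  (which requires $\eta_{\hat H}\|m\|^2 < 2$), after which the learner
  collapses irrecoverably. Starting from zero means the controller does
  not move until the forward model has learned from prediction errors —
  the natural reading of a map that is not known a priori.
* **RBF width** $\sigma = 0.25$ (1.25 grid spacings). The learning gain
  of the policy loop scales with $\|\Phi\|^2$. At $\sigma = 0.2$ the
  gradient reaching targets that sit between synergy force directions is
  too weak to overcome the regularization decay, and a fifth to a third
  of initializations never converge during pre-training; at
  $\sigma \ge 0.3$ the loop gain crosses its stability threshold when
  command norms grow under a virtual surgery and runs diverge. 0.25 is
  the regime in which every initialization converges and every standard
  condition is stable.
* **Noise coefficient** $c_v = 0.1$, a typical coefficient of variation
  for motor output; `cv = 0` gives the deterministic variant.

## Generator conditioning

The environment generator draws muscle force directions uniformly on the
circle with norms uniform on $[0.5, 1.5]$ and requires positive span.
Two conditioning margins are added, both chosen from failure analysis
before any outcome comparisons and then frozen:

* the largest angular gap between adjacent muscle directions must be
  below $150^\circ$, and every target's minimum-norm activation norm
  must be at most 0.9. Near-degenerate spanning sets need activations an
  order of magnitude above the force norms (observed: norms of 10-30),
  which immediately violates the forward-model stability bound.
* the synergy-defining force directions must have gaps below
  $120^\circ$: with non-negative recruitment, a target inside a wide gap
  is reachable only by ill-conditioned cancellation between the flanking
  synergies, and the baseline then cannot converge within the fixed
  324-cycle pre-training.

What the generator emulates is the *geometry* of an isometric
force task: linear activation-to-force, redundant muscles, low-dimensional
synergy structure, signal-dependent noise. It does not emulate
musculotendon dynamics, within-trial time courses, feedback corrections,
co-varying noise between muscles, or the estimation noise of synergies
identified from EMG — so passing tests support conclusions about the
learning architecture, not about any of those aspects of real data.

## Numerical choices and degenerate inputs

* Orthonormal bases come from singular value decompositions with a
  $10^{-10}$ relative tolerance; the four subspace projections then close
  pythagorically to $10^{-8}$ on every trial, which the tests assert.
* The reconstruction $R^2$ of a cycle pools non-negative least-squares
  residuals over the 8 trials and takes total variation about the
  cycle's mean pattern (`center = FALSE` gives the uncentered variant).
* Convex-hull areas use the hull of the synergy force endpoints (the
  origin is not added as a vertex), after normalizing synergies to unit
  norm, scaled by the same construction on the individual muscle forces;
  collinear sets return exactly zero.
* Undefined metrics (zero executed force, rank-zero synergy snapshots)
  propagate as `NA` and are excluded from cycle averages, never imputed.
* Learning with a badly wrong forward model (the frozen-teacher
  condition under an incompatible surgery) is genuinely unstable:
  commands grow without bound, as the growing error and activity norms
  in that condition indicate. When a command norm crosses 50 the learner
  is frozen for the remainder of the phase, so the runaway is recorded
  as a large finite error plateau rather than a floating-point overflow.
  No standard condition ever approaches this bound.
* The rotation-onset measurement (45° check) runs its measured cycle
  with learning rates zero on a copy of the converged learner: with
  learning on, later trials of the first cycle already adapt and the
  cycle mean understates the onset error by several degrees. Noise-free
  pre-training occasionally plateaus above the 1° convergence criterion
  (no exploration); the measurement then resamples the initialization
  stream, since it is defined conditional on a converged baseline.

## Worked example

```{r example, eval = FALSE}
fit <- adapt_synergies("incompatible", seed = 1, cv = 0.1)
print(fit)
summary(fit)
plot(fit)
coef(fit)$W          # learned synergies after washout
```

Batches reproduce the three study designs:

```{r batch, eval = FALSE}
b <- run_batch(simulation = 3, n_init = 16, seed = 1)
final_perturbation_cycle(b)   # per-init values for paired contrasts
tidy_results(b)               # long table for mixed-model analysis
```

## Problem sizes used by the tests

Unit and property tests run on small instances (M of 4-6 for oracles,
smoke schedules of 3-8 cycles per phase). The end-to-end scientific
checks and the acceptance script run the full study design — 16
initializations, 4 repetitions, 324 pre-training cycles and 36/36/36
recorded cycles — for the simulation grids they need; the
noise-coefficient sensitivity check runs at 2 initializations and 2
repetitions, a scale we consider sufficient for a finiteness check but
not for effect-size estimation.

## Known limitations

* The regularization contrasts are small differences between noisy
  endpoint metrics; with 16 initializations their Monte-Carlo error is
  of the same order as the effects themselves.
* A single fixed number of synergies; no fractionation or merging.
* Fixed learning rates; no adaptation of rates to feedback uncertainty.
* No within-trial dynamics or online corrections; the model generates
  one feedforward pattern per trial.
* Surgeries are built from the ground-truth synergies, not from
  synergies estimated from simulated EMG; the estimation step of the
  experimental procedure is out of scope.
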