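# synlearn

Trial-by-trial learning of muscle synergies for isometric force control.

## What it is for

How does the nervous system learn *new* muscle activity patterns, rather
than just re-weighting the ones it already has? `synlearn` implements a
computational model for studying that question in simulated isometric
force-reaching: feedforward muscle activity is generated by a modular
controller built on spatial muscle synergies, and every stage of the
controller — the synergy structure, its recruitment policy, and an
internal forward model of the muscle-to-force map — is updated trial by
trial from movement errors. The package is aimed at computational motor
control researchers who want to simulate, perturb, and analyze such
modular learners under visuomotor rotations and "virtual surgery"
perturbations that re-map muscle pulling directions.

## The model

A desired planar force f\* is mapped to a muscle pattern through

    m(f*) = W Z Φ(f*),        f = H m

with Φ a 121-element Gaussian radial-basis feature vector (11×11 grid on
[-1,1]²), Z ≥ 0 the recruitment policy of N = 5 synergies, W ≥ 0 the
M = 10-muscle synergy matrix, and H the 2×10 linear environment.
Signal-dependent noise (sd = cv × activation) perturbs the command.
Learning backpropagates the force error δf = f − f\* through the
learner's own estimate Ĥ of the environment:

    ΔW = −η_W Ĥᵀ δf Φᵀ Zᵀ − λ_W W
    ΔZ = −η_Z Wᵀ Ĥᵀ δf Φᵀ − λ_Z Z      (negative entries clipped to 0)
    ΔĤ = −η_Ĥ (Ĥm − f) mᵀ

Virtual surgeries are orthogonal rotations T of muscle space built from
the null space of H and the span of the baseline synergies: compatible
surgeries (H T_c) leave the synergy forces spanning the force plane,
incompatible ones (H T_i) collapse them onto a line, and the pair is
matched on an index of difficulty (summed change in minimum-norm
non-negative activations across the 8 targets). The standard protocol is
324 pre-training cycles, then 36 baseline / 36 perturbation / 36 washout
cycles (8 targets per cycle), 4 noise repetitions, 16 model
initializations.

## Worked example

```r
library(synlearn)
fit <- adapt_synergies("incompatible", seed = 1, cv = 0.1)
print(fit)
#> Simulated synergy adaptation (incompatible)
#>   dims: D=2 M=10 N=5 NPhi=121
#>   phases (cycles): pretrain=324, baseline=36, perturbation=36, washout=36; reps=4; cv=0.1
#>   baseline     final cycle: dir err   5.98 deg, mag err  0.082, R2 0.988
#>   perturbation final cycle: dir err  13.03 deg, mag err  0.191, R2 0.356
#>   washout      final cycle: dir err  15.75 deg, mag err  0.139, R2 0.439
```

After 36 cycles under an incompatible surgery the direction error is
still well above baseline (13° vs 6°) — incompatible re-mappings are
learned slowly — and the ability of the *baseline* synergies to
reconstruct the ongoing muscle activity has collapsed (R² 0.99 → 0.36
for this initialization), the signature of genuinely new muscle
patterns. The structural change persists through washout: R² stays low
and the errors do not fully return to baseline, because the
reorganized, larger-norm commands carry more signal-dependent noise.
Compare `adapt_synergies("compatible", ...)`, which adapts within a few
cycles with a modest R² decline. Across 16 initializations the final
incompatible-cycle direction error averages ~29° against ~6° for
compatible surgeries (see the batch interface below). `summary()`, `plot()`, `coef()`,
`predict()`, `residuals()` and `simulate()` work as usual for fitted
models; `run_batch(simulation = 1:3)` reproduces the full condition
grids (which components learn, forward-model variants, regularization
on/off) and `tidy_results()` emits a long table ready for mixed-model
post-hoc analysis.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/synlearn.R simulate -c config.yml -p incompatible -o results/
Rscript inst/cli/synlearn.R batch --preset sim3 -o results/
```

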