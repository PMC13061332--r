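Package: synlearn
Title: Trial-by-Trial Learning of Muscle Synergies for Isometric Force Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator of trial-by-trial, error-based motor learning in a modular
    muscle-synergy architecture. Feedforward muscle activity for isometric force
    targets is generated by a radial-basis-function control policy recruiting
    non-negative spatial muscle synergies; the policy, the synergies, and an
    internal forward model of the muscle-to-force map are all updated across
    trials by backpropagated force and prediction errors. Implements visuomotor
    rotations and compatible and incompatible virtual-surgery perturbations with
    difficulty matching, the full experimental protocol (pre-training, baseline,
    perturbation, washout over cycles of eight targets), and a metric suite
    covering force errors, synergy reconstruction quality, null-space
    decompositions, convex-hull areas of synergy forces, and principal angles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
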