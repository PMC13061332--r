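## The user-facing "fit": run one simulated adaptation experiment
## (pre-training, baseline, perturbation, washout) and return a classed
## object carrying trial records, per-cycle and per-block metrics, and
## the learned matrices, with the usual methods.

#' Simulate trial-by-trial adaptation of a synergy-based controller
#'
#' Initializes a model (or reuses one), pre-trains it in the baseline
#' environment, then runs the recorded protocol — 36 baseline cycles,
#' 36 perturbation cycles, 36 washout cycles by default, each cycle
#' visiting the 8 targets in random order — with learning on
#' throughout. Recorded metrics are averaged across `n_reps`
#' repetitions that restart from the same post-pre-training state under
#' different motor-noise streams.
#'
#' @param perturbation `"rotation"`, `"compatible"`, `"incompatible"`,
#'   or `"none"`.
#' @param config a [learning_config()].
#' @param seed master seed; all sub-streams (initialization, surgery,
#'   pre-training, repetitions) are derived from it deterministically.
#' @param cv motor-noise coefficient (0 disables noise).
#' @param n_reps repetitions averaged per initialization (default 4).
#' @param cycles named vector of recorded phase lengths.
#' @param pretrain_cycles unrecorded pre-training cycles (default 324).
#' @param pretrain_config learning configuration for pre-training
#'   (default: the full model with regularization, whatever `config`
#'   says; the condition under study applies from the recorded phases
#'   onward).
#' @param model optionally a pre-built [synergy_model()]; when given,
#'   the initialization stream is not consumed.
#' @param surgery_pair optionally a pre-built [build_surgery_pair()]
#'   result (required fields when `perturbation` is a surgery kind).
#' @param keep_records keep per-trial records of every repetition
#'   (default `TRUE`; set `FALSE` in large batches).
#' @return an object of class `synergy_adaptation`.
#' @seealso [run_batch()] for the full simulation grids.
#' @export
adapt_synergies <- function(perturbation = c("rotation", "compatible",
                                             "incompatible", "none"),
                            config = learning_config(), seed = 1,
                            cv = 0.1, n_reps = 4,
                            cycles = c(baseline = 36, perturbation = 36,
                                       washout = 36),
                            pretrain_cycles = 324,
                            pretrain_config = learning_config(),
                            model = NULL, surgery_pair = NULL,
                            keep_records = TRUE) {
  perturbation <- match.arg(perturbation)
  if (is.null(model)) {
    model <- synergy_model(cv = cv, seed = substream_seed(seed, "init"))
  }
  model$cv <- cv
  trained <- pretrain(model, pretrain_config, pretrain_cycles,
                      seed = substream_seed(seed, "pretrain"))
  ## baseline synergies = those in effect at the start of the recorded
  ## phases (the surgery pair and all structure metrics use them)
  if (pretrain_cycles > 0) trained$W0 <- trained$W
  if (perturbation %in% c("compatible", "incompatible") &&
      is.null(surgery_pair)) {
    surgery_pair <- build_surgery_pair(trained,
                                       seed = substream_seed(seed, "surgery"))
  }
  spec <- switch(perturbation,
                 rotation = "rotation",
                 none = identity_surgery(model$M),
                 compatible = surgery_pair$compatible,
                 incompatible = surgery_pair$incompatible)
  H_pert <- perturbed_environment(trained$H, spec)
  dec <- if (!is.null(surgery_pair)) surgery_pair$dec else
    decompose_subspaces(trained$H, trained$W0)

  reps <- vector("list", n_reps)
  cm <- NULL; bm <- NULL
  for (r in seq_len(n_reps)) {
    reps[[r]] <- run_repetition(trained, H_pert, config, cycles,
                                seed = substream_seed(seed, "rep", r))
    cm_r <- cycle_metrics_one(reps[[r]]$records, trained, dec)
    bm_r <- block_metrics_one(reps[[r]]$snapshots, trained, surgery_pair)
    cm <- if (is.null(cm)) cm_r else accumulate_metrics(cm, cm_r)
    if (!is.null(bm_r)) bm <- if (is.null(bm)) bm_r else accumulate_metrics(bm, bm_r)
  }
  cm <- finalize_metrics(cm, n_reps, keep = c("cycle", "phase"))
  if (!is.null(bm)) bm <- finalize_metrics(bm, n_reps, keep = "block")

  structure(list(
    perturbation = perturbation, config = config, seed = seed, cv = cv,
    n_reps = n_reps, cycles = cycles, pretrain_cycles = pretrain_cycles,
    model = trained, trained = trained, surgery_pair = surgery_pair,
    dec = dec, H_pert = H_pert,
    diverged = vapply(reps, `[[`, TRUE, "diverged"),
    cycle_metrics = cm, block_metrics = bm,
    records = if (keep_records) lapply(reps, `[[`, "records") else NULL,
    snapshots = if (keep_records) lapply(reps, `[[`, "snapshots") else NULL,
    final = lapply(reps, function(r) list(W = r$W, Z = r$Z, Hhat = r$Hhat))),
    class = "synergy_adaptation")
}

#' @rdname adapt_synergies
#' @export
run_experiment <- adapt_synergies

## running sums / division for rep-averaged metric frames
accumulate_metrics <- function(acc, new) {
  num <- vapply(acc, is.numeric, TRUE) & !(names(acc) %in% c("cycle", "block"))
  acc[num] <- acc[num] + new[num]
  acc
}
finalize_metrics <- function(acc, n, keep) {
  num <- vapply(acc, is.numeric, TRUE) & !(names(acc) %in% keep)
  acc[num] <- acc[num] / n
  acc
}

#' @export
print.synergy_adaptation <- function(x, ...) {
  cat("Simulated synergy adaptation (", x$perturbation, ")\n", sep = "")
  cat("  dims: D=", x$model$D, " M=", x$model$M, " N=", x$model$N,
      " NPhi=", nrow(x$model$grid$centers), "\n", sep = "")
  cat("  phases (cycles): pretrain=", x$pretrain_cycles, ", ",
      paste(names(x$cycles), x$cycles, sep = "=", collapse = ", "),
      "; reps=", x$n_reps, "; cv=", x$cv, "\n", sep = "")
  pm <- x$cycle_metrics
  for (ph in unique(pm$phase)) {
    last <- pm[pm$phase == ph, ]
    last <- last[nrow(last), ]
    cat(sprintf("  %-12s final cycle: dir err %6.2f deg, mag err %6.3f, R2 %5.3f\n",
                ph, last$direction_error, last$magnitude_error,
                last$r2_baseline))
  }
  invisible(x)
}

#' @export
summary.synergy_adaptation <- function(object, ...) {
  pm <- object$cycle_metrics
  agg <- stats::aggregate(pm[setdiff(names(pm), c("cycle", "phase"))],
                          by = list(phase = pm$phase), FUN = mean)
  agg <- agg[order(match(agg$phase, c("baseline", "perturbation", "washout"))), ]
  structure(list(perturbation = object$perturbation, by_phase = agg,
                 I_diff = if (!is.null(object$surgery_pair))
                   c(incompatible = object$surgery_pair$incompatible$I_diff,
                     compatible = object$surgery_pair$compatible$I_diff)
                 else NULL),
            class = "summary.synergy_adaptation")
}

#' @export
print.summary.synergy_adaptation <- function(x, ...) {
  cat("Phase means (", x$perturbation, "):\n", sep = "")
  print(x$by_phase, row.names = FALSE, digits = 4)
  if (!is.null(x$I_diff)) {
    cat(sprintf("Surgery difficulty: Idiff(incompatible) = %.3f, Idiff(compatible) = %.3f\n",
                x$I_diff[1], x$I_diff[2]))
  }
  invisible(x)
}

#' Learned matrices of a simulated adaptation
#'
#' @param object a `synergy_adaptation`.
#' @param rep which repetition's final state (default 1).
#' @param ... unused.
#' @return list with the final `W`, `Z`, `Hhat` and the baseline `W0`.
#' @export
coef.synergy_adaptation <- function(object, rep = 1, ...) {
  c(object$final[[rep]], list(W0 = object$model$W0))
}

#' Noiseless forces produced by the learned policy
#'
#' @param object a `synergy_adaptation`.
#' @param targets `2 x K` matrix of desired forces (default the task's
#'   8 targets).
#' @param environment `"baseline"` or `"perturbed"` map to execute in.
#' @param rep which repetition's final state.
#' @param ... unused.
#' @return `2 x K` matrix of executed forces.
#' @export
predict.synergy_adaptation <- function(object, targets = object$model$targets,
                                       environment = c("baseline", "perturbed"),
                                       rep = 1, ...) {
  environment <- match.arg(environment)
  H <- if (environment == "baseline") object$model$H else object$H_pert
  st <- object$final[[rep]]
  grid <- object$model$grid
  vapply(seq_len(ncol(targets)), function(k) {
    phi <- rbf_features(targets[, k], grid)
    drop(H %*% st$W %*% st$Z %*% phi)
  }, numeric(2))
}

#' Per-trial force errors of the recorded phases
#'
#' @param object a `synergy_adaptation` run with `keep_records = TRUE`.
#' @param rep repetition index.
#' @param ... unused.
#' @return matrix of `delta_f = f_exec - f_star`, one row per trial.
#' @export
residuals.synergy_adaptation <- function(object, rep = 1, ...) {
  rec <- object$records[[rep]]
  if (is.null(rec)) stop("records were not kept; rerun with keep_records = TRUE")
  rec$f_exec - t(object$model$targets[, rec$target])
}

#' Re-run the recorded phases under fresh noise streams
#'
#' @param object a `synergy_adaptation`.
#' @param nsim number of new repetitions.
#' @param seed master seed for the new noise streams.
#' @param ... unused.
#' @return list of repetition results (records, snapshots, final state).
#' @export
simulate.synergy_adaptation <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- substream_seed(object$seed, "simulate")
  lapply(seq_len(nsim), function(r) {
    run_repetition(object$trained, object$H_pert, object$config,
                   object$cycles, seed = substream_seed(seed, "sim-rep", r))
  })
}

#' Plot metric time-courses of a simulated adaptation
#'
#' Draws the four headline per-cycle metrics (direction error,
#' magnitude error, reconstruction R2, activity norm) against cycle,
#' with the perturbation phase shaded.
#'
#' @param x a `synergy_adaptation`.
#' @param ... passed to [plot()].
#' @export
plot.synergy_adaptation <- function(x, ...) {
  pm <- x$cycle_metrics
  shade <- range(pm$cycle[pm$phase == "perturbation"])
  panels <- c(direction_error = "Direction error (deg)",
              magnitude_error = "Magnitude error",
              r2_baseline = "R2 (baseline synergies)",
              activity_norm = "Muscle activity norm")
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(panels)) {
    graphics::plot(pm$cycle, pm[[nm]], type = "l", xlab = "cycle",
                   ylab = panels[[nm]], main = panels[[nm]], ...)
    graphics::rect(shade[1] - 0.5, graphics::par("usr")[3], shade[2] + 0.5,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
  }
  invisible(x)
}
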