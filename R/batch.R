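## The three main simulation grids: parameter combinations crossed with
## the three perturbations and 16 random model initializations. Within
## an initialization, all conditions share the environment, the initial
## matrices, and the difficulty-matched surgery pair; within a
## condition, the pre-trained state is shared across perturbations.

#' Condition grids of the three main simulations
#'
#' Simulation 1 varies which of the policy (`Z`) and synergies (`W`) are
#' updated; Simulation 2 varies the forward-model learning (off, slow,
#' ideal); Simulation 3 toggles regularization. Regularization weights,
#' when on, are 1% of the corresponding learning rate.
#'
#' @param simulation 1, 2 or 3.
#' @return named list of [learning_config()]s.
#' @export
simulation_conditions <- function(simulation) {
  switch(as.character(simulation),
    "1" = list(
      Z_only = learning_config(eta_W = 0, eta_Z = 0.05),
      W_only = learning_config(eta_W = 0.05, eta_Z = 0),
      both   = learning_config(eta_W = 0.05, eta_Z = 0.05)),
    "2" = list(
      fm_off   = learning_config(eta_Hhat = 0),
      fm_slow  = learning_config(eta_Hhat = 0.25),
      fm_ideal = learning_config(ideal_forward_model = TRUE)),
    "3" = list(
      no_reg = learning_config(lambda_W = 0, lambda_Z = 0),
      reg    = learning_config()),
    stop("unknown simulation id: ", simulation))
}

#' Run a full simulation grid
#'
#' Runs `conditions x perturbations x n_init` simulated experiments and
#' collects per-cycle and per-block metric tables keyed by
#' initialization, condition and perturbation.
#'
#' @param simulation 1, 2 or 3 (Table-style preset), or a named list of
#'   [learning_config()]s for a custom grid.
#' @param n_init number of model initializations (default 16).
#' @param perturbations subset of
#'   `c("rotation", "compatible", "incompatible")`.
#' @param seed master seed.
#' @param cv motor-noise coefficient.
#' @param n_reps repetitions per initialization (default 4).
#' @param cycles,pretrain_cycles protocol lengths, as in
#'   [adapt_synergies()].
#' @param pretrain_config learning configuration used during the single
#'   shared pre-training of each initialization (default: the full
#'   model with regularization). Condition-specific configurations
#'   apply from the recorded phases onward.
#' @param progress print a line per initialization.
#' @return object of class `synergy_batch`: a list with `cycle_metrics`
#'   and `block_metrics` data frames (long over init / condition /
#'   perturbation), `surgeries` (per-init difficulty indices), and the
#'   call parameters.
#' @export
run_batch <- function(simulation = 1, n_init = 16,
                      perturbations = c("rotation", "compatible",
                                        "incompatible"),
                      seed = 1, cv = 0.1, n_reps = 4,
                      cycles = c(baseline = 36, perturbation = 36,
                                 washout = 36),
                      pretrain_cycles = 324,
                      pretrain_config = learning_config(),
                      progress = FALSE) {
  conditions <- if (is.list(simulation)) simulation
                else simulation_conditions(simulation)
  sim_label <- if (is.list(simulation)) "custom" else as.character(simulation)
  cm_all <- list(); bm_all <- list(); surg <- list()
  for (i in seq_len(n_init)) {
    model <- synergy_model(cv = cv, seed = substream_seed(seed, "init", i))
    ## one pre-training per initialization, under the default full model;
    ## condition-specific parameters apply from the recorded phases on
    trained <- pretrain(model, pretrain_config, pretrain_cycles,
                        seed = substream_seed(seed, "pretrain", i))
    ## baseline synergies = those in effect after pre-training; the
    ## surgery pair is built from them, as from baseline-identified
    ## synergies in the experimental procedure
    trained$W0 <- trained$W
    pair <- build_surgery_pair(trained,
                               seed = substream_seed(seed, "surgery", i))
    surg[[i]] <- data.frame(init = i,
                            I_diff_incompatible = pair$incompatible$I_diff,
                            I_diff_compatible = pair$compatible$I_diff)
    for (cond in names(conditions)) {
      cfg <- conditions[[cond]]
      for (pert in perturbations) {
        ## repetition streams differ across init/condition/perturbation
        run_seed <- substream_seed(seed, "run", i, cond, pert)
        fit <- adapt_synergies(pert, config = cfg, seed = run_seed, cv = cv,
                               n_reps = n_reps, cycles = cycles,
                               pretrain_cycles = 0, model = trained,
                               surgery_pair = pair, keep_records = FALSE)
        cm <- fit$cycle_metrics
        cm$init <- i; cm$condition <- cond; cm$perturbation <- pert
        cm_all[[length(cm_all) + 1L]] <- cm
        if (!is.null(fit$block_metrics)) {
          bm <- fit$block_metrics
          bm$init <- i; bm$condition <- cond; bm$perturbation <- pert
          bm_all[[length(bm_all) + 1L]] <- bm
        }
      }
    }
    if (progress) message("init ", i, "/", n_init, " done")
  }
  structure(list(simulation = sim_label,
                 cycle_metrics = do.call(rbind, cm_all),
                 block_metrics = if (length(bm_all)) do.call(rbind, bm_all),
                 surgeries = do.call(rbind, surg),
                 conditions = conditions, perturbations = perturbations,
                 n_init = n_init, n_reps = n_reps, seed = seed, cv = cv,
                 cycles = cycles, pretrain_cycles = pretrain_cycles),
            class = "synergy_batch")
}

#' @export
print.synergy_batch <- function(x, ...) {
  cat("Simulation batch (preset ", x$simulation, "): ",
      x$n_init, " initializations x ",
      length(x$conditions), " conditions x ",
      length(x$perturbations), " perturbations, ",
      x$n_reps, " reps, cv=", x$cv, "\n", sep = "")
  cat("  conditions: ", paste(names(x$conditions), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Metric values at the final perturbation cycle
#'
#' Convenience extractor used by the paired contrasts: one row per
#' initialization x condition x perturbation.
#'
#' @param batch a `synergy_batch`.
#' @return data frame of final-perturbation-cycle metrics.
#' @export
final_perturbation_cycle <- function(batch) {
  cm <- batch$cycle_metrics
  pm <- cm[cm$phase == "perturbation", ]
  last <- max(pm$cycle)
  pm[pm$cycle == last, ]
}

#' Tidy long-format results table
#'
#' One row per initialization x condition x perturbation x phase x
#' cycle x metric, suitable for CSV export and off-the-shelf statistics.
#'
#' @param batch a `synergy_batch`.
#' @return long data frame with columns `init`, `condition`,
#'   `perturbation`, `phase`, `cycle`, `metric`, `value`.
#' @export
tidy_results <- function(batch) {
  cm <- batch$cycle_metrics
  id <- c("init", "condition", "perturbation", "phase", "cycle")
  metrics <- setdiff(names(cm), id)
  out <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(cm[id], metric = m, value = cm[[m]], row.names = NULL)
  }))
  out[order(out$init, out$condition, out$perturbation, out$cycle), ]
}

#' Direction error at perturbation onset, measured on a frozen learner
#'
#' Pre-trains a noise-free model in the baseline environment until the
#' mean per-cycle direction error falls below `threshold` (324 cycles,
#' extended in 36-cycle steps if needed), then runs one cycle under the
#' perturbation with all learning rates set to zero, so the measured
#' errors reflect the converged baseline policy confronted with the
#' perturbation and no within-cycle adaptation.
#'
#' The measurement conditions on a converged baseline. Noise-free
#' learning can plateau for rare initializations (no exploration), in
#' which case the precondition is unattainable and the next
#' initialization sub-stream is tried (bounded, with a warning).
#'
#' @param perturbation as in [adapt_synergies()].
#' @param seed master seed.
#' @param cv motor-noise coefficient (default 0: deterministic onset).
#' @param config learning configuration used during pre-training.
#' @param threshold convergence criterion on the baseline direction
#'   error, degrees.
#' @param max_extra_cycles cap on additional pre-training.
#' @param max_inits initializations tried before giving up.
#' @return list with `onset_error` (mean over the 8 targets, degrees),
#'   `per_target` errors, `pretrain_cycles` actually used, and
#'   `init_attempt`.
#' @export
onset_direction_error <- function(perturbation = "rotation", seed = 1,
                                  cv = 0, config = learning_config(),
                                  threshold = 1, max_extra_cycles = 1800,
                                  max_inits = 8) {
  trained <- NULL
  for (attempt in seq_len(max_inits)) {
    model <- synergy_model(cv = cv,
                           seed = substream_seed(seed, "init", attempt))
    cand <- pretrain(model, config, 324,
                     seed = substream_seed(seed, "pretrain", attempt))
    used <- 324
    while (!isTRUE(utils::tail(cand$pretrain_dir_err, 1) < threshold) &&
           used < 324 + max_extra_cycles) {
      cand <- pretrain(cand, config, 36,
                       seed = substream_seed(seed, "pretrain", attempt, used))
      used <- used + 36
    }
    if (isTRUE(utils::tail(cand$pretrain_dir_err, 1) < threshold)) {
      trained <- cand
      break
    }
    warning("initialization ", attempt, " did not converge below ",
            threshold, " degrees; resampling")
  }
  if (is.null(trained))
    stop("no initialization converged below ", threshold, " degrees")
  trained$W0 <- trained$W      # baseline synergies: post-pre-training
  pair <- if (perturbation %in% c("compatible", "incompatible")) {
    build_surgery_pair(trained, seed = substream_seed(seed, "surgery", attempt))
  } else NULL
  spec <- switch(perturbation,
                 rotation = "rotation",
                 none = identity_surgery(trained$M),
                 compatible = pair$compatible,
                 incompatible = pair$incompatible)
  H_pert <- perturbed_environment(trained$H, spec)
  frozen <- learning_config(eta_W = 0, eta_Z = 0, eta_Hhat = 0)
  set.seed(substream_seed(seed, "onset"))
  out <- sim_cycles(trained$W, trained$Z, trained$Hhat, H_pert, trained$Phi,
                    trained$targets, 1L, cv, frozen, record = TRUE,
                    phase_label = "onset", snapshot_every = 0L)
  per_target <- vapply(seq_len(nrow(out$records$f_exec)), function(i) {
    force_direction_error(out$records$f_exec[i, ],
                          trained$targets[, out$records$target[i]])
  }, 0)
  list(onset_error = mean(per_target), per_target = per_target,
       pretrain_cycles = used, init_attempt = attempt)
}
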