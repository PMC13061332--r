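## Experimental protocol: trials, cycles, phases, repetitions and
## initialization batches. A cycle is 8 trials, one per target in random
## order; the default schedule is 324 unrecorded pre-training cycles
## followed by recorded baseline / perturbation / washout phases of 36
## cycles each, with recorded data averaged across 4 repetitions that
## restart from the same post-pre-training state under different noise
## streams.

#' The eight standard force targets
#'
#' @param K number of targets (default 8).
#' @param radius target radius in force units (default 0.5).
#' @return `2 x K` matrix of targets uniformly spaced on the circle.
#' @export
target_set <- function(K = 8, radius = 0.5) {
  ang <- 2 * pi * (seq_len(K) - 1) / K
  rbind(radius * cos(ang), radius * sin(ang))
}

#' Deterministic sub-stream seed
#'
#' Fans a master seed out into named sub-streams (environment, surgery,
#' pre-training, per-repetition noise, ...) so that paired conditions can
#' share exactly the streams they must share. Always below 2^31.
#'
#' @param ... labels (coerced to character) identifying the stream.
#' @return a single integer seed.
#' @export
substream_seed <- function(...) {
  s <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Initialize a synergy-learning model
#'
#' Draws a random environment `H`, baseline synergies `W0` (minimum-norm
#' non-negative patterns for random positively spanning forces), a policy
#' matrix `Z0` with entries uniform on `[0, z_init_max]`, and a forward
#' model `Hhat0` initialized at zero: the muscle-to-force map is not
#' assumed known a priori, so the controller does not move until the
#' forward model has learned from prediction errors during pre-training.
#' (`hhat_init_max > 0` instead draws entries uniform on
#' `[0, hhat_init_max]`.)
#'
#' @param D,M,N force dimensionality, muscle count, synergy count.
#' @param grid an [rbf_grid()].
#' @param cv signal-dependent motor-noise coefficient.
#' @param z_init_max,hhat_init_max initialization scales.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @return object of class `synergy_model`.
#' @export
synergy_model <- function(D = 2, M = 10, N = 5, grid = rbf_grid(),
                          cv = 0.1, z_init_max = 0.05,
                          hhat_init_max = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- init_environment(D, M)
  W0 <- init_synergies(H, N)
  NPhi <- nrow(grid$centers)
  Z0 <- matrix(stats::runif(N * NPhi, 0, z_init_max), N, NPhi)
  Hhat0 <- matrix(stats::runif(D * M, 0, hhat_init_max), D, M)
  targets <- target_set()
  Phi <- vapply(seq_len(ncol(targets)),
                function(k) rbf_features(targets[, k], grid), numeric(NPhi))
  structure(list(H = H, W0 = W0, Z0 = Z0, Hhat0 = Hhat0,
                 W = W0, Z = Z0, Hhat = Hhat0,
                 grid = grid, cv = cv, targets = targets, Phi = Phi,
                 D = D, M = M, N = N),
            class = "synergy_model")
}

#' Build the difficulty-matched surgery pair for a model
#'
#' Uses the model's environment and its initial (baseline) synergies, as
#' the experimental procedure prescribes; the compatible surgery's angle
#' is matched to the incompatible one's index of difficulty.
#'
#' @param model a [synergy_model()].
#' @param seed optional seed for the random `w` / `n` directions.
#' @param max_tries resampling attempts on geometry failures.
#' @return list with elements `incompatible`, `compatible` (both
#'   `surgery_spec`) and `dec` (the subspace decomposition).
#' @export
build_surgery_pair <- function(model, seed = NULL, max_tries = 20L) {
  if (!is.null(seed)) set.seed(seed)
  dec <- decompose_subspaces(model$H, model$W0)
  for (i in seq_len(max_tries)) {
    ok <- tryCatch({
      Ti <- build_incompatible(model$H, model$W0, dec, model$targets)
      Tc <- build_compatible(model$H, model$W0, dec, Ti, model$targets)
      list(incompatible = Ti, compatible = Tc, dec = dec)
    }, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
  stop("build_surgery_pair(): failed after ", max_tries, " attempts")
}

## Core trial loop over n_cycles. Operates on (W, Z, Hhat) under a fixed
## environment, updating per the learning rules; optionally records per-
## trial quantities. Returns the updated matrices plus records. RNG state
## is the caller's responsibility.
sim_cycles <- function(W, Z, Hhat, H_cur, Phi, targets, n_cycles, cv, cfg,
                       record = FALSE, phase_label = "", cycle_offset = 0L,
                       snapshot_every = 3L, runaway_norm = 50) {
  K <- ncol(targets)
  ideal <- cfg$ideal_forward_model
  ## Learning with a badly wrong (e.g. frozen) forward model can be
  ## unstable: commands then grow without bound. Once the command norm
  ## crosses `runaway_norm` the learner is frozen for the rest of the
  ## phase so the runaway is recorded as a finite error plateau.
  learning_on <- TRUE; diverged <- FALSE
  nT <- n_cycles * K
  if (record) {
    M <- nrow(W); N <- ncol(W); D <- nrow(H_cur)
    rec <- list(
      phase = rep(phase_label, nT), cycle = integer(nT), target = integer(nT),
      f_exec = matrix(0, nT, D), f_pred = matrix(0, nT, D),
      m_command = matrix(0, nT, M), m_exec = matrix(0, nT, M),
      c = matrix(0, nT, N), sensitivity = logical(nT))
    n_snap <- if (snapshot_every > 0) n_cycles %/% snapshot_every else 0L
    snaps <- if (n_snap > 0) array(0, c(M, N, n_snap)) else NULL
  }
  dir_err_cycle <- numeric(n_cycles)
  i <- 0L; isnap <- 0L
  for (cyc in seq_len(n_cycles)) {
    ord <- sample.int(K)
    derr <- 0; nerr <- 0L
    for (k in ord) {
      i <- i + 1L
      phi <- Phi[, k]
      cc <- drop(Z %*% phi)
      m_cmd <- drop(W %*% cc)
      m_exec <- if (cv > 0) pmax(0, m_cmd + stats::rnorm(length(m_cmd), 0, cv * m_cmd)) else m_cmd
      f_exec <- drop(H_cur %*% m_exec)
      if (ideal) Hhat <- H_cur
      f_pred <- drop(Hhat %*% m_exec)
      f_star <- targets[, k]
      delta_f <- f_exec - f_star
      delta_fp <- f_pred - f_exec
      ## angle error for convergence tracking (always cheap)
      fn <- sqrt(sum(f_exec^2))
      if (fn > 0) {  # undefined (zero-force) trials are excluded, not zeroed
        derr <- derr +
          acos(max(-1, min(1, sum(f_exec * f_star) / (fn * sqrt(sum(f_star^2)))))) * 180 / pi
        nerr <- nerr + 1L
      }
      if (record) {
        rec$cycle[i] <- cycle_offset + cyc
        rec$target[i] <- k
        rec$f_exec[i, ] <- f_exec
        rec$f_pred[i, ] <- f_pred
        rec$m_command[i, ] <- m_cmd
        rec$m_exec[i, ] <- m_exec
        rec$c[i, ] <- cc
        rec$sensitivity[i] <- drop(crossprod(delta_f, H_cur %*% crossprod(Hhat, delta_f))) > 0
      }
      if (learning_on && sum(m_cmd^2) > runaway_norm^2) {
        learning_on <- FALSE; diverged <- TRUE
      }
      if (learning_on) {
        ## W and Z updated with the trial-start Hhat, then Hhat from dfp
        bp <- drop(crossprod(Hhat, delta_f))             # M-vector
        Wn <- pmax(W - cfg$eta_W * tcrossprod(bp, cc) - cfg$lambda_W * W, 0)
        Zn <- pmax(Z - cfg$eta_Z * tcrossprod(drop(crossprod(W, bp)), phi) -
                     cfg$lambda_Z * Z, 0)
        W <- Wn; Z <- Zn
        if (!ideal) Hhat <- Hhat - cfg$eta_Hhat * tcrossprod(delta_fp, m_exec)
      }
    }
    dir_err_cycle[cyc] <- if (nerr > 0) derr / nerr else NA_real_
    if (record && snapshot_every > 0 && n_snap > 0 &&
        cyc %% snapshot_every == 0L && isnap < n_snap) {
      isnap <- isnap + 1L
      snaps[, , isnap] <- W
    }
  }
  out <- list(W = W, Z = Z, Hhat = Hhat, dir_err_cycle = dir_err_cycle,
              diverged = diverged)
  if (record) { out$records <- rec; out$snapshots <- snaps }
  out
}

#' Run a single trial
#'
#' Executes the full feedforward chain (features, recruitment,
#' composition, motor noise, execution, prediction) followed by the
#' learning updates: W and Z from the force error using the trial-start
#' forward model, then the forward model from the prediction error.
#'
#' @param model a [synergy_model()] (its `W`, `Z`, `Hhat` are the state).
#' @param target_index which of the 8 targets to reach.
#' @param H_current current environment (default the model's baseline).
#' @param config a [learning_config()].
#' @return list with the updated `model` and a one-row `record` list
#'   (f_exec, f_pred, m_command, m_exec, c, delta_f, delta_fp,
#'   sensitivity).
#' @export
run_trial <- function(model, target_index, H_current = model$H,
                      config = learning_config()) {
  out <- sim_cycles(model$W, model$Z, model$Hhat, H_current,
                    model$Phi[, target_index, drop = FALSE],
                    model$targets[, target_index, drop = FALSE],
                    n_cycles = 1L, cv = model$cv, cfg = config,
                    record = TRUE, snapshot_every = 0L)
  model$W <- out$W; model$Z <- out$Z; model$Hhat <- out$Hhat
  r <- out$records
  rec <- list(target = target_index,
              f_exec = r$f_exec[1, ], f_pred = r$f_pred[1, ],
              m_command = r$m_command[1, ], m_exec = r$m_exec[1, ],
              c = r$c[1, ],
              delta_f = r$f_exec[1, ] - model$targets[, target_index],
              delta_fp = r$f_pred[1, ] - r$f_exec[1, ],
              sensitivity = r$sensitivity[1])
  list(model = model, record = rec)
}

#' Pre-train a model in the baseline environment
#'
#' Runs unrecorded cycles in the baseline environment with learning on,
#' establishing the converged baseline policy and forward model.
#'
#' @param model a [synergy_model()].
#' @param config a [learning_config()].
#' @param cycles number of pre-training cycles (default 324).
#' @param seed seed for the pre-training stream.
#' @return the model with updated `W`, `Z`, `Hhat`, plus a
#'   `pretrain_dir_err` field with the per-cycle mean direction error.
#' @export
pretrain <- function(model, config = learning_config(), cycles = 324L,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- sim_cycles(model$W, model$Z, model$Hhat, model$H, model$Phi,
                    model$targets, cycles, model$cv, config)
  model$W <- out$W; model$Z <- out$Z; model$Hhat <- out$Hhat
  model$pretrain_dir_err <- out$dir_err_cycle
  model
}

## One repetition of the recorded phases: baseline -> perturbation ->
## washout, learning on throughout; washout returns to the baseline
## environment. Returns records, snapshots, final state.
run_repetition <- function(model, H_pert, config, cycles, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phases <- list(
    list(label = "baseline", H = model$H, n = cycles[["baseline"]]),
    list(label = "perturbation", H = H_pert, n = cycles[["perturbation"]]),
    list(label = "washout", H = model$H, n = cycles[["washout"]]))
  W <- model$W; Z <- model$Z; Hhat <- model$Hhat
  recs <- list(); snaps <- list(); off <- 0L; diverged <- FALSE
  for (ph in phases) {
    if (ph$n == 0L) next
    out <- sim_cycles(W, Z, Hhat, ph$H, model$Phi, model$targets, ph$n,
                      model$cv, config, record = TRUE,
                      phase_label = ph$label, cycle_offset = off)
    W <- out$W; Z <- out$Z; Hhat <- out$Hhat
    diverged <- diverged || out$diverged
    recs[[ph$label]] <- out$records
    snaps[[ph$label]] <- out$snapshots
    off <- off + ph$n
  }
  rec <- list(
    phase = unlist(lapply(recs, `[[`, "phase"), use.names = FALSE),
    cycle = unlist(lapply(recs, `[[`, "cycle"), use.names = FALSE),
    target = unlist(lapply(recs, `[[`, "target"), use.names = FALSE),
    sensitivity = unlist(lapply(recs, `[[`, "sensitivity"), use.names = FALSE),
    f_exec = do.call(rbind, lapply(recs, `[[`, "f_exec")),
    f_pred = do.call(rbind, lapply(recs, `[[`, "f_pred")),
    m_command = do.call(rbind, lapply(recs, `[[`, "m_command")),
    m_exec = do.call(rbind, lapply(recs, `[[`, "m_exec")),
    c = do.call(rbind, lapply(recs, `[[`, "c")))
  snap_arr <- abind3(snaps)
  list(records = rec, snapshots = snap_arr,
       W = W, Z = Z, Hhat = Hhat, diverged = diverged)
}

## bind a list of M x N x k arrays along the third margin
abind3 <- function(lst) {
  lst <- lst[!vapply(lst, is.null, TRUE)]
  if (!length(lst)) return(NULL)
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE),
        c(d[1], d[2], sum(vapply(lst, function(a) dim(a)[3], 0))))
}
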