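## Configuration files (YAML), model-state snapshots (JSON), results
## tables (CSV), and deterministic test fixtures.

#' Default experiment configuration
#'
#' All tunables of a simulated experiment in one serializable list.
#' @return named list (see fields).
#' @export
default_config <- function() {
  list(
    dims = list(D = 2, M = 10, N = 5),
    grid = list(points_per_axis = 11, lim = 1, width = 0.2),
    noise = list(cv = 0.1),
    init = list(z_init_max = 0.05, hhat_init_max = 0,
                norm_range = c(0.5, 1.5)),
    learning = list(eta_W = 0.05, eta_Z = 0.05, eta_Hhat = 0.25,
                    lambda_W = 5e-4, lambda_Z = 5e-4,
                    ideal_forward_model = FALSE),
    schedule = list(pretrain = 324, baseline = 36, perturbation = 36,
                    washout = 36, n_reps = 4),
    batch = list(n_init = 16, simulation = 1,
                 perturbations = c("rotation", "compatible", "incompatible")),
    seed = 1)
}

#' Load an experiment configuration from a YAML file
#'
#' Missing fields fall back to [default_config()]; an empty file yields
#' the defaults. The presets `"sim1"`, `"sim2"`, `"sim3"` name the three
#' standard simulation grids and may be given instead of a path.
#'
#' @param path YAML file path, or one of `"sim1"`, `"sim2"`, `"sim3"`.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (path %in% c("sim1", "sim2", "sim3")) {
    cfg <- default_config()
    cfg$batch$simulation <- as.integer(sub("sim", "", path))
    return(validate_config(cfg))
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(utils::modifyList(default_config(), user))
}

#' Write a configuration to YAML
#' @param config configuration list.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  d <- cfg$dims
  if (!(d$M > d$D && d$D >= 1)) stop("config: need M > D >= 1")
  if (!(d$N >= d$D)) stop("config: need N >= D")
  l <- cfg$learning
  for (f in c("eta_W", "eta_Z", "eta_Hhat", "lambda_W", "lambda_Z")) {
    if (l[[f]] < 0) stop("config: learning$", f, " must be >= 0")
  }
  if (cfg$noise$cv < 0) stop("config: noise$cv must be >= 0")
  if (cfg$grid$width <= 0) stop("config: grid$width must be > 0")
  cfg
}

#' Learning configuration from an experiment configuration
#' @param config a configuration list.
#' @return a [learning_config()].
#' @export
config_learning <- function(config) {
  l <- config$learning
  learning_config(eta_W = l$eta_W, eta_Z = l$eta_Z, eta_Hhat = l$eta_Hhat,
                  lambda_W = l$lambda_W, lambda_Z = l$lambda_Z,
                  ideal_forward_model = isTRUE(l$ideal_forward_model))
}

#' Serialize a model state snapshot to JSON
#'
#' Stores `H`, `W`, `Z`, `Hhat`, the grid specification, the noise
#' coefficient and (optionally) a surgery spec at full double precision
#' so that a load reproduces the state bit-exactly.
#'
#' @param model a [synergy_model()].
#' @param path output JSON file.
#' @param surgery optional `surgery_spec` to store alongside.
#' @export
save_snapshot <- function(model, path, surgery = NULL) {
  snap <- list(
    dims = list(D = model$D, M = model$M, N = model$N),
    H = model$H, W0 = model$W0, Z0 = model$Z0, Hhat0 = model$Hhat0,
    W = model$W, Z = model$Z, Hhat = model$Hhat,
    grid = list(points_per_axis = model$grid$points_per_axis,
                lim = model$grid$lim, width = model$grid$width),
    cv = model$cv)
  if (!is.null(surgery)) {
    snap$surgery <- list(T = surgery$T, kind = surgery$kind,
                         w = surgery$w, w_prime = surgery$w_prime,
                         n = surgery$n, angle = surgery$angle,
                         I_diff = surgery$I_diff)
  }
  jsonlite::write_json(snap, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Load a model state snapshot from JSON
#' @param path snapshot file written by [save_snapshot()].
#' @return a [synergy_model()] (plus a `surgery` attribute if stored).
#' @export
load_snapshot <- function(path) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  dbl <- function(x) { storage.mode(x) <- "double"; x }  # JSON reads 0 as integer
  for (f in c("H", "W0", "Z0", "Hhat0", "W", "Z", "Hhat")) snap[[f]] <- dbl(snap[[f]])
  grid <- rbf_grid(snap$grid$points_per_axis, snap$grid$lim, snap$grid$width)
  targets <- target_set()
  Phi <- vapply(seq_len(ncol(targets)),
                function(k) rbf_features(targets[, k], grid),
                numeric(nrow(grid$centers)))
  model <- structure(list(
    H = snap$H, W0 = snap$W0, Z0 = snap$Z0, Hhat0 = snap$Hhat0,
    W = snap$W, Z = snap$Z, Hhat = snap$Hhat,
    grid = grid, cv = snap$cv, targets = targets, Phi = Phi,
    D = snap$dims$D, M = snap$dims$M, N = snap$dims$N),
    class = "synergy_model")
  if (!is.null(snap$surgery)) {
    attr(model, "surgery") <- structure(
      list(T = snap$surgery$T, kind = snap$surgery$kind,
           w = snap$surgery$w, w_prime = snap$surgery$w_prime,
           n = snap$surgery$n, angle = snap$surgery$angle,
           I_diff = snap$surgery$I_diff),
      class = "surgery_spec")
  }
  model
}

#' Write a results table to CSV
#'
#' Numeric columns are written with 15 significant digits so metric
#' precision survives the round trip.
#'
#' @param table data frame (e.g. from [tidy_results()]).
#' @param path output CSV file.
#' @export
write_results <- function(table, path) {
  tab <- table
  num <- vapply(tab, is.numeric, TRUE) & !vapply(tab, is.integer, TRUE)
  tab[num] <- lapply(tab[num], function(x) sprintf("%.15g", x))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path CSV file.
#' @return data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Deterministic small model fixtures
#'
#' Profiles: `"1d-two-muscle"` (H = (1, -1), two muscles pulling in
#' opposite directions along one force axis), `"tiny-2x4x2"` (a fixed
#' 2-force, 4-muscle, 2-synergy instance on a coarse grid), and
#' `"paper-default"` (the standard D=2, M=10, N=5, 121-feature model at
#' a fixed seed).
#'
#' @param profile fixture name.
#' @return a [synergy_model()]-like state (for `"1d-two-muscle"`, a
#'   plain list with `H` and the worked-example solution).
#' @export
make_fixture <- function(profile = c("paper-default", "tiny-2x4x2",
                                     "1d-two-muscle")) {
  profile <- match.arg(profile)
  switch(profile,
    "1d-two-muscle" = list(
      H = matrix(c(1, -1), 1, 2),
      target = 0.5,
      min_norm_solution = c(0.5, 0)),
    "tiny-2x4x2" = {
      H <- matrix(c(1, 0, 0, 1, -1, 0, 0, -1), 2, 4)
      W <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 4, 2)
      grid <- rbf_grid(points_per_axis = 3)
      NPhi <- nrow(grid$centers)
      targets <- target_set()
      structure(list(H = H, W0 = W, Z0 = matrix(0.02, 2, NPhi),
                     Hhat0 = matrix(0, 2, 4), W = W,
                     Z = matrix(0.02, 2, NPhi), Hhat = matrix(0, 2, 4),
                     grid = grid, cv = 0, targets = targets,
                     Phi = vapply(seq_len(ncol(targets)),
                                  function(k) rbf_features(targets[, k], grid),
                                  numeric(NPhi)),
                     D = 2, M = 4, N = 2),
                class = "synergy_model")
    },
    "paper-default" = synergy_model(seed = 20260101))
}
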