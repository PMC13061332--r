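## Performance metrics computed per cycle of 8 trials (force errors,
## reconstruction quality, activity and subspace norms, prediction
## error) and per 3-cycle block from synergy snapshots (convex-hull
## areas of synergy forces, principal angles to the surgery vectors).

#' Unsigned angle between executed force and target, in degrees
#'
#' @param f_exec,f_star force vectors. Zero vectors give `NA` (the
#'   metric is undefined there and is excluded from averages, never
#'   imputed as zero).
#' @return angle in `[0, 180]` degrees, or `NA`.
#' @export
force_direction_error <- function(f_exec, f_star) {
  a <- sqrt(sum(f_exec^2)); b <- sqrt(sum(f_star^2))
  if (a == 0 || b == 0) return(NA_real_)
  acos(max(-1, min(1, sum(f_exec * f_star) / (a * b)))) * 180 / pi
}

#' Norm of the difference between target and executed force
#' @inheritParams force_direction_error
#' @export
force_magnitude_error <- function(f_exec, f_star) {
  sqrt(sum((f_exec - f_star)^2))
}

#' Norm of the difference between predicted and executed force
#' @param f_pred,f_exec force vectors.
#' @export
prediction_error_metric <- function(f_pred, f_exec) {
  sqrt(sum((f_pred - f_exec)^2))
}

#' Reconstruction quality of muscle patterns by the baseline synergies
#'
#' For each pattern, finds the non-negative least-squares recruitment of
#' the baseline synergies and pools the residuals over the cycle:
#' `R^2 = 1 - SSE / SST`, with `SST` taken about the mean pattern of the
#' cycle (set `center = FALSE` for uncentered total variation).
#'
#' @param patterns `n x M` matrix of muscle patterns (rows are trials of
#'   one cycle).
#' @param W_baseline `M x N` baseline synergy matrix.
#' @param center logical; center `SST` about the cycle mean (default).
#' @return scalar in `(-Inf, 1]`, or `NA` if total variation is zero.
#' @export
reconstruction_r2 <- function(patterns, W_baseline, center = TRUE) {
  patterns <- as.matrix(patterns)
  sse <- 0
  for (i in seq_len(nrow(patterns))) {
    m <- patterns[i, ]
    cc <- pracma::lsqnonneg(W_baseline, m)$x
    sse <- sse + sum((drop(W_baseline %*% cc) - m)^2)
  }
  mu <- if (center) colMeans(patterns) else 0
  sst <- sum(sweep(patterns, 2, mu)^2)
  if (sst <= 0) return(NA_real_)
  1 - sse / sst
}

#' Norms of a muscle pattern projected into the four task subspaces
#'
#' Projects `m` onto the baseline task space (row space of `H`), the
#' null space, and the null space's `Nc` and `Nnc` components, using the
#' orthonormal bases of a [decompose_subspaces()] result. The task and
#' null norms close pythagorically to the total norm, and `Nc`/`Nnc`
#' close to the null norm.
#'
#' @param m muscle pattern.
#' @param dec a `subspace_decomposition`.
#' @return named numeric vector `(task, null, N_c, N_nc)`.
#' @export
subspace_norms <- function(m, dec) {
  pn <- function(B) if (ncol(B)) sqrt(sum(crossprod(B, m)^2)) else 0
  c(task = pn(dec$task), null = pn(dec$N_null),
    N_c = pn(dec$N_c), N_nc = pn(dec$N_nc))
}

#' Normalized convex-hull area of the synergy forces
#'
#' Normalizes each synergy to unit norm, projects through the given
#' environment, and takes the area of the convex hull of the projected
#' force endpoints, scaled by the same construction applied to the
#' individual muscle forces (the columns of `H_space`). Collinear force
#' sets give exactly 0.
#'
#' @param W_snapshot `M x N` synergy matrix.
#' @param H_space `2 x M` task environment (baseline `H` or `H T_i`).
#' @return non-negative scalar (1 when the synergies are the muscles
#'   themselves).
#' @export
hull_area <- function(W_snapshot, H_space) {
  Wn <- as.matrix(W_snapshot)
  nrm <- sqrt(colSums(Wn^2))
  keep <- nrm > 0
  if (!any(keep)) return(0)
  Wn <- sweep(Wn[, keep, drop = FALSE], 2, nrm[keep], "/")
  num <- poly_hull_area(t(H_space %*% Wn))
  den <- poly_hull_area(t(H_space))
  if (den <= 0) return(NA_real_)
  num / den
}

## area of the convex hull of 2-D points (0 for degenerate sets)
poly_hull_area <- function(P) {
  P <- unique(P)
  if (nrow(P) < 3) return(0)
  idx <- tryCatch(grDevices::chull(P), error = function(e) integer(0))
  if (length(idx) < 3) return(0)
  x <- P[idx, 1]; y <- P[idx, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Smallest principal angle between the synergy span and a vector
#'
#' Computed from the singular values of the product of orthonormal
#' bases: `angle = acos(max singular value of U' v)` with `U` an
#' orthonormal basis of `span(W)`.
#'
#' @param W_snapshot `M x N` synergy matrix (rank >= 1; a rank-0
#'   snapshot gives `NA`, following the missing-value policy).
#' @param v unit vector in muscle space.
#' @return angle in `[0, 90]` degrees, or `NA`.
#' @export
principal_angle <- function(W_snapshot, v) {
  U <- orth_basis(W_snapshot)
  if (!ncol(U)) return(NA_real_)
  v <- as.numeric(v); v <- v / sqrt(sum(v^2))
  s <- sqrt(sum(crossprod(U, v)^2))
  acos(max(-1, min(1, s))) * 180 / pi
}

## Per-cycle metric table for one repetition's records.
cycle_metrics_one <- function(rec, model, dec, H_incomp = NULL) {
  targets <- model$targets
  nT <- length(rec$cycle)
  f_star <- t(targets[, rec$target])
  dotp <- rowSums(rec$f_exec * f_star)
  fn <- sqrt(rowSums(rec$f_exec^2))
  tn <- sqrt(rowSums(f_star^2))
  dir_err <- acos(pmax(-1, pmin(1, dotp / (fn * tn)))) * 180 / pi
  dir_err[fn == 0] <- NA_real_
  mag_err <- sqrt(rowSums((rec$f_exec - f_star)^2))
  pred_err <- sqrt(rowSums((rec$f_pred - rec$f_exec)^2))
  act_norm <- sqrt(rowSums(rec$m_exec^2))
  proj2 <- function(B) if (ncol(B)) rowSums((rec$m_exec %*% B)^2) else numeric(nT)
  n_task <- sqrt(proj2(dec$task)); n_null <- sqrt(proj2(dec$N_null))
  n_nc <- sqrt(proj2(dec$N_c));    n_nnc <- sqrt(proj2(dec$N_nc))
  cyc <- rec$cycle
  agg <- function(x) tapply(x, cyc, mean, na.rm = TRUE)
  cycles <- sort(unique(cyc))
  r2 <- vapply(cycles, function(ci) {
    reconstruction_r2(rec$m_exec[cyc == ci, , drop = FALSE], model$W0)
  }, 0)
  data.frame(
    cycle = cycles,
    phase = rec$phase[match(cycles, cyc)],
    direction_error = as.numeric(agg(dir_err)),
    magnitude_error = as.numeric(agg(mag_err)),
    prediction_error = as.numeric(agg(pred_err)),
    activity_norm = as.numeric(agg(act_norm)),
    norm_task = as.numeric(agg(n_task)),
    norm_null = as.numeric(agg(n_null)),
    norm_Nc = as.numeric(agg(n_nc)),
    norm_Nnc = as.numeric(agg(n_nnc)),
    r2_baseline = r2,
    row.names = NULL)
}

## Per-block structure metrics from synergy snapshots.
block_metrics_one <- function(snaps, model, surgery_pair = NULL) {
  if (is.null(snaps)) return(NULL)
  nb <- dim(snaps)[3]
  H <- model$H
  Hi <- if (!is.null(surgery_pair)) H %*% surgery_pair$incompatible$T else NULL
  out <- data.frame(block = seq_len(nb))
  out$hull_area_baseline <- vapply(seq_len(nb), function(b)
    hull_area(snaps[, , b], H), 0)
  if (!is.null(Hi)) {
    out$hull_area_incompatible <- vapply(seq_len(nb), function(b)
      hull_area(snaps[, , b], Hi), 0)
    sp <- surgery_pair$incompatible
    out$angle_w <- vapply(seq_len(nb), function(b)
      principal_angle(snaps[, , b], sp$w), 0)
    out$angle_n <- vapply(seq_len(nb), function(b)
      principal_angle(snaps[, , b], sp$n), 0)
    wp <- surgery_pair$compatible$w_prime
    out$angle_w_prime <- vapply(seq_len(nb), function(b)
      principal_angle(snaps[, , b], wp), 0)
  }
  out
}

#' Paired-condition effect summary with bootstrap confidence interval
#'
#' Computes per-pair differences (`a - b`) of a metric, their mean, and
#' a percentile bootstrap confidence interval. Stands in for the formal
#' mixed-model post-hoc analysis: the per-initialization tables emitted
#' by [run_batch()] make the latter possible with standard tools.
#'
#' @param a,b numeric vectors of paired per-initialization values.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @return list with `mean_diff`, `ci` (length 2), and `diffs`.
#' @export
paired_effect_summary <- function(a, b, n_boot = 2000, conf = 0.95) {
  stopifnot(length(a) == length(b))
  d <- a - b
  n <- length(d)
  bm <- vapply(seq_len(n_boot), function(i) mean(d[sample.int(n, n, TRUE)]), 0)
  alpha <- (1 - conf) / 2
  list(mean_diff = mean(d),
       ci = unname(stats::quantile(bm, c(alpha, 1 - alpha))),
       diffs = d)
}
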