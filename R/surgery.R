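## Virtual surgeries: orthogonal remappings of muscle space built from
## the null space of H and the span of the baseline synergies, plus the
## 45-degree visuomotor rotation, with index-of-difficulty matching
## between the compatible and incompatible surgery of a pair.

#' Decompose muscle space relative to the synergies and the null space
#'
#' Computes orthonormal bases for: the null space of `H`; `Nc`, the
#' subspace common to the synergy span and the null space; `Wnc`, the
#' component of the synergy span outside the null space; and `Nnc`, the
#' component of the null space not reachable by synergy combinations.
#' With the default dimensions (D = 2, M = 10, N = 5) and generic
#' full-rank inputs these have dimensions 8, 3, 2 and 5.
#'
#' @param H `D x M` environment map (full row rank).
#' @param W `M x N` synergy matrix (full column rank).
#' @return object of class `subspace_decomposition` with fields
#'   `N_null`, `N_c`, `W_nc`, `N_nc` and `task` (orthonormal basis of
#'   the row space of `H`, i.e. the baseline task space).
#' @export
decompose_subspaces <- function(H, W) {
  H <- as.matrix(H); W <- as.matrix(W)
  D <- nrow(H)
  if (mat_rank(H) < D) stop("decompose_subspaces(): H is rank deficient")
  if (mat_rank(W) < ncol(W)) stop("decompose_subspaces(): W is rank deficient")
  N_null <- null_basis(H)
  W_orth <- orth_basis(W)
  ## synergy-span directions mapping to zero force: H W_orth y = 0
  Yc <- null_basis(H %*% W_orth)
  N_c <- if (ncol(Yc)) orth_basis(W_orth %*% Yc) else matrix(0, ncol(H), 0L)
  ## complement of N_c inside span(W)
  W_nc <- if (ncol(N_c)) {
    orth_basis(W_orth - N_c %*% crossprod(N_c, W_orth))
  } else W_orth
  ## complement of N_c inside null(H)
  N_nc <- if (ncol(N_c)) {
    coef <- null_basis(crossprod(N_c, N_null))
    N_null %*% coef
  } else N_null
  structure(list(N_null = N_null, N_c = N_c, W_nc = W_nc, N_nc = N_nc,
                 task = orth_basis(t(H))),
            class = "subspace_decomposition")
}

#' Rotation in the plane spanned by two vectors
#'
#' Builds the `M x M` orthogonal matrix rotating by `angle` within
#' `span{u, v}` and acting as the identity on the orthogonal
#' complement. With `angle` equal to the angle between `u` and `v`,
#' `T u = v`.
#'
#' @param u,v unit vectors (not collinear).
#' @param angle rotation angle in radians.
#' @return orthogonal matrix with determinant +1.
#' @export
plane_rotation <- function(u, v, angle) {
  u <- as.numeric(u); v <- as.numeric(v)
  e1 <- u / sqrt(sum(u^2))
  v_perp <- v - sum(v * e1) * e1
  nv <- sqrt(sum(v_perp^2))
  if (nv < 1e-12) stop("plane_rotation(): u and v are collinear")
  e2 <- v_perp / nv
  M <- length(u)
  diag(M) +
    (cos(angle) - 1) * (tcrossprod(e1) + tcrossprod(e2)) +
    sin(angle) * (tcrossprod(e2, e1) - tcrossprod(e1, e2))
}

#' Index of difficulty of a perturbation
#'
#' Summed absolute change, across muscles and the 8 force targets, of
#' the minimum-norm non-negative activation patterns solving the task
#' before (`H`) and during (`H_perturbed`) the perturbation.
#'
#' @param H,H_perturbed environment maps (both must positively span).
#' @param targets `D x K` matrix of force targets (default [target_set()]).
#' @return non-negative scalar.
#' @export
index_of_difficulty <- function(H, H_perturbed, targets = target_set()) {
  tot <- 0
  for (k in seq_len(ncol(targets))) {
    m0 <- min_norm_activation(H, targets[, k])
    m1 <- min_norm_activation(H_perturbed, targets[, k])
    tot <- tot + sum(abs(m0 - m1))
  }
  tot
}

#' Incompatible virtual surgery
#'
#' Rotates a random unit vector `w` in the span of `Wnc` onto a random
#' unit vector `n` in the span of `Nnc` (by the full angle between
#' them), so that the baseline synergy forces collapse onto a single
#' axis: `rank(H Ti W) = 1` and the convex hull of the projected
#' synergy forces has zero area.
#'
#' @param H environment map.
#' @param W baseline synergy matrix.
#' @param dec a [decompose_subspaces()] result for `(H, W)`.
#' @param targets force targets used for the index of difficulty.
#' @return object of class `surgery_spec` with fields `T` (the `M x M`
#'   rotation), `kind`, `w`, `n`, `angle` and `I_diff`.
#' @export
build_incompatible <- function(H, W, dec, targets = target_set()) {
  if (ncol(dec$W_nc) < 2 || ncol(dec$N_nc) < 1)
    stop("build_incompatible(): degenerate subspaces")
  w <- rand_unit_in(dec$W_nc)
  n <- rand_unit_in(dec$N_nc)
  ang <- acos(max(-1, min(1, sum(w * n))))
  Ti <- plane_rotation(w, n, ang)
  spec <- structure(list(T = Ti, kind = "incompatible", w = w, w_prime = NULL,
                         n = n, angle = ang, I_diff = NA_real_),
                    class = "surgery_spec")
  spec$I_diff <- index_of_difficulty(H, H %*% Ti, targets)
  spec
}

#' Compatible virtual surgery matched in difficulty
#'
#' Rotates `w` within the span of `Wnc` (so synergy forces stay
#' spanning) by an angle chosen by bisection so that the index of
#' difficulty matches the paired incompatible surgery to within
#' `match_tol` relative.
#'
#' @inheritParams build_incompatible
#' @param Ti the paired incompatible `surgery_spec` (matching target).
#' @param match_tol relative matching tolerance (default 0.05).
#' @param theta_max search range upper limit, radians (default 120 deg).
#' @return a `surgery_spec` of kind `"compatible"`.
#' @export
build_compatible <- function(H, W, dec, Ti, targets = target_set(),
                             match_tol = 0.05, theta_max = 2 * pi / 3) {
  if (ncol(dec$W_nc) < 2) stop("build_compatible(): degenerate Wnc")
  w <- Ti$w
  ## second direction of the rotation plane, inside span(Wnc)
  e2 <- dec$W_nc %*% null_basis(crossprod(w, dec$W_nc))
  e2 <- drop(e2[, 1]) ; e2 <- e2 / sqrt(sum(e2^2))
  idiff_at <- function(theta) {
    if (theta == 0) return(0)
    Tc <- plane_rotation(w, e2, theta)
    index_of_difficulty(H, H %*% Tc, targets)
  }
  target <- Ti$I_diff
  lo <- 0; hi <- theta_max
  if (idiff_at(hi) < target)
    stop("build_compatible(): failed to bracket the difficulty match; ",
         "resample the surgery pair")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    val <- idiff_at(mid)
    if (abs(val - target) / target <= match_tol * 0.2) { lo <- hi <- mid; break }
    if (val < target) lo <- mid else hi <- mid
  }
  theta <- (lo + hi) / 2
  Tc <- plane_rotation(w, e2, theta)
  I <- index_of_difficulty(H, H %*% Tc, targets)
  if (abs(I - target) / target > match_tol)
    stop("build_compatible(): difficulty matching did not converge")
  w_prime <- drop(Tc %*% w)
  structure(list(T = Tc, kind = "compatible", w = w, w_prime = w_prime,
                 n = Ti$n, angle = theta, I_diff = I),
            class = "surgery_spec")
}

#' Identity (no-op) surgery
#' @return a `surgery_spec` of kind `"none"` for an `M`-muscle system.
#' @export
identity_surgery <- function(M) {
  structure(list(T = diag(M), kind = "none", w = NULL, w_prime = NULL,
                 n = NULL, angle = 0, I_diff = 0),
            class = "surgery_spec")
}

#' Current environment under a perturbation
#'
#' Virtual surgeries act in muscle space (`H T`: the pulling direction
#' of each muscle changes); the visuomotor rotation acts in force space
#' (`R(45deg CCW) H`); baseline and washout leave `H` unchanged.
#'
#' @param H baseline environment map.
#' @param perturbation one of `"none"`, `"rotation"`, or a
#'   `surgery_spec`.
#' @param rotation_angle rotation angle in radians (default 45 deg CCW).
#' @return the current `D x M` map.
#' @export
perturbed_environment <- function(H, perturbation = "none",
                                  rotation_angle = pi / 4) {
  if (inherits(perturbation, "surgery_spec")) {
    if (perturbation$kind == "none") return(H)
    return(H %*% perturbation$T)
  }
  switch(perturbation,
         none = H,
         rotation = {
           R <- matrix(c(cos(rotation_angle), sin(rotation_angle),
                         -sin(rotation_angle), cos(rotation_angle)), 2, 2)
           R %*% H
         },
         stop("unknown perturbation: ", perturbation))
}

## Uniform random unit vector inside the span of an orthonormal basis.
rand_unit_in <- function(B) {
  y <- stats::rnorm(ncol(B))
  v <- drop(B %*% y)
  v / sqrt(sum(v^2))
}
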