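## Small linear-algebra utilities shared across the package.
## Everything here operates on plain numeric matrices/vectors.

#' Orthonormal basis of the column space of a matrix
#'
#' @param A numeric matrix.
#' @param tol singular values below `tol * max(sv)` are treated as zero.
#' @return matrix whose columns are an orthonormal basis of `span(A)`;
#'   a zero-column matrix if `A` is (numerically) zero.
#' @keywords internal
orth_basis <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (ncol(A) == 0L) return(matrix(0, nrow(A), 0L))
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, .Machine$double.eps)
  sv$u[, keep, drop = FALSE]
}

#' Orthonormal basis of the null space of a matrix
#'
#' @inheritParams orth_basis
#' @return matrix whose columns span `null(A)` (vectors v with `A v = 0`).
#' @keywords internal
null_basis <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  n <- ncol(A)
  sv <- svd(A, nu = 0, nv = n)
  rank <- sum(sv$d > tol * max(sv$d, .Machine$double.eps))
  if (rank >= n) return(matrix(0, n, 0L))
  sv$v[, seq.int(rank + 1L, n), drop = FALSE]
}

#' Numerical rank via singular values
#' @keywords internal
mat_rank <- function(A, tol = 1e-8) {
  d <- svd(as.matrix(A), nu = 0, nv = 0)$d
  if (!length(d)) return(0L)
  sum(d > tol * max(d))
}

#' Do a set of force vectors positively span the force space?
#'
#' A set of vectors positively spans R^D when every direction is reachable
#' as a non-negative combination; equivalently the origin lies strictly
#' inside the convex hull of the directions. Implemented exactly for
#' D = 1 (both signs present) and D = 2 (largest angular gap between
#' sorted directions < 180 degrees).
#'
#' @param H `D x M` matrix whose columns are the vectors.
#' @return logical scalar.
#' @export
positively_spans <- function(H) {
  H <- as.matrix(H)
  D <- nrow(H)
  nz <- H[, colSums(abs(H)) > 0, drop = FALSE]
  if (ncol(nz) <= D) return(FALSE)
  if (D == 1L) return(any(nz > 0) && any(nz < 0))
  if (D == 2L) {
    ang <- sort(atan2(nz[2, ], nz[1, ]))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    return(max(gaps) < pi - 1e-12)
  }
  stop("positively_spans() is implemented for D = 1 or D = 2")
}

#' Minimum-norm non-negative muscle activation for a target force
#'
#' Solves the quadratic program
#' \deqn{\min_m \|m\|^2 \quad \mathrm{s.t.}\ H m = f,\ m \ge 0,}
#' the construction used both to define synergies at initialization and
#' to score the index of difficulty of a perturbation. The equality
#' constraints are eliminated first (the particular solution `H^+ f`
#' lies in the row space, orthogonal to the null space), which leaves a
#' least-distance program over null-space coordinates; that is solved by
#' the classical reduction to non-negative least squares.
#'
#' @param H `D x M` activation-to-force matrix.
#' @param f length-`D` target force.
#' @param tol feasibility tolerance on the equality residual.
#' @return length-`M` non-negative vector `m` with `H m = f`.
#'   Errors if the program is infeasible (e.g. `H` does not positively
#'   span the force space for this target).
#' @export
min_norm_activation <- function(H, f, tol = 1e-8) {
  H <- as.matrix(H)
  f <- as.numeric(f)
  stopifnot(nrow(H) == length(f))
  if (all(abs(f) < .Machine$double.eps)) return(numeric(ncol(H)))
  sv <- svd(H)
  pos <- sv$d > 1e-12 * max(sv$d)
  if (!all(pos)) stop("min_norm_activation(): H is rank deficient")
  m0 <- sv$v %*% ((crossprod(sv$u, f)) / sv$d)     # H^+ f, min-norm unconstrained
  m0 <- drop(m0)
  N <- null_basis(H)
  if (ncol(N) == 0L) {
    if (any(m0 < -tol)) stop("min_norm_activation(): infeasible (no null space)")
    return(pmax(m0, 0))
  }
  if (all(m0 >= 0)) return(m0)
  ## LDP: min ||z||  s.t.  N z >= -m0  (then m = m0 + N z, ||m||^2 = ||m0||^2 + ||z||^2)
  z <- solve_ldp(N, -m0)
  if (is.null(z)) stop("min_norm_activation(): infeasible non-negativity constraints")
  m <- m0 + drop(N %*% z)
  if (max(abs(H %*% m - f)) > tol * max(1, sqrt(sum(f^2)))) {
    stop("min_norm_activation(): equality residual exceeds tolerance")
  }
  pmax(m, 0)
}

## Least-distance program min ||z|| s.t. G z >= h, via NNLS (Lawson & Hanson).
## Returns NULL when the constraints are infeasible.
solve_ldp <- function(G, h, tol = 1e-10) {
  n <- ncol(G)
  E <- rbind(t(G), as.numeric(h))      # (n+1) x mcon
  g <- c(rep(0, n), 1)
  u <- pracma::lsqnonneg(E, g)$x
  r <- drop(E %*% u) - g
  rn <- sqrt(sum(r^2))
  if (rn < tol) return(NULL)
  -r[seq_len(n)] / r[n + 1L]
}
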