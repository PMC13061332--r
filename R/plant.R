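## Feedforward generation pathway: environment map H, synergy set W,
## RBF control policy (Z, grid), forward model Hhat, motor noise.

#' Random muscle-to-force environment
#'
#' Assigns each of the `M` muscles a random `D`-dimensional force vector
#' (direction uniform, norm uniform on `norm_range`), accepting only
#' draws whose columns positively span the force space so that every
#' force direction is reachable with non-negative activations.
#'
#' Two conditioning margins are applied. Draws whose largest angular
#' gap between adjacent muscle directions exceeds `max_gap_deg` are
#' rejected (near-degenerate spanning sets require activations with
#' norms far above the force norms). Draws for which any of the 8
#' standard targets needs a minimum-norm activation with norm above
#' `max_effort` are also rejected: the isometric task must be
#' performable with activations commensurate with the force demands,
#' which keeps the learner inside the stable dynamic range of the
#' forward-model update.
#'
#' @param D force dimensionality (default 2).
#' @param M number of muscles (default 10).
#' @param norm_range interval for per-muscle force-vector norms.
#' @param max_gap_deg largest admissible angular gap between adjacent
#'   muscle force directions (default 150; 180 is bare positive span).
#' @param max_effort largest admissible minimum-norm activation norm
#'   over the 8 standard targets (default 0.9; `Inf` disables).
#' @param max_tries bounded resampling before giving up.
#' @return `D x M` matrix `H`.
#' @export
init_environment <- function(D = 2, M = 10, norm_range = c(0.5, 1.5),
                             max_gap_deg = 150, max_effort = 0.9,
                             max_tries = 1000L) {
  stopifnot(M > D, D >= 1)
  for (i in seq_len(max_tries)) {
    dirs <- matrix(stats::rnorm(D * M), D, M)
    dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
    norms <- stats::runif(M, norm_range[1], norm_range[2])
    H <- sweep(dirs, 2, norms, "*")
    ok <- if (D == 2L) {
      ang <- sort(atan2(H[2, ], H[1, ]))
      max(diff(c(ang, ang[1] + 2 * pi))) < max_gap_deg * pi / 180
    } else positively_spans(H)
    if (ok && D == 2L && is.finite(max_effort)) {
      tg <- target_set()
      eff <- vapply(seq_len(ncol(tg)), function(k)
        sqrt(sum(min_norm_activation(H, tg[, k])^2)), 0)
      ok <- max(eff) <= max_effort
    }
    if (ok) return(H)
  }
  stop("init_environment(): could not achieve a positively spanning set in ",
       max_tries, " attempts")
}

#' Initialize muscle synergies as minimum-norm activation patterns
#'
#' Draws `N` random force vectors that positively span the force space
#' (directions uniform, norms from the same interval as the muscle
#' forces) and takes each synergy to be the minimum-norm non-negative
#' activation pattern producing that force under `H`. Resamples the
#' force set if the synergy forces `H W` do not span the force space.
#'
#' A conditioning margin applies to the synergy-defining force
#' directions: with non-negative recruitment, a target inside a wide
#' angular gap of the synergy forces is reachable only through
#' ill-conditioned cancellation between the flanking synergies, and the
#' baseline task then fails to converge within the standard
#' pre-training budget. Requiring gaps below 120 degrees keeps the
#' recruitment well-conditioned for every target direction.
#'
#' @param H environment map.
#' @param N number of synergies (default 5).
#' @param norm_range norms of the synergy-defining force vectors.
#' @param max_gap_deg largest admissible angular gap between adjacent
#'   synergy force directions (default 120).
#' @param max_tries bounded resampling.
#' @return `M x N` non-negative synergy matrix `W` with `rank(H W) = D`.
#' @export
init_synergies <- function(H, N = 5, norm_range = c(0.5, 1.5),
                           max_gap_deg = 120, max_tries = 1000L) {
  D <- nrow(H)
  stopifnot(N >= D)
  for (i in seq_len(max_tries)) {
    dirs <- matrix(stats::rnorm(D * N), D, N)
    dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
    ok <- if (D == 2L) {
      ang <- sort(atan2(dirs[2, ], dirs[1, ]))
      max(diff(c(ang, ang[1] + 2 * pi))) < max_gap_deg * pi / 180
    } else positively_spans(dirs)
    if (!ok) next
    norms <- stats::runif(N, norm_range[1], norm_range[2])
    fk <- sweep(dirs, 2, norms, "*")
    W <- vapply(seq_len(N), function(k) min_norm_activation(H, fk[, k]),
                numeric(ncol(H)))
    ## W itself must have full column rank (nearby targets can share small
    ## active sets, making synergy columns linearly dependent)
    if (mat_rank(H %*% W) == D && mat_rank(W, tol = 1e-6) == N) return(W)
  }
  stop("init_synergies(): failed to obtain synergies spanning the force space")
}

#' Radial-basis-function grid over force space
#'
#' @param points_per_axis grid resolution per force dimension (default 11).
#' @param lim half-width of the square grid (centers span `[-lim, lim]`).
#' @param width Gaussian scale sigma, in force units. Defaults to 1.25
#'   times the grid spacing (0.25 with the default 11-point grid on
#'   `[-1, 1]`): wide enough that every target direction receives a
#'   usable learning gradient, narrow enough that the policy loop stays
#'   stable when command norms grow under a perturbation.
#' @return object of class `rbf_grid` with fields `centers` (`NPhi x 2`)
#'   and `width`.
#' @export
rbf_grid <- function(points_per_axis = 11, lim = 1,
                     width = 1.25 * 2 * lim / (points_per_axis - 1)) {
  ax <- seq(-lim, lim, length.out = points_per_axis)
  centers <- as.matrix(expand.grid(x = ax, y = ax))
  stopifnot(width > 0)
  structure(list(centers = unname(centers), width = width,
                 points_per_axis = points_per_axis, lim = lim),
            class = "rbf_grid")
}

#' Gaussian feature vector for a desired force
#'
#' `phi_j = exp(-||f* - center_j||^2 / (2 sigma^2))`.
#'
#' @param f_star desired force (length 2).
#' @param grid an [rbf_grid()].
#' @return numeric vector of length `NPhi`, entries in `(0, 1]`.
#' @export
rbf_features <- function(f_star, grid) {
  d2 <- colSums((t(grid$centers) - as.numeric(f_star))^2)
  exp(-d2 / (2 * grid$width^2))
}

#' Recruit synergies and compose the muscle command
#'
#' The noiseless feedforward chain `c = Z phi`, `m = W c` (all factors
#' non-negative, hence so are `c` and `m`).
#'
#' @param Z `N x NPhi` non-negative policy matrix.
#' @param W `M x N` non-negative synergy matrix.
#' @param phi feature vector.
#' @return list with `c` (synergy recruitment) and `m_command`.
#' @export
recruit_and_compose <- function(Z, W, phi) {
  stopifnot(ncol(Z) == length(phi), ncol(W) == nrow(Z))
  cc <- drop(Z %*% phi)
  list(c = cc, m_command = drop(W %*% cc))
}

#' Signal-dependent motor noise
#'
#' Adds independent Gaussian noise to each muscle with standard deviation
#' `cv` times that muscle's activation (variance quadratic in activation),
#' then clips negative activities to zero.
#'
#' @param m_command non-negative command pattern.
#' @param cv noise coefficient (0 disables noise).
#' @return executed pattern `m_exec >= 0`.
#' @export
apply_motor_noise <- function(m_command, cv = 0.1) {
  if (cv <= 0) return(m_command)
  pmax(0, m_command + stats::rnorm(length(m_command), 0, cv * m_command))
}

#' Execute a muscle pattern in the (possibly perturbed) environment
#' @param H_current current `D x M` map (including any active perturbation).
#' @param m_exec executed muscle pattern.
#' @return executed force `f = H m`.
#' @export
execute_force <- function(H_current, m_exec) {
  stopifnot(ncol(H_current) == length(m_exec))
  drop(H_current %*% m_exec)
}

#' Predict force with the internal forward model
#' @param Hhat learner's `D x M` estimate of the environment.
#' @param m muscle pattern (the executed efference copy).
#' @return predicted force `Hhat m`.
#' @export
predict_force <- function(Hhat, m) {
  stopifnot(ncol(Hhat) == length(m))
  drop(Hhat %*% m)
}
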