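## Independent oracles used across the test suite. These deliberately use
## brute-force or elementwise constructions, never the package's own
## linear-algebra paths.

## Exact minimum-norm non-negative solution of H m = f by active-set
## enumeration: every support set is tried, the equality-constrained
## minimum-norm solution on the support computed from the normal
## equations, and the best feasible candidate returned. Exponential in M;
## use only on small instances.
enum_min_norm <- function(H, f, tol = 1e-9) {
  M <- ncol(H)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^M - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(M) - 1)) > 0)
    if (length(free) < 1) {
      if (max(abs(f)) < tol) return(numeric(M))
      next
    }
    Hf <- H[, free, drop = FALSE]
    G <- Hf %*% t(Hf)
    if (abs(det(G)) < 1e-12) next
    mf <- drop(t(Hf) %*% solve(G, f))
    if (any(mf < -tol)) next
    m <- numeric(M)
    m[free] <- pmax(mf, 0)
    if (max(abs(H %*% m - f)) > tol * max(1, max(abs(f)))) next
    obj <- sum(m^2)
    if (obj < best_obj) { best <- m; best_obj <- obj }
  }
  best
}

## Matrix-vector product by explicit summation.
matvec_sum <- function(A, x) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    s <- 0
    for (j in seq_len(ncol(A))) s <- s + A[i, j] * x[j]
    out[i] <- s
  }
  out
}

## Central finite-difference gradient of a scalar function of a matrix.
fd_gradient <- function(fn, X, h = 1e-5) {
  G <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xm <- X
    Xp[i] <- Xp[i] + h
    Xm[i] <- Xm[i] - h
    G[i] <- (fn(Xp) - fn(Xm)) / (2 * h)
  }
  G
}

## Random small positively-spanning 2 x M environment.
rand_env_2d <- function(M = 6) {
  repeat {
    H <- matrix(stats::rnorm(2 * M), 2, M)
    if (positively_spans(H)) return(H)
  }
}

## A tiny pre-built model + surgery pair shared by several tests
## (computed lazily, once per test run).
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- synergy_model(cv = 0.1, seed = 424242)
      p <- build_surgery_pair(m, seed = 434343)
      cache <<- list(model = m, pair = p)
    }
    cache
  }
})
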