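## Gradient-oracle equivalence is the core test here: each update rule
## must match central finite differences of its objective, pre-clipping.

rand_instance <- function() {
  M <- sample(4:6, 1); N <- sample(2:3, 1); NPhi <- sample(4:6, 1)
  list(W = matrix(stats::runif(M * N, 1, 2), M, N),
       Z = matrix(stats::runif(N * NPhi, 1, 2), N, NPhi),
       Hhat = matrix(stats::rnorm(2 * M), 2, M),
       phi = stats::runif(NPhi),
       delta_f = stats::rnorm(2))
}

test_that("synergy update matches the finite-difference gradient oracle", {
  set.seed(101)
  cfg <- learning_config(eta_W = 1e-3, eta_Z = 1e-3, lambda_W = 0, lambda_Z = 0)
  for (i in 1:100) {
    inst <- rand_instance()
    with(inst, {
      ## target reconstructed so that the residual at W equals delta_f
      y <- drop(Hhat %*% W %*% Z %*% phi) - delta_f
      J <- function(Wx) 0.5 * sum((drop(Hhat %*% Wx %*% Z %*% phi) - y)^2)
      G <- fd_gradient(J, W)
      Wn <- update_synergies(W, Z, Hhat, delta_f, phi, cfg)
      step <- -(Wn - W) / cfg$eta_W     # entries large: clipping never fires
      expect_equal(step, G, tolerance = 1e-6)
    })
  }
})

test_that("policy update matches the finite-difference gradient oracle", {
  set.seed(102)
  cfg <- learning_config(eta_W = 1e-3, eta_Z = 1e-3, lambda_W = 0, lambda_Z = 0)
  for (i in 1:100) {
    inst <- rand_instance()
    with(inst, {
      y <- drop(Hhat %*% W %*% Z %*% phi) - delta_f
      J <- function(Zx) 0.5 * sum((drop(Hhat %*% W %*% Zx %*% phi) - y)^2)
      G <- fd_gradient(J, Z)
      Zn <- update_policy(W, Z, Hhat, delta_f, phi, cfg)
      expect_equal(-(Zn - Z) / cfg$eta_Z, G, tolerance = 1e-6)
    })
  }
})

test_that("forward-model update matches the finite-difference gradient oracle", {
  set.seed(103)
  cfg <- learning_config(eta_Hhat = 1e-3)
  for (i in 1:100) {
    M <- sample(4:6, 1)
    Hhat <- matrix(stats::rnorm(2 * M), 2, M)
    m <- stats::runif(M)
    delta_fp <- stats::rnorm(2)
    f <- drop(Hhat %*% m) - delta_fp
    J <- function(Hx) 0.5 * sum((drop(Hx %*% m) - f)^2)
    G <- fd_gradient(J, Hhat)
    Hn <- update_forward_model(Hhat, delta_fp, m, cfg)
    expect_equal(-(Hn - Hhat) / cfg$eta_Hhat, G, tolerance = 1e-6)
  }
})

test_that("trivial update cases behave as stated", {
  set.seed(104)
  inst <- rand_instance()
  zero <- c(0, 0)
  cfg0 <- learning_config(lambda_W = 0, lambda_Z = 0)
  expect_equal(update_synergies(inst$W, inst$Z, inst$Hhat, zero, inst$phi, cfg0),
               inst$W)
  expect_equal(update_policy(inst$W, inst$Z, inst$Hhat, zero, inst$phi, cfg0),
               inst$Z)
  ## pure shrinkage: W' = (1 - lambda) W
  cfgl <- learning_config(lambda_W = 0.01, lambda_Z = 0.02)
  expect_equal(update_synergies(inst$W, inst$Z, inst$Hhat, zero, inst$phi, cfgl),
               (1 - 0.01) * inst$W)
  expect_equal(update_policy(inst$W, inst$Z, inst$Hhat, zero, inst$phi, cfgl),
               (1 - 0.02) * inst$Z)
  ## frozen components
  cfgf <- learning_config(eta_Z = 0, lambda_Z = 0, eta_Hhat = 0)
  expect_equal(update_policy(inst$W, inst$Z, inst$Hhat, inst$delta_f, inst$phi,
                             cfgf), inst$Z)
  expect_equal(update_forward_model(inst$Hhat, inst$delta_f, stats::runif(ncol(inst$Hhat)),
                                    cfgf), inst$Hhat)
  expect_equal(update_forward_model(inst$Hhat, zero, stats::runif(ncol(inst$Hhat)),
                                    learning_config()), inst$Hhat)
})

test_that("one joint update with the true model never increases the error", {
  set.seed(105)
  cfg <- learning_config(eta_W = 1e-3, eta_Z = 1e-3, eta_Hhat = 0,
                         lambda_W = 0, lambda_Z = 0)
  for (i in 1:100) {
    M <- 6; N <- 3; NPhi <- 5
    H <- rand_env_2d(M)
    W <- matrix(stats::runif(M * N), M, N)
    Z <- matrix(stats::runif(N * NPhi), N, NPhi)
    phi <- stats::runif(NPhi)
    f_star <- stats::rnorm(2) * 0.5
    err <- function(Wx, Zx) sqrt(sum((drop(H %*% Wx %*% Zx %*% phi) - f_star)^2))
    delta_f <- drop(H %*% W %*% Z %*% phi) - f_star
    Wn <- update_synergies(W, Z, H, delta_f, phi, cfg)
    Zn <- update_policy(W, Z, H, delta_f, phi, cfg)
    expect_lte(err(Wn, Zn), err(W, Z) + 1e-12)
  }
})

test_that("shrinkage alone strictly decreases Frobenius norms toward zero", {
  set.seed(106)
  inst <- rand_instance()
  cfg <- learning_config(lambda_W = 0.05, lambda_Z = 0.05)
  W <- inst$W; Z <- inst$Z
  for (i in 1:10) {
    Wn <- update_synergies(W, Z, inst$Hhat, c(0, 0), inst$phi, cfg)
    Zn <- update_policy(W, Z, inst$Hhat, c(0, 0), inst$phi, cfg)
    expect_lt(norm(Wn, "F"), norm(W, "F"))
    expect_lt(norm(Zn, "F"), norm(Z, "F"))
    W <- Wn; Z <- Zn
  }
})

test_that("clipping is idempotent", {
  set.seed(107)
  X <- matrix(stats::rnorm(30), 5, 6)
  expect_identical(pmax(pmax(X, 0), 0), pmax(X, 0))
  ## and the updates always return non-negative matrices
  inst <- rand_instance()
  cfg <- learning_config(eta_W = 10, eta_Z = 10)   # force severe clipping
  Wn <- update_synergies(inst$W, inst$Z, inst$Hhat, inst$delta_f, inst$phi, cfg)
  Zn <- update_policy(inst$W, inst$Z, inst$Hhat, inst$delta_f, inst$phi, cfg)
  expect_true(all(Wn >= 0) && all(Zn >= 0))
})

test_that("sensitivity condition agrees with direct scalar evaluation", {
  set.seed(108)
  H <- rand_env_2d(5)
  df <- stats::rnorm(2)
  expect_true(sensitivity_condition(H, H, df))
  expect_false(sensitivity_condition(H, -H, df))
  for (i in 1:20) {
    Hhat <- matrix(stats::rnorm(10), 2, 5)
    val <- 0
    v1 <- matvec_sum(t(H), df); v2 <- matvec_sum(t(Hhat), df)
    val <- sum(v1 * v2)
    expect_identical(sensitivity_condition(H, Hhat, df), val > 0)
  }
})
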