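smoke_cycles <- c(baseline = 3, perturbation = 3, washout = 3)

test_that("schedule bookkeeping: phase lengths, cycle count, target coverage", {
  fit <- adapt_synergies("rotation", seed = 77, cv = 0.1, n_reps = 2,
                         cycles = smoke_cycles, pretrain_cycles = 4)
  rec <- fit$records[[1]]
  expect_equal(length(rec$cycle), sum(smoke_cycles) * 8)
  expect_equal(as.vector(table(rec$phase)[c("baseline", "perturbation", "washout")]),
               rep(24L, 3))
  ## every cycle holds each of the 8 targets exactly once
  for (ci in unique(rec$cycle)) {
    expect_equal(sort(rec$target[rec$cycle == ci]), 1:8)
  }
  ## cycle metrics rows: one per cycle; snapshots: one block per 3 cycles
  expect_equal(nrow(fit$cycle_metrics), sum(smoke_cycles))
  expect_equal(dim(fit$snapshots[[1]])[3], sum(smoke_cycles) %/% 3)
})

test_that("identical seeds give bit-identical runs", {
  f1 <- adapt_synergies("compatible", seed = 88, cv = 0.1, n_reps = 2,
                        cycles = smoke_cycles, pretrain_cycles = 4)
  f2 <- adapt_synergies("compatible", seed = 88, cv = 0.1, n_reps = 2,
                        cycles = smoke_cycles, pretrain_cycles = 4)
  expect_identical(f1$records, f2$records)
  expect_identical(f1$cycle_metrics, f2$cycle_metrics)
  expect_identical(coef(f1), coef(f2))
})

test_that("a frozen learner leaves the state untouched and is deterministic", {
  tw <- tiny_world()
  frozen <- learning_config(eta_W = 0, eta_Z = 0, eta_Hhat = 0,
                            lambda_W = 0, lambda_Z = 0)
  model <- tw$model; model$cv <- 0
  set.seed(1); out1 <- run_trial(model, 3, config = frozen)
  set.seed(1); out2 <- run_trial(model, 3, config = frozen)
  expect_identical(out1$record, out2$record)
  expect_identical(out1$model$W, model$W)
  expect_identical(out1$model$Z, model$Z)
  expect_identical(out1$model$Hhat, model$Hhat)
  expect_equal(out1$record$m_exec, out1$record$m_command)
})

test_that("run_trial applies the full chain and its record is consistent", {
  tw <- tiny_world()
  model <- tw$model; model$cv <- 0.1
  set.seed(5)
  out <- run_trial(model, 1, config = learning_config())
  r <- out$record
  expect_equal(r$m_command, drop(model$W %*% r$c), tolerance = 1e-12)
  expect_equal(r$f_exec, drop(model$H %*% r$m_exec), tolerance = 1e-12)
  expect_equal(r$delta_f, r$f_exec - model$targets[, 1], tolerance = 1e-12)
  expect_equal(r$delta_fp, r$f_pred - r$f_exec, tolerance = 1e-12)
  expect_true(all(r$m_exec >= 0) && all(r$c >= 0))
})

test_that("a converged true-model learner does not drift", {
  ## pre-train noise-free, then pin the forward model to the truth with
  ## no shrinkage: the policy is at a fixed point of the updates
  cfg0 <- learning_config(lambda_W = 0, lambda_Z = 0)
  model <- synergy_model(cv = 0, seed = 515151)
  trained <- pretrain(model, cfg0, 324, seed = 525252)
  ideal <- learning_config(lambda_W = 0, lambda_Z = 0,
                           ideal_forward_model = TRUE)
  out <- synlearn:::sim_cycles(trained$W, trained$Z, trained$Hhat, model$H,
                               model$Phi, model$targets, 13, 0, ideal)
  e <- out$dir_err_cycle
  expect_lt(mean(tail(e, 3)), mean(head(e, 3)) + 0.5)
})

test_that("conditions within an initialization share state and surgery pair", {
  m1 <- synergy_model(cv = 0.1, seed = substream_seed(99, "init", 1))
  m2 <- synergy_model(cv = 0.1, seed = substream_seed(99, "init", 1))
  expect_identical(m1$H, m2$H)
  expect_identical(m1$W0, m2$W0)
  expect_identical(m1$Z0, m2$Z0)
  p1 <- build_surgery_pair(m1, seed = substream_seed(99, "surgery", 1))
  p2 <- build_surgery_pair(m2, seed = substream_seed(99, "surgery", 1))
  expect_identical(p1$incompatible$T, p2$incompatible$T)
  expect_identical(p1$compatible$T, p2$compatible$T)
})

test_that("a null experiment shows no systematic error trend across phases", {
  slopes <- vapply(1:6, function(i) {
    fit <- adapt_synergies("none", seed = substream_seed(1234, i), cv = 0.1,
                           n_reps = 2,
                           cycles = c(baseline = 8, perturbation = 8,
                                      washout = 8),
                           pretrain_cycles = 120, keep_records = FALSE)
    pm <- fit$cycle_metrics
    unname(stats::coef(stats::lm(direction_error ~ cycle, pm))[2])
  }, 0)
  ci <- mean(slopes) + c(-1, 1) * stats::qt(0.975, 5) * stats::sd(slopes) / sqrt(6)
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("batch smoke profile runs end to end with the full grid shape", {
  b <- run_batch(simulation = 2, n_init = 2, seed = 7, n_reps = 2,
                 cycles = smoke_cycles, pretrain_cycles = 4)
  cm <- b$cycle_metrics
  expect_equal(nrow(cm), 2 * 3 * 3 * sum(smoke_cycles))
  expect_setequal(unique(cm$condition), c("fm_off", "fm_slow", "fm_ideal"))
  expect_setequal(unique(cm$perturbation),
                  c("rotation", "compatible", "incompatible"))
  expect_equal(nrow(b$surgeries), 2)
  ## simulation presets expose the documented parameter grids
  s1 <- simulation_conditions(1)
  expect_equal(length(s1), 3)
  expect_equal(s1$Z_only$eta_W, 0)
  expect_equal(s1$both$eta_Z, 0.05)
  s2 <- simulation_conditions(2)
  expect_true(s2$fm_ideal$ideal_forward_model)
  expect_equal(s2$fm_off$eta_Hhat, 0)
  s3 <- simulation_conditions(3)
  expect_equal(s3$no_reg$lambda_W, 0)
  expect_equal(s3$reg$lambda_W, 5e-4)
  expect_error(simulation_conditions(9), "unknown")
})

test_that("the ideal forward model nulls the prediction error", {
  fit <- adapt_synergies("incompatible", seed = 99, cv = 0,
                         config = learning_config(ideal_forward_model = TRUE),
                         n_reps = 1, cycles = smoke_cycles, pretrain_cycles = 4)
  expect_lt(max(fit$cycle_metrics$prediction_error), 1e-12)
})
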