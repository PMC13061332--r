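## Trial-by-trial update rules: gradient steps on the squared force error
## backpropagated through the forward model, with L2 shrinkage and
## non-negativity clipping for W and Z, and a prediction-error-driven
## update for the forward model itself.

#' Learning-rate and regularization configuration
#'
#' Defaults follow the main simulations: policy and synergy learning
#' rates 0.05, forward-model learning rate 0.25, regularization weights
#' 1% of the corresponding learning rate.
#'
#' @param eta_W,eta_Z,eta_Hhat scalar learning rates (>= 0).
#' @param lambda_W,lambda_Z scalar regularization weights (>= 0).
#' @param ideal_forward_model logical; if `TRUE` the forward model is
#'   pinned to the current (possibly perturbed) environment each trial.
#' @return a `learning_config` list.
#' @export
learning_config <- function(eta_W = 0.05, eta_Z = 0.05, eta_Hhat = 0.25,
                            lambda_W = 0.01 * eta_W,
                            lambda_Z = 0.01 * eta_Z,
                            ideal_forward_model = FALSE) {
  stopifnot(eta_W >= 0, eta_Z >= 0, eta_Hhat >= 0,
            lambda_W >= 0, lambda_Z >= 0)
  structure(list(eta_W = eta_W, eta_Z = eta_Z, eta_Hhat = eta_Hhat,
                 lambda_W = lambda_W, lambda_Z = lambda_Z,
                 ideal_forward_model = isTRUE(ideal_forward_model)),
            class = "learning_config")
}

#' Update the synergy matrix from the force error
#'
#' `W' = clip0(W - eta_W * Hhat' df phi' Z' - lambda_W * W)`; negative
#' entries are set to zero after the full (gradient + shrinkage) step.
#'
#' @param W,Z current synergy and policy matrices.
#' @param Hhat forward model used to backpropagate the error.
#' @param delta_f force error `f - f*`.
#' @param phi feature vector of the trial's target.
#' @param config a [learning_config()].
#' @return updated `W`.
#' @export
update_synergies <- function(W, Z, Hhat, delta_f, phi, config) {
  grad <- crossprod(Hhat, delta_f) %*% crossprod(phi, t(Z))  # M x N
  pmax(W - config$eta_W * grad - config$lambda_W * W, 0)
}

#' Update the policy matrix from the force error
#'
#' `Z' = clip0(Z - eta_Z * W' Hhat' df phi' - lambda_Z * Z)`.
#'
#' @inheritParams update_synergies
#' @return updated `Z`.
#' @export
update_policy <- function(W, Z, Hhat, delta_f, phi, config) {
  grad <- crossprod(W, crossprod(Hhat, delta_f)) %*% t(phi)  # N x NPhi
  pmax(Z - config$eta_Z * grad - config$lambda_Z * Z, 0)
}

#' Update the forward model from the prediction error
#'
#' `Hhat' = Hhat - eta_Hhat * dfp m'` where `dfp = f_pred - f_exec` and
#' `m` is the executed (efference-copy) pattern. No clipping: the
#' forward model may take either sign.
#'
#' @param Hhat current forward model.
#' @param delta_fp prediction error.
#' @param m_exec executed muscle pattern.
#' @param config a [learning_config()].
#' @return updated `Hhat`.
#' @export
update_forward_model <- function(Hhat, delta_fp, m_exec, config) {
  Hhat - config$eta_Hhat * tcrossprod(delta_fp, m_exec)
}

#' Sensitivity condition for error reduction
#'
#' Diagnostic: the update direction given by the forward model reduces
#' the squared force error (to first order) when
#' `df' H Hhat' df > 0`, i.e. the backpropagated error through the
#' estimate has an angle below 90 degrees with the true one.
#'
#' @param H_current true current environment map.
#' @param Hhat forward model.
#' @param delta_f force error.
#' @return logical scalar.
#' @export
sensitivity_condition <- function(H_current, Hhat, delta_f) {
  drop(crossprod(delta_f, H_current %*% crossprod(Hhat, delta_f))) > 0
}
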