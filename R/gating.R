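#' Create a TD critic
#'
#' The adaptive-gating unit computes a value estimate `V(t)` as a learned
#' linear readout of PFC activations plus a learned intercept (so that the
#' reward expectation generalises across PFC states); weights and
#' intercept are trained by TD(0) using the (kappa-scaled) TD error.
#'
#' @param n_pfc number of PFC units (length of the weight vector).
#' @param gamma discount factor in `[0, 1)`.
#' @param kappa dopamine efficacy in `(0, 1]`; 1 models typical modulation,
#'   values below 1 attenuate the TD error everywhere it is used.
#' @param alpha critic learning rate.
#' @return an object of class `xt_critic`.
#' @export
new_critic <- function(n_pfc = 20, gamma = 0.9, kappa = 1, alpha = 0.2) {
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]")
  structure(list(weights = numeric(n_pfc), bias = 0, gamma = gamma,
                 kappa = kappa, alpha = alpha, value_prev = 0,
                 value_curr = 0),
            class = "xt_critic")
}

#' Critic value estimate
#'
#' `V = sum(weights * activations) + bias`: the expected reward given the
#' current PFC state.
#'
#' @param critic an `xt_critic`.
#' @param pfc_activations PFC activation vector.
#' @return scalar value estimate.
#' @export
compute_value <- function(critic, pfc_activations) {
  stopifnot(inherits(critic, "xt_critic"))
  if (length(pfc_activations) != length(critic$weights))
    stop("PFC activation length does not match critic weights")
  sum(critic$weights * pfc_activations) + critic$bias
}

#' Kappa-scaled TD error
#'
#' `delta = kappa * (r + gamma * v_t1 - v_t)`.  With perfect prediction
#' (`v_t = r + gamma * v_t1`) the error is exactly zero for any kappa, and
#' the error is exactly linear in kappa.
#'
#' @param r reward delivered this step.
#' @param v_t value estimate before the outcome.
#' @param v_t1 value estimate for the next step (0 at trial end).
#' @param gamma discount factor in `[0, 1)`.
#' @param kappa dopamine efficacy in `(0, 1]`.
#' @return the scalar TD error.
#' @export
compute_td_error <- function(r, v_t, v_t1 = 0, gamma = 0.9, kappa = 1) {
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]")
  kappa * (r + gamma * v_t1 - v_t)
}

#' Classify the gate action for a TD error
#'
#' Positive errors strengthen the current PFC representation, negative
#' errors destabilise it, and errors within `tol` of zero hold.
#'
#' @param delta TD error.
#' @param tol zero band (default 1e-9).
#' @param kappa the dopamine efficacy that produced `delta` (recorded so
#'   the exploration floor of [apply_gate()] can be scaled consistently).
#' @return a list of class `xt_gate_signal` with `delta` and `action`
#'   (`"strengthen"`, `"destabilize"` or `"hold"`).
#' @export
classify_gate <- function(delta, tol = 1e-9, kappa = 1) {
  action <- if (delta > tol) "strengthen"
            else if (delta < -tol) "destabilize"
            else "hold"
  structure(list(delta = delta, action = action, kappa = kappa),
            class = "xt_gate_signal")
}

#' TD(0) update of the critic weights
#'
#' `weights <- weights + alpha * delta * pfc_activations_prev`.  `delta` is
#' already kappa-scaled, so reduced dopamine efficacy also slows value
#' learning.
#'
#' @param critic an `xt_critic`.
#' @param delta TD error.
#' @param pfc_activations_prev PFC activations that produced `V(t)`.
#' @return the updated critic.
#' @export
update_critic <- function(critic, delta, pfc_activations_prev) {
  stopifnot(inherits(critic, "xt_critic"))
  if (length(pfc_activations_prev) != length(critic$weights))
    stop("PFC activation length does not match critic weights")
  critic$weights <- critic$weights + critic$alpha * delta * pfc_activations_prev
  critic$bias <- critic$bias + critic$alpha * delta
  critic
}

# The gate signal's kappa, when recorded by the caller; defaults to 1.
kappa_of <- function(signal) signal$kappa %||% 1

#' Apply the adaptive gate to PFC maintenance
#'
#' Strengthen: the maintenance current of currently active PFC units is set
#' to `maintenance_gain` (all others zeroed) and any pending noise is
#' cleared; maintenance then persists until destabilised.  Destabilise: maintenance currents are attenuated and seeded
#' Gaussian noise is scheduled for the PFC net inputs on the next settle so
#' that a new representation can be sampled; both the attenuation and the
#' noise amplitude are graded by the gate magnitude
#' `g = min(1, |delta|)` — the behavioural expression of dopamine efficacy.
#' Hold: no change.
#'
#' Noise is drawn from the caller's R random stream; seed upstream for
#' reproducibility.
#'
#' @param net an `xt_network`.
#' @param signal an `xt_gate_signal` from [classify_gate()].
#' @param pfc_activations PFC activations of the settle that produced the
#'   gated response.
#' @param maintenance_gain maintenance current for strengthened units.
#' @param noise_sd base standard deviation of destabilisation noise.
#' @return the updated network.
#' @export
apply_gate <- function(net, signal, pfc_activations = NULL,
                       maintenance_gain = NULL, noise_sd = NULL) {
  stopifnot(inherits(net, "xt_network"), inherits(signal, "xt_gate_signal"))
  cfg <- net$config
  maintenance_gain <- maintenance_gain %||% cfg$maintenance_gain
  noise_sd <- noise_sd %||% cfg$noise_sd
  if (signal$action == "strengthen") {
    if (is.null(pfc_activations))
      stop("strengthening requires the current PFC activations")
    net$maintenance <- ifelse(pfc_activations > cfg$a_on,
                              maintenance_gain, 0)
    net$noise_pending <- numeric(cfg$n_pfc)
  } else if (signal$action == "destabilize") {
    g <- min(1, max(abs(signal$delta), kappa_of(signal) * cfg$gate_floor))
    g <- g^cfg$gate_power
    net$maintenance <- net$maintenance * (1 - g)
    kick <- rnorm(cfg$n_pfc, 0, noise_sd * g)
    if (cfg$kick_width > 0 && cfg$kick_width < cfg$n_pfc) {
      keep <- order(abs(kick), decreasing = TRUE)[seq_len(cfg$kick_width)]
      focal <- numeric(cfg$n_pfc)
      focal[keep] <- abs(kick[keep])
      kick <- focal
    }
    net$noise_pending <- kick
  }
  net
}
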