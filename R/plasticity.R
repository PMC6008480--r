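#' Parameters of the memristive plasticity rule
#'
#' Constructs and validates the constant set governing the voltage-based,
#' weight-dependent synaptic update rule.  A synapse carries a normalized
#' conductance (weight) \eqn{\omega \in [\omega_{min}, \omega_{max}]}.
#' Whenever the pre-synaptic neuron spikes the weight moves along a modified
#' logistic flow
#' \deqn{f(\omega, V_{post}) = k\,(V_{post} - V_{critical})\,
#'       \omega^2 (1 - \omega/\omega_{max}),}
#' applied as one forward-Euler event of duration `tau_event` together with a
#' linear leak \eqn{-\kappa\omega}; between events only the leak acts
#' (see [decay()]).  The post-synaptic membrane potential alone signs the
#' update: depolarized partners (\eqn{V_{post} > V_{critical}}) are
#' potentiated, hyperpolarized partners depressed.
#'
#' @param k learning-rate constant, per ms.  Default 1.21.
#' @param kappa forgetting (leak) rate, per ms.  Default `4.17e-6` per ms,
#'   i.e. 0.417 % per second, the retention loss used for the network
#'   simulations.
#' @param omega_min,omega_max weight bounds (dimensionless normalized
#'   conductance).  The lower clamp protects a silent connection from being
#'   lost for all time; the logistic factor makes `omega_max` a fixed point.
#' @param V_critical set-point voltage separating potentiation from
#'   depression, in volts.
#' @param tau_event effective duration of one spike-triggered update event,
#'   in ms.  Default 0.15 ms (roughly the width of an action-potential
#'   peak); together with `t_ref` this is the rule's calibration constant,
#'   chosen once so the pair-frequency protocols reproduce the
#'   electrophysiological anchor points (see the package vignette).
#' @param V_clamp_low,V_clamp_high admissible range for clamped
#'   post-synaptic potentials, in volts (used by [voltage_clamp()]).
#'
#' @return An object of class `plasticity_params` (a named list).
#' @seealso [learning_rate()], [drift()], [spike_update()], [decay()]
#' @examples
#' p <- plasticity_params()
#' drift(0.5, 0.06175, p)
#' @export
plasticity_params <- function(k = 1.21, kappa = 4.17e-6,
                              omega_min = 0.05, omega_max = 1.0,
                              V_critical = 0, tau_event = 0.15,
                              V_clamp_low = -0.011, V_clamp_high = 0.06175) {
  p <- list(k = k, kappa = kappa, omega_min = omega_min,
            omega_max = omega_max, V_critical = V_critical,
            tau_event = tau_event, V_clamp_low = V_clamp_low,
            V_clamp_high = V_clamp_high)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("plasticity parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (p$k <= 0) stop("k must be > 0", call. = FALSE)
  if (p$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (!(p$omega_min >= 0 && p$omega_min < p$omega_max && p$omega_max <= 1))
    stop("weight bounds must satisfy 0 <= omega_min < omega_max <= 1",
         call. = FALSE)
  if (p$tau_event <= 0) stop("tau_event must be > 0", call. = FALSE)
  if (!(p$V_clamp_low <= p$V_critical && p$V_critical <= p$V_clamp_high))
    stop("V_critical must lie within [V_clamp_low, V_clamp_high]",
         call. = FALSE)
  structure(p, class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("Memristive plasticity parameters\n")
  cat(sprintf("  k           %g /ms\n", x$k))
  cat(sprintf("  kappa       %g /ms (%.3g %%/s)\n", x$kappa, x$kappa * 1e5))
  cat(sprintf("  omega       [%g, %g]\n", x$omega_min, x$omega_max))
  cat(sprintf("  V_critical  %g V\n", x$V_critical))
  cat(sprintf("  tau_event   %g ms\n", x$tau_event))
  invisible(x)
}

check_v <- function(V_post) {
  if (!is.numeric(V_post) || any(!is.finite(V_post)))
    stop("V_post must be finite", call. = FALSE)
  V_post
}

check_w <- function(omega, params) {
  if (!is.numeric(omega) || any(!is.finite(omega)))
    stop("omega must be finite", call. = FALSE)
  if (any(omega < params$omega_min - 1e-12 | omega > params$omega_max + 1e-12))
    stop("omega outside [omega_min, omega_max]", call. = FALSE)
  omega
}

#' Voltage- and weight-dependent synaptic learning rate
#'
#' \eqn{\beta = k\,\omega\,(V_{post} - V_{critical})}, in per-ms units with
#' `V_post` entering as its numeric value in volts.  The sign of `beta`
#' equals the sign of the post-synaptic potential relative to the set point.
#'
#' @param omega synaptic weight(s) in `[omega_min, omega_max]`.
#' @param V_post post-synaptic membrane potential, volts.
#' @param params a [plasticity_params()] object.
#' @return Learning rate(s), per ms.  Vectorized over `omega` and `V_post`.
#' @export
learning_rate <- function(omega, V_post, params = plasticity_params()) {
  check_w(omega, params); check_v(V_post)
  params$k * omega * (V_post - params$V_critical)
}

#' Logistic weight-change flow of the plasticity rule
#'
#' \eqn{f = \beta\,\omega\,(1 - \omega/\omega_{max})
#'        = k (V_{post}-V_{critical})\,\omega^2 (1-\omega/\omega_{max})}.
#' Exactly zero at \eqn{\omega = 0} and \eqn{\omega = \omega_{max}} (the
#' stable ends of the modified logistic equation); for a fixed depolarized
#' potential the flow is largest at mid-range weights
#' (analytic maximum at \eqn{2\omega_{max}/3}).
#'
#' @inheritParams learning_rate
#' @return Rate of weight change, per ms.
#' @export
drift <- function(omega, V_post, params = plasticity_params()) {
  check_v(V_post)
  if (!is.numeric(omega) || any(!is.finite(omega)))
    stop("omega must be finite", call. = FALSE)
  params$k * (V_post - params$V_critical) * omega^2 *
    (1 - omega / params$omega_max)
}

#' Apply one spike-triggered weight update event
#'
#' Invoked at a pre-synaptic spike time: one forward-Euler step of
#' \eqn{d\omega/dt = f(\omega, V_{post}) - \kappa\omega} over the event
#' duration `tau_event`, clamped to the weight bounds.
#'
#' @inheritParams learning_rate
#' @return Updated weight(s), clamped to `[omega_min, omega_max]`.
#' @export
spike_update <- function(omega, V_post, params = plasticity_params()) {
  check_w(omega, params); check_v(V_post)
  dw <- (drift(omega, V_post, params) - params$kappa * omega) *
    params$tau_event
  pmin(params$omega_max, pmax(params$omega_min, omega + dw))
}

#' Continuous weight leak between spike events
#'
#' Exact integration of \eqn{d\omega/dt = -\kappa\omega} over `dt`
#' milliseconds: \eqn{\omega \leftarrow \omega e^{-\kappa\,dt}}, clamped at
#' the lower weight bound.  Models both the continuous depression seen in
#' physiological synapses and the retention loss of memristive devices.
#'
#' @inheritParams learning_rate
#' @param dt elapsed time since the last event, ms (`dt >= 0`).
#' @return Decayed weight(s).
#' @export
decay <- function(omega, dt, params = plasticity_params()) {
  check_w(omega, params)
  if (any(dt < 0)) stop("dt must be >= 0", call. = FALSE)
  pmin(params$omega_max,
       pmax(params$omega_min, omega * exp(-params$kappa * dt)))
}
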