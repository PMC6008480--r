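#' Parameters of the quadratic integrate-and-fire neuron
#'
#' The membrane potential obeys
#' \deqn{C\,du/dt = \tilde g_L (u - u_{rest})(u - u_{critical}) + I(t),}
#' a quadratic nonlinearity with a stable resting potential, an unstable
#' critical potential above which a spike is self-induced, and a hard
#' threshold \eqn{\theta_{thres}} at which the spike is registered and the
#' membrane reset to \eqn{u_{rest}} for a refractory period `t_ref`.
#'
#' Internally all electrical quantities are SI (volts, amperes, farads,
#' \eqn{\tilde g_L} in A/V\eqn{^2}); protocol clocks are in milliseconds.
#'
#' @param C membrane capacitance, farads (default 1 mF).
#' @param g_L leak coefficient \eqn{\tilde g_L}, A/V^2 (default 1).
#' @param u_rest resting potential, volts (default -11 mV).
#' @param u_critical critical potential for self-induced spiking, volts
#'   (default 9 mV).
#' @param theta_thres spiking threshold, volts (default 61.75 mV).
#' @param t_ref absolute refractory period, ms, during which the membrane is
#'   held at `u_rest`.  Default 6.44 ms, calibrated once so that the
#'   post-pre pair-frequency protocol changes sign at 40 Hz (see the
#'   package vignette).
#' @return An object of class `neuron_params`.
#' @seealso [membrane_derivative()], [rk4_step()], [rheobase()],
#'   [current_for_rate()]
#' @export
neuron_params <- function(C = 1e-3, g_L = 1, u_rest = -0.011,
                          u_critical = 0.009, theta_thres = 0.06175,
                          t_ref = 6.44) {
  p <- list(C = C, g_L = g_L, u_rest = u_rest, u_critical = u_critical,
            theta_thres = theta_thres, t_ref = t_ref)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("neuron parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (p$C <= 0 || p$g_L <= 0) stop("C and g_L must be > 0", call. = FALSE)
  if (p$t_ref < 0) stop("t_ref must be >= 0", call. = FALSE)
  if (!(p$u_rest < p$u_critical && p$u_critical < p$theta_thres))
    stop("need u_rest < u_critical < theta_thres", call. = FALSE)
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("QIF neuron parameters\n")
  cat(sprintf("  theta_thres %g mV\n", x$theta_thres * 1e3))
  cat(sprintf("  u_critical  %g mV\n", x$u_critical * 1e3))
  cat(sprintf("  u_rest      %g mV\n", x$u_rest * 1e3))
  cat(sprintf("  C           %g F,  g_L %g A/V^2\n", x$C, x$g_L))
  cat(sprintf("  t_ref       %g ms\n", x$t_ref))
  invisible(x)
}

#' Membrane potential derivative of the QIF model
#'
#' @param u membrane potential(s), volts.
#' @param I input current, amperes.
#' @param params a [neuron_params()] object.
#' @return du/dt in V/s.  Zero at `u_rest` and `u_critical` when `I = 0`.
#' @export
membrane_derivative <- function(u, I, params = neuron_params()) {
  if (any(!is.finite(u)) || any(!is.finite(I)))
    stop("u and I must be finite", call. = FALSE)
  (params$g_L * (u - params$u_rest) * (u - params$u_critical) + I) / params$C
}

#' Fresh dynamic state for a single QIF neuron
#'
#' @param params a [neuron_params()] object.
#' @param u initial membrane potential, volts (default `u_rest`).
#' @return A list with elements `u`, `refractory_remaining` (ms) and
#'   `spike_flag`.
#' @export
neuron_state <- function(params = neuron_params(), u = params$u_rest) {
  list(u = u, refractory_remaining = 0, spike_flag = FALSE)
}

#' One classical Runge-Kutta (RK4) step of the QIF membrane
#'
#' Advances the membrane one step of size `dt` under the input current
#' `I_of_t` (a constant or a function of time in ms).  If the updated
#' potential reaches `theta_thres` a spike is flagged, the membrane is reset
#' to `u_rest` and held there for `t_ref` (threshold crossings are resolved
#' at step end).  During refractoriness the dynamics are suspended.
#'
#' @param state a [neuron_state()] list.
#' @param I_of_t input current in amperes: a single number or a function
#'   `I(t_ms)`.
#' @param dt step size, ms (> 0).
#' @param params a [neuron_params()] object.
#' @param t current time, ms (only used to evaluate a time-dependent
#'   current).
#' @return The updated state list.
#' @export
rk4_step <- function(state, I_of_t, dt, params = neuron_params(), t = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  Ifun <- if (is.function(I_of_t)) I_of_t else function(tt) I_of_t
  state$spike_flag <- FALSE
  if (state$refractory_remaining > 0) {
    state$u <- params$u_rest
    state$refractory_remaining <- max(0, state$refractory_remaining - dt)
    return(state)
  }
  dt_s <- dt * 1e-3
  f <- function(u, I) membrane_derivative(u, I, params)
  k1 <- f(state$u, Ifun(t))
  k2 <- f(state$u + dt_s * k1 / 2, Ifun(t + dt / 2))
  k3 <- f(state$u + dt_s * k2 / 2, Ifun(t + dt / 2))
  k4 <- f(state$u + dt_s * k3, Ifun(t + dt))
  u_new <- state$u + dt_s * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  if (u_new >= params$theta_thres) {
    state$spike_flag <- TRUE
    state$u <- params$u_rest
    state$refractory_remaining <- params$t_ref
  } else {
    state$u <- u_new
  }
  state
}

#' Minimal constant current for self-sustained spiking
#'
#' The quadratic nullcline has its maximum midway between `u_rest` and
#' `u_critical`; the rheobase is
#' \eqn{\tilde g_L ((u_{critical} - u_{rest})/2)^2}.  With the default
#' parameters this is 0.1 mA.
#'
#' @param params a [neuron_params()] object.
#' @return Current in amperes.
#' @export
rheobase <- function(params = neuron_params()) {
  params$g_L * ((params$u_critical - params$u_rest) / 2)^2
}

#' Simulate a single QIF neuron
#'
#' Fixed-step RK4 integration (threshold detected at step end) of one
#' neuron under a constant or piecewise-constant current.
#'
#' @param I input current, amperes: a single number, or a two-column
#'   structure `cbind(duration_ms, current_A)` of consecutive segments.
#' @param duration_ms simulated time, ms (for a single-number `I`).
#' @param params a [neuron_params()] object.
#' @param dt integration step, ms.
#' @param u0 initial membrane potential, volts.
#' @param record_trace return the membrane trace as well.
#' @return A list with `spikes` (spike times, ms) and, if requested,
#'   `trace` (`data.frame(t_ms, u)`).
#' @export
qif_simulate <- function(I, duration_ms = NULL, params = neuron_params(),
                         dt = 0.05, u0 = params$u_rest,
                         record_trace = FALSE) {
  if (is.matrix(I)) {
    seg_dur <- I[, 1]; seg_I <- matrix(I[, 2], ncol = 1)
  } else {
    if (is.null(duration_ms))
      stop("duration_ms required for a constant current", call. = FALSE)
    seg_dur <- duration_ms; seg_I <- matrix(I, ncol = 1)
  }
  res <- .engine_run(matrix(0, 1, 1), unclass(params),
                     unclass(plasticity_params()),
                     seg_dur, seg_I, 1L, dt, 0, dt, FALSE, 0,
                     record_trace, 1L, u0)
  out <- list(spikes = res$spike_t, duration_ms = res$duration_ms)
  if (record_trace)
    out$trace <- data.frame(t_ms = res$trace_t, u = res$traces[, 1])
  out
}

steady_period <- function(spikes) {
  n <- length(spikes)
  if (n < 4) return(NA_real_)
  mean(diff(spikes[(n - 2):n]))
}

#' Constant current producing a target steady-state firing rate
#'
#' Bisection on the simulated free-running firing rate of a single QIF
#' neuron.  Used to build rate-coded stimuli ("the input current to the
#' spiking neurons has been varied" across target frequencies).
#'
#' @param target_rate desired firing rate, Hz (> 0).
#' @param params a [neuron_params()] object.
#' @param dt integration step, ms.
#' @param tol relative rate tolerance of the bisection (default 1 %).
#' @return Current in amperes whose steady firing rate is within `tol` of
#'   `target_rate`.
#' @export
current_for_rate <- function(target_rate, params = neuron_params(),
                             dt = 0.05, tol = 0.01) {
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("target_rate must be > 0", call. = FALSE)
  target_T <- 1000 / target_rate                       # ms
  if (target_T <= params$t_ref + 2 * dt)
    stop("target_rate unreachable: period below the refractory period",
         call. = FALSE)
  sim_T <- function(I) {
    dur <- max(400, 6 * target_T)
    s <- qif_simulate(I, dur, params, dt)$spikes
    if (length(s) < 4) Inf else steady_period(s)
  }
  lo <- rheobase(params)          # period Inf (no repetitive firing)
  hi <- lo * 2
  while (is.infinite(sim_T(hi)) || sim_T(hi) > target_T) {
    hi <- hi * 2
    if (hi > 1e4) stop("bisection failed to bracket the target rate",
                       call. = FALSE)
  }
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    Tm <- sim_T(mid)
    if (is.infinite(Tm) || Tm > target_T) lo <- mid else hi <- mid
    if (is.finite(Tm) && abs(Tm - target_T) / target_T < tol * 0.25) break
  }
  (lo + hi) / 2
}

# steady-state membrane trajectory over one firing period, phase-locked to
# the spike: returns an interpolation function u(phi_ms), phi in [0, T)
qif_phase_trajectory <- function(I, params = neuron_params(), dt = 0.05,
                                 period_hint = NULL) {
  dur <- if (is.null(period_hint)) 400 else max(400, 5.5 * period_hint)
  warmup <- qif_simulate(I, dur, params, dt)
  s <- warmup$spikes
  if (length(s) < 4) {
    sim <- qif_simulate(I, max(6000, 4 * dur), params, dt,
                        record_trace = TRUE)
    s <- sim$spikes
    if (length(s) < 3) stop("current does not drive repetitive firing",
                            call. = FALSE)
  } else {
    need <- s[length(s)] + 1.2 * steady_period(s) + 10
    sim <- qif_simulate(I, need, params, dt, record_trace = TRUE)
    s <- sim$spikes
  }
  n <- length(s)
  t0 <- s[n - 1]; t1 <- s[n]
  tr <- sim$trace
  keep <- tr$t_ms >= t0 & tr$t_ms < t1
  phi <- tr$t_ms[keep] - t0
  uu <- tr$u[keep]
  Tper <- t1 - t0
  fun <- stats::approxfun(phi, uu, rule = 2)
  list(period_ms = Tper, u_of_phase = fun)
}
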