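#' @name protocols
#' @title Single-synapse plasticity protocols
#'
#' @description
#' Drivers reproducing the classical cellular plasticity experiments on a
#' single pre/post pair: pre-synaptic stimulation under post-synaptic
#' voltage clamp, the pair-based spike-timing window, and pair-frequency
#' curves.  In all protocols the synapse starts at half of its maximal
#' conductance (\eqn{\omega_0 = 0.5}) and the reported quantity is the
#' relative weight change \eqn{100\,(\omega_{final} - \omega_0)/\omega_0}
#' in percent.
#'
#' In the pairing protocols the post-synaptic neuron is driven by a
#' constant current whose free-running firing period equals the pairing
#' period (found by [current_for_rate()]), so that its membrane ramps from
#' reset through negative values to a depolarized upstroke before each
#' spike; pre-synaptic spikes are imposed events that read the
#' post-synaptic membrane at their arrival phase.  `leak_mode` selects
#' whether the weight decays continuously between spike events
#' (`"on"`) or is held constant (`"off"`, in which case `kappa` is ignored
#' entirely).
NULL

protocol_result <- function(df, protocol, meta) {
  structure(df, class = c("protocol_result", class(df)),
            protocol = protocol, meta = meta)
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("Protocol '%s' (%d grid points)\n", attr(x, "protocol"),
              nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

kappa_eff <- function(plast, leak_mode) {
  if (identical(leak_mode, "on")) plast
  else plasticity_params(k = plast$k, kappa = 0,
                         omega_min = plast$omega_min,
                         omega_max = plast$omega_max,
                         V_critical = plast$V_critical,
                         tau_event = plast$tau_event,
                         V_clamp_low = plast$V_clamp_low,
                         V_clamp_high = plast$V_clamp_high)
}

#' Pre-synaptic stimulation under post-synaptic voltage clamp
#'
#' The post-synaptic potential is fixed to each value of `V_grid` while a
#' train of `n_pulses` pre-synaptic spikes is applied; every pre-spike
#' triggers one plasticity event against the clamped potential.  Clamps
#' below the set-point voltage induce depression, clamps above induce
#' potentiation.  The result also carries a presentation axis shifted by
#' -29 mV (mapping the model frame `[-11, 61.75] mV` onto the
#' experimental frame `[-40, 32.75] mV`).
#'
#' @param V_grid clamped potentials, volts, within
#'   `[V_clamp_low, V_clamp_high]`.
#' @param n_pulses pre-synaptic spikes per clamp level (default 25).
#' @param plast a [plasticity_params()] object.
#' @param leak_mode `"off"` (default) or `"on"`; with the leak on the
#'   weight also decays between pulses at `pulse_rate_hz`.
#' @param pulse_rate_hz pre-spike train rate, Hz (immaterial with the leak
#'   off, where updates commute).
#' @param omega0 initial weight (default 0.5).
#' @return A `protocol_result` data frame with columns `V`, `V_shifted`,
#'   `change_pct`.
#' @export
voltage_clamp <- function(V_grid, n_pulses = 25,
                          plast = plasticity_params(),
                          leak_mode = c("off", "on"), pulse_rate_hz = 1,
                          omega0 = 0.5) {
  leak_mode <- match.arg(leak_mode)
  if (any(V_grid < plast$V_clamp_low - 1e-12 |
          V_grid > plast$V_clamp_high + 1e-12))
    stop("clamp voltage outside the admissible range [",
         plast$V_clamp_low, ", ", plast$V_clamp_high, "] V", call. = FALSE)
  if (is.unsorted(V_grid, strictly = TRUE))
    stop("V_grid must be strictly increasing", call. = FALSE)
  pp <- kappa_eff(plast, leak_mode)
  T_ms <- 1000 / pulse_rate_hz
  change <- vapply(V_grid, function(V) {
    w <- omega0
    for (i in seq_len(n_pulses)) {
      w <- spike_update(w, V, pp)
      if (leak_mode == "on" && i < n_pulses) w <- decay(w, T_ms, pp)
    }
    100 * (w - omega0) / omega0
  }, numeric(1))
  protocol_result(
    data.frame(V = V_grid, V_shifted = V_grid - 0.029,
               change_pct = change),
    "voltage_clamp",
    list(n_pulses = n_pulses, omega0 = omega0, leak_mode = leak_mode,
         pulse_rate_hz = pulse_rate_hz))
}

# shared pairing engine: returns % change for one (frequency, offset)
pair_run <- function(freq_hz, dt_pair_ms, n_pairs, neuron, plast,
                     leak_mode, omega0, dt, phase_cache = NULL) {
  T_ms <- 1000 / freq_hz
  if (abs(dt_pair_ms) >= T_ms)
    stop("|dt| of ", dt_pair_ms, " ms is incompatible with a ",
         freq_hz, " Hz pairing period", call. = FALSE)
  traj <- if (is.null(phase_cache)) {
    I <- current_for_rate(freq_hz, neuron, dt)
    qif_phase_trajectory(I, neuron, dt, period_hint = T_ms)
  } else phase_cache
  phase <- if (dt_pair_ms > 0) traj$period_ms - dt_pair_ms else -dt_pair_ms
  V <- traj$u_of_phase(phase)
  pp <- kappa_eff(plast, leak_mode)
  w <- omega0
  for (i in seq_len(n_pairs)) {
    w <- spike_update(w, V, pp)
    if (leak_mode == "on") w <- decay(w, T_ms, pp)
  }
  100 * (w - omega0) / omega0
}

#' Spike-timing-dependent plasticity window
#'
#' For each timing offset `dt_grid` (ms; positive = pre leads post),
#' `n_pairs` pre/post pairings are applied at `pair_freq` Hz and the
#' relative weight change is reported.  Pre-spikes shortly before the post
#' spike read the depolarized pre-spike upstroke of the post membrane
#' (potentiation); pre-spikes shortly after read the reset/refractory
#' hyperpolarization (depression).
#'
#' @param dt_grid timing offsets, ms, `|dt| <` pairing period.
#' @param n_pairs number of pairings (default 60).
#' @param pair_freq pairing frequency, Hz (default 6).
#' @param neuron a [neuron_params()] object.
#' @param plast a [plasticity_params()] object.
#' @param leak_mode `"off"` (default) or `"on"`.
#' @param omega0 initial weight.
#' @param dt integration step, ms.
#' @return A `protocol_result` data frame with columns `dt_ms`,
#'   `change_pct`.
#' @export
stdp_window <- function(dt_grid, n_pairs = 60, pair_freq = 6,
                        neuron = neuron_params(),
                        plast = plasticity_params(),
                        leak_mode = c("off", "on"), omega0 = 0.5,
                        dt = 0.05) {
  leak_mode <- match.arg(leak_mode)
  if (is.unsorted(dt_grid, strictly = TRUE))
    stop("dt_grid must be strictly increasing", call. = FALSE)
  I <- current_for_rate(pair_freq, neuron, dt)
  traj <- qif_phase_trajectory(I, neuron, dt, period_hint = 1000 / pair_freq)
  change <- vapply(dt_grid, function(d)
    pair_run(pair_freq, d, n_pairs, neuron, plast, leak_mode, omega0,
             dt, traj), numeric(1))
  protocol_result(
    data.frame(dt_ms = dt_grid, change_pct = change),
    "stdp_window",
    list(n_pairs = n_pairs, pair_freq = pair_freq, omega0 = omega0,
         leak_mode = leak_mode))
}

#' Pair-frequency dependence of spike pairing
#'
#' Sweeps the pairing frequency at a fixed timing offset (`+10` ms
#' pre-post or `-10` ms post-pre) and reports the relative weight change
#' after `n_pairs` pairings per frequency.  On the post-pre branch the
#' sign of the change flips from depression to potentiation near 40 Hz;
#' on the pre-post branch with the continuous leak enabled, pairing rates
#' below about 2 Hz can no longer produce net potentiation because the
#' leak outweighs the infrequent spike-driven updates.
#'
#' @param freq_grid pairing frequencies, Hz (default `1:60`).
#' @param dt_pair_ms timing offset, ms: `+10` (pre-post) or `-10`
#'   (post-pre), or any offset compatible with every grid frequency.
#' @inheritParams stdp_window
#' @return A `protocol_result` data frame with columns `freq_hz`,
#'   `change_pct`, `branch`, `leak_mode`.
#' @export
pair_frequency_curve <- function(freq_grid = 1:60, dt_pair_ms = -10,
                                 n_pairs = 60, neuron = neuron_params(),
                                 plast = plasticity_params(),
                                 leak_mode = c("off", "on"),
                                 omega0 = 0.5, dt = 0.05) {
  leak_mode <- match.arg(leak_mode)
  if (is.unsorted(freq_grid, strictly = TRUE))
    stop("freq_grid must be strictly increasing", call. = FALSE)
  change <- vapply(freq_grid, function(f)
    pair_run(f, dt_pair_ms, n_pairs, neuron, plast, leak_mode, omega0,
             dt), numeric(1))
  branch <- if (dt_pair_ms > 0) "pre_post" else "post_pre"
  protocol_result(
    data.frame(freq_hz = freq_grid, change_pct = change,
               branch = branch, leak_mode = leak_mode),
    "pair_frequency",
    list(n_pairs = n_pairs, dt_pair_ms = dt_pair_ms, omega0 = omega0,
         leak_mode = leak_mode))
}

#' Zero crossing of a weight-change curve
#'
#' Linear interpolation of the first negative-to-positive sign change of
#' `change_pct` along the independent variable (first column) of a
#' protocol result.
#'
#' @param result a `protocol_result` (or any data frame whose first
#'   column is the grid and which has a `change_pct` column).
#' @return The interpolated crossover (same units as the grid), or
#'   `NA_real_` when the curve does not change sign.
#' @export
find_sign_crossover <- function(result) {
  x <- result[[1]]
  y <- result$change_pct
  s <- sign(y)
  idx <- which(s[-length(s)] <= 0 & s[-1] > 0)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (y[i] == 0) return(x[i])
  x[i] + (x[i + 1] - x[i]) * (0 - y[i]) / (y[i + 1] - y[i])
}
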