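#' Initialize the weight matrix of an all-to-all network
#'
#' Row `i`, column `j` holds the weight \eqn{\omega_{ij}} of the directed
#' connection from neuron `i` to neuron `j`.  Self-projections are
#' forbidden: the diagonal is fixed at zero and never updated.
#'
#' @param n number of neurons (>= 2).
#' @param init one of `"constant"` (all off-diagonal entries equal to
#'   `value`; the single-synapse experiments initialize at 0.5),
#'   `"uniform"` (i.i.d. uniform on `[omega_min, omega_max]`, the
#'   pre-training state of the large-scale network) or `"explicit"`
#'   (use the matrix supplied in `value`).
#' @param params a [plasticity_params()] object supplying the weight
#'   bounds.
#' @param value constant weight, or an `n` by `n` matrix for
#'   `init = "explicit"`.
#' @param seed integer seed for the `"uniform"` mode (reproducible draws).
#' @return An `n` by `n` weight matrix of class `weight_matrix`.
#' @export
init_network <- function(n, init = c("constant", "uniform", "explicit"),
                         params = plasticity_params(), value = 0.5,
                         seed = 1L) {
  init <- match.arg(init)
  if (!is.numeric(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  n <- as.integer(n)
  w <- switch(init,
    constant = {
      if (value < params$omega_min || value > params$omega_max)
        stop("constant weight outside the admissible bounds", call. = FALSE)
      matrix(value, n, n)
    },
    uniform = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(as.integer(seed))
      matrix(stats::runif(n * n, params$omega_min, params$omega_max), n, n)
    },
    explicit = {
      if (!is.matrix(value) || !all(dim(value) == n))
        stop("explicit init needs an n x n matrix", call. = FALSE)
      if (any(value[row(value) != col(value)] < params$omega_min) ||
          any(value > params$omega_max))
        stop("explicit weights outside the admissible bounds", call. = FALSE)
      value
    })
  diag(w) <- 0
  class(w) <- c("weight_matrix", class(w))
  w
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' External input current vector for a binary pattern
#'
#' \eqn{I^{ext}_n = I_0^{ext} P_n}: each active pixel's neuron receives the
#' constant drive `I0_ext`, all others zero.
#'
#' @param pattern binary vector (entries 0/1) or a [pattern()] object.
#' @param I0_ext drive amplitude, amperes (the large-scale simulations use
#'   430.25 mA).
#' @return Per-neuron current vector, amperes.
#' @export
external_current <- function(pattern, I0_ext = 0.43025) {
  p <- if (inherits(pattern, "memstdp_pattern")) pattern$pixels else pattern
  if (!all(p %in% c(0, 1)))
    stop("pattern must be binary (0/1)", call. = FALSE)
  I0_ext * p
}

#' Normalized internal current delivered by spiking neurons
#'
#' Neuron `j` receives
#' \eqn{\sum_{i \in S} \omega_{ij}\, I_0^{int} / \sum_i \omega_{ij}}
#' from the set `S` of currently spiking neurons: the recurrent drive is
#' normalized by the neuron's total incoming weight, bounding it by
#' `I0_int` and making the delivered share proportional to the spiking
#' sources' share of the incoming connectivity.
#'
#' @param weights an `n` by `n` weight matrix (row = source).
#' @param spiking integer indices of the neurons spiking this step.
#' @param I0_int pulse amplitude, amperes (default 2.4).
#' @return Per-neuron current amplitude vector, amperes.
#' @export
internal_current <- function(weights, spiking, I0_int = 2.4) {
  n <- nrow(weights)
  if (length(spiking) == 0) return(numeric(n))
  if (any(spiking < 1 | spiking > n))
    stop("spiking indices out of range", call. = FALSE)
  colsum <- colSums(weights)
  num <- colSums(weights[spiking, , drop = FALSE])
  out <- ifelse(colsum > 0, I0_int * num / colsum, 0)
  as.numeric(out)
}

#' Time-resolved external stimulus program
#'
#' A cyclic schedule of piecewise-constant per-neuron currents: segment `s`
#' lasts `durations_ms[s]` and applies the current vector `currents[s, ]`;
#' the whole cycle is repeated `repeats` times.
#'
#' @param durations_ms segment durations, ms (all > 0).
#' @param currents matrix with one row per segment and one column per
#'   neuron, amperes.  A single vector is taken as one segment.
#' @param repeats number of cycles (>= 1).
#' @return An object of class `stimulus_program`.
#' @export
stimulus_program <- function(durations_ms, currents, repeats = 1L) {
  if (is.vector(currents)) currents <- matrix(currents, nrow = 1)
  if (length(durations_ms) != nrow(currents))
    stop("one duration per segment row required", call. = FALSE)
  if (any(durations_ms < 0)) stop("durations must be >= 0", call. = FALSE)
  if (any(!is.finite(currents))) stop("currents must be finite", call. = FALSE)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  structure(list(durations_ms = as.numeric(durations_ms),
                 currents = currents, repeats = as.integer(repeats)),
            class = "stimulus_program")
}

#' @export
print.stimulus_program <- function(x, ...) {
  cat(sprintf("Stimulus program: %d segment(s) x %d repeats, cycle %.4g ms, total %.4g ms\n",
              length(x$durations_ms), x$repeats, sum(x$durations_ms),
              sum(x$durations_ms) * x$repeats))
  invisible(x)
}

#' Simulate a plastic recurrent QIF network
#'
#' Integrates `n` quadratic integrate-and-fire neurons coupled all-to-all
#' through memristive synapses.  Each spike (i) triggers one plasticity
#' event on the spiking neuron's outgoing weights, signed by the partners'
#' start-of-step membrane potentials, and (ii) is propagated as a
#' rectangular internal-current pulse normalized by the receiving neuron's
#' total incoming weight.  With `leak = TRUE` all weights additionally
#' decay continuously at rate `kappa`.
#'
#' @param weights initial weight matrix (see [init_network()]).
#' @param program a [stimulus_program()] with one current column per
#'   neuron.
#' @param neuron a [neuron_params()] object.
#' @param plast a [plasticity_params()] object.
#' @param dt integration step, ms.
#' @param I0_int internal pulse amplitude, amperes.
#' @param pulse_width_ms duration of the internal current pulse, ms
#'   (default: one integration step, the discretized delta pulse).
#' @param leak apply the continuous weight leak between spike events.
#' @param snapshot_every_ms record weight-matrix snapshots at this
#'   interval (0 = none).
#' @param record_traces record all membrane traces (only sensible for
#'   small networks).
#' @param engine `"cpp"` (compiled, default) or `"r"` (plain-R reference
#'   stepper, identical semantics, for validation and small runs).
#' @param u0 initial membrane potentials (default all `u_rest`).
#' @return A `simulation_result` list: `spikes` (data.frame `neuron`,
#'   `t_ms`), final `omega`, optional `snapshots`/`traces`, and the
#'   resolved configuration.
#' @export
run_network <- function(weights, program, neuron = neuron_params(),
                        plast = plasticity_params(), dt = 0.05,
                        I0_int = 2.4, pulse_width_ms = dt, leak = TRUE,
                        snapshot_every_ms = 0, record_traces = FALSE,
                        engine = c("cpp", "r"),
                        u0 = rep(neuron$u_rest, nrow(weights))) {
  engine <- match.arg(engine)
  n <- nrow(weights)
  if (ncol(program$currents) != n)
    stop("program has ", ncol(program$currents),
         " current columns for ", n, " neurons", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (record_traces && n > 64)
    stop("trace recording is limited to small networks", call. = FALSE)
  w <- unclass(weights)

  if (engine == "cpp") {
    res <- .engine_run(w, unclass(neuron), unclass(plast),
                       program$durations_ms, program$currents,
                       program$repeats, dt, I0_int, pulse_width_ms,
                       leak, snapshot_every_ms, record_traces, 1L, u0)
  } else {
    res <- .engine_run_r(w, neuron, plast, program, dt, I0_int,
                         pulse_width_ms, leak, snapshot_every_ms,
                         record_traces, u0)
  }
  out <- list(
    spikes = data.frame(neuron = as.integer(res$spike_id),
                        t_ms = as.numeric(res$spike_t)),
    omega = res$omega,
    duration_ms = res$duration_ms,
    snapshots = res$snapshots,
    snapshot_t = res$snapshot_t,
    config = list(n = n, dt = dt, I0_int = I0_int,
                  pulse_width_ms = pulse_width_ms, leak = leak,
                  neuron = unclass(neuron), plast = unclass(plast),
                  engine = engine))
  if (record_traces) {
    out$traces <- res$traces
    out$trace_t <- res$trace_t
  }
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Network simulation: %d neurons, %.4g ms, %d spikes\n",
              x$config$n, x$duration_ms, nrow(x$spikes)))
  invisible(x)
}

# plain-R reference implementation of the engine loop; semantics mirror
# src/engine.cpp step for step and the two are cross-checked in the tests
.engine_run_r <- function(w, neuron, plast, program, dt, I0_int,
                          pulse_width_ms, leak, snapshot_every_ms,
                          record_traces, u0) {
  n <- nrow(w)
  seg_end <- cumsum(program$durations_ms)
  cyc <- seg_end[length(seg_end)]
  total <- cyc * program$repeats
  n_steps <- round(total / dt)
  dt_s <- dt * 1e-3
  ref_steps <- round(neuron$t_ref / dt)
  pulse_steps <- max(1, round(pulse_width_ms / dt))
  snap_steps <- if (snapshot_every_ms > 0) max(1, round(snapshot_every_ms / dt)) else 0
  leak_f <- exp(-plast$kappa * dt)
  do_leak <- leak && plast$kappa > 0

  u <- u0; refrac <- integer(n); I_int <- numeric(n)
  pulses <- list()
  sp_id <- integer(0); sp_t <- numeric(0)
  snaps <- list(); snap_t <- numeric(0)
  traces <- if (record_traces) matrix(NA_real_, n_steps + 1, n) else NULL
  if (record_traces) traces[1, ] <- u

  offd <- row(w) != col(w)
  for (step in seq_len(n_steps) - 1L) {
    t <- step * dt
    t_cyc <- t %% cyc
    seg <- which(t_cyc < seg_end - 1e-9)[1]
    if (is.na(seg)) seg <- length(seg_end)
    drop <- vapply(pulses, function(p) p$end <= step, logical(1))
    if (any(drop)) {
      for (p in pulses[drop]) I_int <- I_int - p$delta
      pulses <- pulses[!drop]
    }
    u_snap <- u
    active <- refrac == 0
    u[!active] <- neuron$u_rest
    refrac[!active] <- refrac[!active] - 1L
    if (any(active)) {
      I <- program$currents[seg, active] + I_int[active]
      fd <- function(uu) (neuron$g_L * (uu - neuron$u_rest) *
                            (uu - neuron$u_critical) + I) / neuron$C
      k1 <- fd(u[active])
      k2 <- fd(u[active] + dt_s * k1 / 2)
      k3 <- fd(u[active] + dt_s * k2 / 2)
      k4 <- fd(u[active] + dt_s * k3)
      u[active] <- u[active] + dt_s * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    spiked <- which(active & u >= neuron$theta_thres)
    if (do_leak)   # this step's leak acts before the spike-gated event
      w[offd] <- pmax(plast$omega_min, w[offd] * leak_f)
    if (length(spiked)) {
      delta <- if (I0_int > 0) internal_current(w, spiked, I0_int) else numeric(n)
      for (i in spiked) {
        wrow <- w[i, ]
        V <- u_snap
        f <- plast$k * (V - plast$V_critical) * wrow^2 * (1 - wrow / plast$omega_max)
        wnew <- wrow + (f - plast$kappa * wrow) * plast$tau_event
        wnew <- pmin(plast$omega_max, pmax(plast$omega_min, wnew))
        wnew[i] <- 0
        w[i, ] <- wnew
      }
      if (I0_int > 0) {
        I_int <- I_int + delta
        pulses[[length(pulses) + 1]] <- list(end = step + pulse_steps + 1,
                                             delta = delta)
      }
      u[spiked] <- neuron$u_rest
      refrac[spiked] <- ref_steps
      sp_id <- c(sp_id, spiked)
      sp_t <- c(sp_t, rep((step + 1) * dt, length(spiked)))
    }
    if (snap_steps > 0 && (step + 1) %% snap_steps == 0) {
      snaps[[length(snaps) + 1]] <- w
      snap_t <- c(snap_t, (step + 1) * dt)
    }
    if (record_traces) traces[step + 2, ] <- u
  }
  out <- list(spike_id = sp_id, spike_t = sp_t, omega = w,
              snapshots = snaps, snapshot_t = snap_t, duration_ms = total)
  if (record_traces) {
    out$traces <- traces
    out$trace_t <- seq(0, by = dt, length.out = n_steps + 1)
  }
  out
}

#' Advance an explicit network state by one integration step
#'
#' Single-step interface to the reference stepper: useful for inspecting
#' the update order (integrate, spike-gated plasticity against start-of-
#' step potentials, reset, continuous leak) on small examples.  The bulk
#' simulations use [run_network()].
#'
#' @param state list with elements `u` (potentials, V), `refractory_steps`
#'   (integer vector), `w` (weight matrix), `I_int` (internal current
#'   vector, A).
#' @param I_ext external current vector for this step, amperes.
#' @param dt step, ms.
#' @param neuron,plast parameter objects.
#' @param leak apply continuous decay this step.
#' @return Updated state, with `spiked` (indices) attached.
#' @export
network_step <- function(state, I_ext, dt, neuron = neuron_params(),
                         plast = plasticity_params(), leak = TRUE) {
  u <- state$u
  refrac <- state$refractory_steps
  w <- state$w
  I_int <- if (is.null(state$I_int)) numeric(length(u)) else state$I_int
  u_snap <- u
  held <- refrac > 0
  u[held] <- neuron$u_rest
  refrac[held] <- refrac[held] - 1L
  active <- !held
  if (any(active)) {
    dt_s <- dt * 1e-3
    I <- I_ext[active] + I_int[active]
    fd <- function(uu) (neuron$g_L * (uu - neuron$u_rest) *
                          (uu - neuron$u_critical) + I) / neuron$C
    k1 <- fd(u[active]); k2 <- fd(u[active] + dt_s * k1 / 2)
    k3 <- fd(u[active] + dt_s * k2 / 2); k4 <- fd(u[active] + dt_s * k3)
    u[active] <- u[active] + dt_s * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  spiked <- which(active & u >= neuron$theta_thres)
  if (leak && plast$kappa > 0) {
    offd <- row(w) != col(w)
    w[offd] <- pmax(plast$omega_min, w[offd] * exp(-plast$kappa * dt))
  }
  if (length(spiked)) {
    for (i in spiked) {
      wrow <- w[i, ]
      f <- plast$k * (u_snap - plast$V_critical) * wrow^2 *
        (1 - wrow / plast$omega_max)
      wnew <- pmin(plast$omega_max,
                   pmax(plast$omega_min,
                        wrow + (f - plast$kappa * wrow) * plast$tau_event))
      wnew[i] <- 0
      w[i, ] <- wnew
    }
    u[spiked] <- neuron$u_rest
    refrac[spiked] <- round(neuron$t_ref / dt)
  }
  state$u <- u
  state$refractory_steps <- refrac
  state$w <- w
  state$I_int <- I_int
  state$spiked <- spiked
  state
}

#' Write a spike raster to CSV
#'
#' @param result a `simulation_result`.
#' @param path output file (two columns: `neuron`, `t_ms`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(result, path) {
  utils::write.csv(result$spikes, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a weight matrix as a plain-text dense matrix
#'
#' Row-major, source neuron by row, whitespace-separated.
#'
#' @param w weight matrix.
#' @param path file path.
#' @return `read_weights` returns a `weight_matrix`; `write_weights`
#'   returns `path` invisibly.
#' @export
write_weights <- function(w, path) {
  utils::write.table(unclass(w), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  w <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(w) <- NULL
  if (nrow(w) != ncol(w)) stop("weight matrix must be square", call. = FALSE)
  class(w) <- c("weight_matrix", class(w))
  w
}
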