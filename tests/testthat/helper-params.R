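# canonical parameter sets used across the suite
default_plast <- function(...) plasticity_params(...)
default_neuron <- function(...) neuron_params(...)

# table constants, spelled out once
TBL <- list(k = 1.21, omega_min = 0.05, omega_max = 1.0, V_critical = 0,
            theta = 0.06175, u_crit = 0.009, u_rest = -0.011,
            C = 1e-3, g_L = 1, I0_ext = 0.43025, I0_int = 2.4)

# closed-form QIF helpers (independent oracle; suprathreshold solution
# u(t) = p + q tan(g q t / C + atan((u0 - p)/q)) for I > rheobase)
qif_oracle <- list(
  subthreshold_equilibrium = function(I, np = neuron_params()) {
    # smaller root of g (u - u_rest)(u - u_crit) + I = 0
    b <- -(np$u_rest + np$u_critical)
    cc <- np$u_rest * np$u_critical + I / np$g_L
    (-b - sqrt(b^2 - 4 * cc)) / 2
  },
  period_ms = function(I, np = neuron_params()) {
    q <- sqrt(I / np$g_L - ((np$u_critical - np$u_rest) / 2)^2)
    p <- (np$u_rest + np$u_critical) / 2
    Tint <- np$C / (np$g_L * q) *
      (atan((np$theta_thres - p) / q) - atan((np$u_rest - p) / q))
    Tint * 1e3 + np$t_ref
  })
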