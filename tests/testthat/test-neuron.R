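test_that("membrane derivative has its fixed points at rest and critical", {
  np <- default_neuron()
  expect_identical(membrane_derivative(np$u_rest, 0, np), 0)
  expect_identical(membrane_derivative(np$u_critical, 0, np), 0)
  # between the two fixed points the flow pushes back to rest,
  # above the critical potential it runs away
  expect_lt(membrane_derivative(0, 0, np), 0)
  expect_gt(membrane_derivative(0.02, 0, np), 0)
  # below rest the flow is positive, back up toward the stable rest point
  expect_gt(membrane_derivative(-0.02, 0, np), 0)
  # strong constant drive: quadratic term is negligible against I/C
  expect_equal(membrane_derivative(0, 0.43025, np),
               (1 * (0 - (-0.011)) * (0 - 0.009) + 0.43025) / 1e-3,
               tolerance = 1e-12)
  expect_equal(membrane_derivative(0, 0.43025, np), 430.25, tolerance = 1e-3)
})

test_that("rheobase closed form matches the simulated firing boundary", {
  np <- default_neuron()
  expect_equal(rheobase(np), 1e-4, tolerance = 1e-12)
  # scaling properties
  np2 <- neuron_params(u_rest = -0.031, u_critical = 0.009)
  expect_equal(rheobase(np2), 4 * rheobase(np), tolerance = 1e-12)
  # just below: no repetitive firing; just above: repetitive firing
  below <- qif_simulate(0.97 * rheobase(np), 3000, np)$spikes
  above <- qif_simulate(1.2 * rheobase(np), 3000, np)$spikes
  expect_lte(length(below), 1)
  expect_gt(length(above), 2)
})

test_that("rk4_step preserves the resting state and spikes above threshold", {
  np <- default_neuron()
  st <- neuron_state(np)
  st2 <- rk4_step(st, 0, 0.05, np)
  expect_equal(st2$u, np$u_rest, tolerance = 1e-15)
  expect_false(st2$spike_flag)
  expect_error(rk4_step(st, 0, -0.1, np), "dt")
  # perturbation above u_critical leads to a spike without any current
  st$u <- np$u_critical + 0.005
  spiked <- FALSE
  for (i in 1:40000) {
    st <- rk4_step(st, 0, 0.05, np)
    if (st$spike_flag) { spiked <- TRUE; break }
  }
  expect_true(spiked)
  expect_equal(st$u, np$u_rest)
  expect_equal(st$refractory_remaining, np$t_ref)
})

test_that("subthreshold response settles at the quadratic-formula root", {
  np <- default_neuron()
  I <- 0.5 * rheobase(np)
  tr <- qif_simulate(I, 2000, np, record_trace = TRUE)$trace
  expect_equal(tail(tr$u, 1), qif_oracle$subthreshold_equilibrium(I, np),
               tolerance = 1e-6)
})

test_that("suprathreshold firing matches the closed-form period", {
  np <- default_neuron()
  for (I in c(4e-4, 2e-3, 6e-3)) {
    s <- qif_simulate(I, 2000, np)$spikes
    isi <- mean(diff(tail(s, 3)))
    expect_equal(isi, qif_oracle$period_ms(I, np), tolerance = 5e-3)
  }
  # firing accelerates with current
  s1 <- qif_simulate(4e-4, 2000, np)$spikes
  s2 <- qif_simulate(2e-3, 2000, np)$spikes
  expect_gt(length(s2), length(s1))
})

test_that("RK4 spike counts agree across step-size halving", {
  np <- default_neuron()
  n_coarse <- length(qif_simulate(2e-3, 1000, np, dt = 0.1)$spikes)
  n_fine <- length(qif_simulate(2e-3, 1000, np, dt = 0.01)$spikes)
  expect_equal(n_coarse, n_fine)
  # time of the 10th spike converges
  t10_a <- qif_simulate(2e-3, 1000, np, dt = 0.1)$spikes[10]
  t10_b <- qif_simulate(2e-3, 1000, np, dt = 0.05)$spikes[10]
  t10_c <- qif_simulate(2e-3, 1000, np, dt = 0.01)$spikes[10]
  expect_lt(abs(t10_c - t10_b), abs(t10_c - t10_a) + 1e-9)
  expect_lt(abs(t10_b - t10_c), 0.2)
})

test_that("refractory period separates spikes", {
  np <- default_neuron()
  s <- qif_simulate(0.43025, 500, np)$spikes
  expect_gt(length(s), 10)
  expect_true(all(diff(s) >= np$t_ref - 1e-9))
})

test_that("RK4 subthreshold trajectory matches a high-accuracy integrator", {
  skip_if_not_installed("deSolve")
  np <- default_neuron()
  I <- 0.8 * rheobase(np)
  tr <- qif_simulate(I, 300, np, dt = 0.05, record_trace = TRUE)$trace
  ref <- deSolve::lsoda(
    y = c(u = np$u_rest), times = seq(0, 0.3, by = 0.05e-3),
    func = function(t, y, parms)
      list((np$g_L * (y - np$u_rest) * (y - np$u_critical) + I) / np$C),
    rtol = 1e-11, atol = 1e-14)
  expect_equal(tr$u, unname(ref[, "u"]), tolerance = 1e-7)
})

test_that("f-I curve is monotone and current_for_rate round-trips", {
  np <- default_neuron()
  rates <- vapply(c(3e-4, 1e-3, 3e-3, 8e-3), function(I)
    length(qif_simulate(I, 1500, np)$spikes), numeric(1))
  expect_true(all(diff(rates) >= 0))
  for (f in c(6, 60)) {
    I <- current_for_rate(f, np)
    s <- qif_simulate(I, max(1000, 8000 / f), np)$spikes
    realized <- 1000 / mean(diff(tail(s, 4)))
    expect_equal(realized, f, tolerance = 0.01)
  }
  expect_lte(current_for_rate(0.5, np), 2 * rheobase(np))
  expect_error(current_for_rate(1000, np), "unreachable")
})
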