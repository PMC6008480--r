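test_that("init_network builds valid weight matrices", {
  p <- default_plast()
  w <- init_network(9, "constant", p, 0.5)
  expect_true(all(diag(w) == 0))
  expect_true(all(w[row(w) != col(w)] == 0.5))
  expect_error(init_network(1, "constant"), "n must be")
  expect_error(init_network(4, "constant", p, 0.01), "bounds")

  wu1 <- init_network(20, "uniform", p, seed = 7)
  wu2 <- init_network(20, "uniform", p, seed = 7)
  expect_identical(wu1, wu2)
  expect_true(all(diag(wu1) == 0))
  off <- wu1[row(wu1) != col(wu1)]
  expect_true(all(off >= p$omega_min & off <= p$omega_max))
  expect_gt(length(unique(off)), 100)

  we <- init_network(3, "explicit", p, value = matrix(0.3, 3, 3))
  expect_true(all(diag(we) == 0))
})

test_that("external current is I0 * P with binary validation", {
  expect_identical(external_current(c(0, 0, 0), 0.43025), c(0, 0, 0))
  expect_equal(external_current(c(0, 1, 0), 0.43025), c(0, 0.43025, 0))
  expect_equal(external_current(c(1, 1), 2 * 0.43025),
               2 * external_current(c(1, 1), 0.43025))
  expect_error(external_current(c(0, 2, 0), 1), "binary")
})

test_that("internal current implements the incoming-sum normalization", {
  p <- default_plast()
  expect_identical(internal_current(init_network(5, "constant", p, 0.5),
                                    integer(0)), numeric(5))
  # single source: normalization cancels the single incoming weight
  w <- matrix(0, 2, 2); w[1, 2] <- 0.5
  expect_equal(internal_current(w, 1, 2.4), c(0, 2.4))
  # all sources spiking: every neuron receives exactly I0_int
  set.seed(1)
  for (n in c(3, 7, 12)) {
    w <- init_network(n, "uniform", p, seed = n)
    got <- internal_current(w, seq_len(n), 2.4)
    expect_equal(got, rep(2.4, n), tolerance = 1e-12)
    # brute-force oracle for a random subset of sources
    S <- sample(n, 3)
    ref <- vapply(seq_len(n), function(j)
      2.4 * sum(w[S, j]) / sum(w[, j]), numeric(1))
    expect_equal(internal_current(w, S, 2.4), ref, tolerance = 1e-12)
  }
  # zero incoming sum is guarded, not an error
  w0 <- matrix(0, 3, 3)
  expect_identical(internal_current(w0, 1, 2.4), numeric(3))
})

test_that("compiled and reference engines agree step for step", {
  p <- plasticity_params(kappa = 4e-3)   # strong leak to exercise decay
  np <- default_neuron()
  w0 <- init_network(3, "uniform", p, seed = 3)
  prog <- stimulus_program(c(30, 20), rbind(c(4e-3, 2e-4, 0),
                                            c(0, 4e-3, 4e-3)),
                           repeats = 4)
  a <- run_network(w0, prog, np, p, dt = 0.05, I0_int = 2.4,
                   pulse_width_ms = 0.1, leak = TRUE, engine = "cpp",
                   record_traces = TRUE)
  b <- run_network(w0, prog, np, p, dt = 0.05, I0_int = 2.4,
                   pulse_width_ms = 0.1, leak = TRUE, engine = "r",
                   record_traces = TRUE)
  expect_gt(nrow(a$spikes), 3)
  expect_equal(a$spikes, b$spikes, tolerance = 1e-12)
  expect_equal(a$omega, b$omega, tolerance = 1e-10)
  expect_equal(a$traces[nrow(a$traces), ], b$traces[nrow(b$traces), ],
               tolerance = 1e-10)
})

test_that("network_step matches the bulk engine on a single step", {
  p <- default_plast(); np <- default_neuron()
  w0 <- init_network(3, "uniform", p, seed = 5)
  st <- list(u = c(0.05, 0.0615, -0.011), refractory_steps = c(0L, 0L, 0L),
             w = unclass(w0), I_int = numeric(3))
  I_ext <- c(0.43025, 0.43025, 0)
  st2 <- network_step(st, I_ext, 0.05, np, p, leak = FALSE)
  prog <- stimulus_program(0.05, matrix(I_ext, nrow = 1))
  ref <- run_network(w0, prog, np, p, dt = 0.05, I0_int = 0,
                     leak = FALSE, engine = "r", u0 = st$u)
  expect_equal(st2$w, ref$omega, tolerance = 1e-12)
  expect_equal(sort(st2$spiked), sort(ref$spikes$neuron))
})

test_that("spike-gated updates follow the partner's membrane sign", {
  # two neurons; A driven to spike while B is clamped depolarized or
  # hyperpolarized by its external current
  p <- default_plast(); np <- default_neuron()
  w0 <- init_network(2, "constant", p, 0.5)
  # B depolarized (started above u_critical, slowly climbing, u > 0)
  # while A is driven to spike: omega_AB must grow
  prog <- stimulus_program(5, matrix(c(0.43025, 0), nrow = 1))
  r <- run_network(w0, prog, np, p, dt = 0.05, I0_int = 0, leak = FALSE,
                   u0 = c(np$u_rest, 0.03))
  expect_gt(r$omega[1, 2], 0.5)
  # B at rest (negative potential): omega_AB must shrink
  r2 <- run_network(w0, prog, np, p, dt = 0.05, I0_int = 0, leak = FALSE,
                    u0 = c(np$u_rest, np$u_rest))
  expect_lt(r2$omega[1, 2], 0.5)
  # the silent neuron's outgoing weight is untouched (locality)
  expect_equal(r$omega[2, 1], 0.5, tolerance = 1e-12)
  expect_equal(r2$omega[2, 1], 0.5, tolerance = 1e-12)
})

test_that("runs are deterministic and respect trivial edge cases", {
  p <- default_plast(); np <- default_neuron()
  w0 <- init_network(4, "uniform", p, seed = 11)
  prog <- stimulus_program(40, matrix(c(0.43025, 0.43025, 0, 0), nrow = 1),
                           repeats = 3)
  r1 <- run_network(w0, prog, np, p, dt = 0.05)
  r2 <- run_network(w0, prog, np, p, dt = 0.05)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$omega, r2$omega)
  # no spikes and no leak: weights unchanged
  quiet <- run_network(w0, stimulus_program(20, matrix(0, 1, 4)),
                       np, p, leak = FALSE)
  expect_equal(quiet$omega, unclass(w0), tolerance = 1e-15)
  expect_identical(nrow(quiet$spikes), 0L)
  # zero-duration run returns the initial state
  z <- run_network(w0, stimulus_program(0, matrix(0, 1, 4)), np, p)
  expect_equal(z$omega, unclass(w0), tolerance = 1e-15)
  # per-neuron spike times respect the refractory gap
  for (id in unique(r1$spikes$neuron)) {
    ts <- r1$spikes$t_ms[r1$spikes$neuron == id]
    expect_true(all(diff(ts) >= np$t_ref - 1e-9))
  }
})

test_that("weight matrices and rasters round-trip through text files", {
  p <- default_plast()
  w <- init_network(6, "uniform", p, seed = 2)
  f <- tempfile(fileext = ".txt")
  write_weights(w, f)
  expect_equal(unclass(read_weights(f)), unclass(w), tolerance = 1e-12)
})
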