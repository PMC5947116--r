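# Integrators: deterministic/stochastic Heun, the adaptive scheme, event
# handling and the stochastic contracts (noiseless limit, seed determinism,
# Wiener variance law, strong small-noise continuity).

test_that("with all conductances off and no drive the state is frozen", {
  p <- model_params(kinetics = leak_only_kinetics(gL = 0), Iapp = 0, sigma = 0)
  st <- model_state(-60, steady_gates(p, -60))
  tr <- integrate_deterministic(p, st, duration = 500, dt = 0.01)
  expect_true(all(tr$V == -60))
  expect_length(tr$spikes, 0)
})

test_that("fixed-step Heun converges on the leak closed form", {
  # dV/dt = (Iapp - gL (V - EL)) / C has an explicit exponential solution
  p <- model_params(kinetics = leak_only_kinetics(), Iapp = 0.3, sigma = 0)
  st <- model_state(-60, steady_gates(p, -60))
  tr <- integrate_deterministic(p, st, duration = 200, dt = 0.01)
  Vinf <- -88.5 + 0.3 / 0.15
  k <- 0.15 / p$C
  exact <- Vinf + (-60 - Vinf) * exp(-k * tr$t)
  expect_equal(tr$V, exact, tolerance = 1e-7)
})

test_that("sigma = 0 stochastic output matches deterministic Heun bitwise", {
  p <- set_params(bursting_params(), sigma = 0)
  init <- model_state(-60, steady_gates(p, -60))
  a <- integrate_deterministic(p, init, duration = 2000, dt = 0.01)
  b <- integrate_stochastic(p, init, duration = 2000, dt = 0.01, seed = 1)
  expect_identical(a$V, b$V)
  expect_identical(a$spikes, b$spikes)
})

test_that("identical seeds give identical traces, different seeds differ", {
  p <- bursting_params()
  init <- model_state(-60, steady_gates(p, -60))
  a <- integrate_stochastic(p, init, duration = 1000, dt = 0.01, seed = 7)
  b <- integrate_stochastic(p, init, duration = 1000, dt = 0.01, seed = 7)
  d <- integrate_stochastic(p, init, duration = 1000, dt = 0.01, seed = 8)
  expect_identical(a$V, b$V)
  expect_false(identical(a$V, d$V))
})

test_that("a conductance-free membrane performs a Wiener random walk", {
  # var(V(t) - V(0)) = (sigma/C)^2 t
  sigma <- 0.2
  p <- model_params(kinetics = leak_only_kinetics(gL = 0), Iapp = 0,
                    sigma = sigma)
  st <- model_state(-60, steady_gates(p, -60))
  dev <- vapply(1:100, function(s) {
    tr <- integrate_stochastic(p, st, duration = 1000, dt = 0.01, seed = s,
                               record_dt = 1000)
    tr$V[length(tr$V)] + 60
  }, 0)
  expect_equal(var(dev), (sigma / p$C)^2 * 1000, tolerance = 0.25)
})

test_that("small-noise traces converge to the deterministic one", {
  p <- set_params(default_params(), Iapp = 0.2) # subthreshold, pre-spike regime
  init <- default_init(p)
  det <- integrate_deterministic(p, init, duration = 1000, dt = 0.01,
                                 record_dt = 1)
  mad <- vapply(c(0.01, 0.001, 1e-4) * p$C, function(s) {
    tr <- integrate_stochastic(set_params(p, sigma = s), init,
                               duration = 1000, dt = 0.01, seed = 5,
                               record_dt = 1)
    mean(abs(tr$V - det$V))
  }, 0)
  expect_true(all(diff(mad) < 0))
})

test_that("halving the step moves deterministic spike times by little", {
  p <- bursting_params()
  init <- model_state(-60, steady_gates(p, -60))
  a <- integrate_deterministic(p, init, duration = 5000, dt = 0.01)
  b <- integrate_deterministic(p, init, duration = 5000, dt = 0.005)
  expect_equal(length(a$spikes), length(b$spikes))
  expect_lt(max(abs(a$spikes - b$spikes)), 0.1)
})

test_that("the adaptive scheme agrees with fixed-step Heun on spike times", {
  p <- bursting_params()
  init <- model_state(-60, steady_gates(p, -60))
  a <- integrate_deterministic(p, init, duration = 5000, dt = 0.005)
  b <- integrate_deterministic(p, init, duration = 5000, adaptive = TRUE,
                               tol = 1e-10, record_dt = 1)
  expect_equal(length(a$spikes), length(b$spikes))
  # the fixed-step scheme accumulates a small phase error over 5 s
  expect_lt(max(abs(a$spikes - b$spikes)), 2)
})

test_that("spike events are ordered, separated, and bracket the threshold", {
  p <- bursting_params()
  tr <- integrate_stochastic(p, duration = 10000, dt = 0.01, seed = 3,
                             record_dt = 0.1)
  expect_gt(length(tr$spikes), 3)
  expect_true(all(diff(tr$spikes) >= p$refract))
  for (s in tr$spikes) {
    i <- findInterval(s, tr$t)
    expect_lt(tr$V[i], p$spike_threshold + 1e-9)
    expect_gte(tr$V[i + 1], p$spike_threshold - 1e-9)
  }
})

test_that("detect_spikes recovers the online spike log from samples", {
  p <- bursting_params()
  tr <- integrate_deterministic(p, duration = 6000, dt = 0.01, record_dt = 0.1)
  st <- detect_spikes(tr)
  expect_equal(length(st$times), length(tr$spikes))
  expect_lt(max(abs(st$times - tr$spikes)), 0.1)
  # trivial cases
  flat <- synthetic_trace(0:100, rep(-60, 101))
  expect_length(detect_spikes(flat)$times, 0)
  V <- rep(-60, 201); V[101] <- 20
  one <- synthetic_trace(0:200, V)
  expect_length(detect_spikes(one)$times, 1)
  expect_equal(detect_spikes(one)$times, 100, tolerance = 1)
})

test_that("divergence is reported as a flagged truncated trace, not an error", {
  # a strong constant inward current with no repolarising channels blows up
  f <- tempfile(fileext = ".ini")
  writeLines("version = 1\n[X]\ng = 5\nE = 500\n[L]\ng = 0.001\nE = -88.5\n", f)
  p <- model_params(kinetics = f, Iapp = 50, sigma = 0)
  tr <- integrate_deterministic(p, model_state(-60, steady_gates(p, -60)),
                                duration = 1000, dt = 0.01)
  expect_true(tr$diverged)
  expect_lt(max(tr$t), 1000)
})
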