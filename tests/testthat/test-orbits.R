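# Return-map machinery: Picard orbit detection, map Jacobians/multipliers,
# Lyapunov exponents (with closed-form map oracles), flip and homoclinic
# localisation.

test_that("Lyapunov exponents of a linear map equal log moduli of eigenvalues", {
  # diagonal map: the QR accumulation is exact from the first iterate
  A <- diag(c(0.9, 0.5))
  step <- function(x) list(x = drop(A %*% x) + c(0.1, -0.05), J = A)
  exps <- lyapunov_qr(step, c(1, 1), n_iter = 60, discard = 5)
  expect_equal(exps, log(c(0.9, 0.5)), tolerance = 1e-8)
  # scaled rotation: a complex pair with equal moduli, also exact under QR
  th <- 0.7
  R <- 0.8 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  stepR <- function(x) list(x = drop(R %*% x), J = R)
  expect_equal(lyapunov_qr(stepR, c(1, 0.2), n_iter = 60), rep(log(0.8), 2),
               tolerance = 1e-8)
  # generic matrix: convergence is O(1/n), checked at matching tolerance
  B <- matrix(c(0.9, 0.2, -0.3, 0.5), 2, 2)
  stepB <- function(x) list(x = drop(B %*% x) + c(0.1, -0.05), J = B)
  expect_equal(lyapunov_qr(stepB, c(1, 1), n_iter = 2000, discard = 10),
               sort(log(Mod(eigen(B)$values)), decreasing = TRUE),
               tolerance = 1e-3)
})

test_that("the logistic map at r = 4 has Lyapunov exponent ln 2", {
  step <- function(x) list(x = 4 * x * (1 - x), J = matrix(4 - 8 * x, 1, 1))
  mle <- lyapunov_qr(step, 0.2137, n_iter = 4000, discard = 100)
  expect_equal(mle, log(2), tolerance = 0.02)
})

test_that("a quiescent regime yields an empty, flagged crossing sequence", {
  p <- set_params(default_params(), gh = 1)
  s <- return_map_sequence(p, init = default_init(p), max_crossings = 5,
                           t_max = 3000)
  expect_true(s$quiescent)
  expect_error(find_periodic_orbit(p, init = default_init(p), t_max = 3000),
               "quiescent")
})

test_that("the bursting operating point has a period-3 orbit closed to 1e-12", {
  p <- bursting_params()
  orb <- find_periodic_orbit(p, max_crossings = 150)
  expect_true(orb$converged)
  expect_equal(orb$period, 3L)
  expect_lt(orb$closure, 1e-12)
  # the integer classification agrees with the map period
  expect_equal(classify_deterministic(
    integrate_deterministic(p, duration = 15000, dt = 0.01, record_dt = 1,
                            burn_in = 6000)), "3")
  mj <- map_jacobian(orb)
  expect_true(mj$stable)
  expect_true(all(Mod(mj$multipliers) < 1))
  # per-iterate Lyapunov exponent from the multipliers is negative
  expect_lt(log(max(Mod(mj$multipliers))) / orb$period, 0)
})

test_that("the tonic regime is a contracting period-1 orbit", {
  p <- set_params(default_params(), gAHP = 0.01, gh = 3.4)
  orb <- find_periodic_orbit(p, max_crossings = 250)
  expect_true(orb$converged)
  expect_equal(orb$period, 1L)
  # regular spiking: ISI coefficient of variation below 1 percent
  tr <- integrate_deterministic(p, spiking_init(p), duration = 10000,
                                dt = 0.01, record_dt = 1, burn_in = 4000)
  isi <- diff(tr$spikes)
  expect_lt(sd(isi) / mean(isi), 0.01)
  # late crossings of the detected sequence contract towards the fixed point
  cr <- orb$crossings
  d <- sqrt(rowSums((cr[-1, , drop = FALSE] -
                     cr[-nrow(cr), , drop = FALSE])^2))
  expect_lt(tail(d, 1), 1e-8)
  expect_lt(tail(d, 1), head(d, 1))
})

test_that("mle_map is negative on a stable orbit", {
  p <- set_params(default_params(), gAHP = 0.01, gh = 3.4)
  mle <- mle_map(p, n_iter = 40, transient_t = 8000, min_iter = 20)
  expect_lt(mle, 0)
})

test_that("a period-5 bursting orbit exists at elevated gAHP", {
  p <- set_params(default_params(), gAHP = 0.6, gh = 2.8)
  orb <- find_periodic_orbit(p, max_crossings = 250, t_max = 300000)
  expect_true(orb$converged)
  expect_equal(orb$period, 5L)
})

test_that("locate_flip finds the tonic to period-2 boundary and rejects flat brackets", {
  p <- set_params(default_params(), gh = 2.8)
  flip <- locate_flip(p, "gAHP", c(0.08, 0.3), tol = 5e-3)
  expect_gt(flip, 0.08)
  expect_lt(flip, 0.3)
  expect_equal(sort(c(attr(flip, "period_lo"), attr(flip, "period_hi"))),
               c(1L, 2L))
  expect_error(locate_flip(p, "gAHP", c(0.24, 0.3)), "same period")
})

test_that("locate_homoclinic needs a regime change across the bracket", {
  p <- default_params()
  expect_error(locate_homoclinic(p, "gh", c(1.0, 1.2), t_probe = 2000),
               "same regime")
})

test_that("the spiking orbit's destruction boundary in gh is sharp", {
  # coarse localisation for speed; the precision run lives in the
  # acceptance suite
  p <- default_params()
  b <- locate_homoclinic(p, "gh", c(2.55, 2.85), tol = 0.02,
                         t_probe = 15000, gap_max = 8000)
  expect_gt(b, 2.55)
  expect_lt(b, 2.85)
  # period divergence signature: near-boundary inter-spike period far
  # exceeds the period well inside the spiking regime
  expect_gt(attr(b, "period_near"), 1000)
})
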