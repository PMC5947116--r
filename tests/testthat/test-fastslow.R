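# Fast-slow decomposition: slow-variable identification, the linear slow
# reduction, fast-subsystem diagrams and the hysteresis-loop verification.

burst_trace <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- integrate_deterministic(bursting_params(), duration = 18000,
                                        dt = 0.01, record_dt = 1,
                                        burn_in = 6000)
    cache
  }
})

test_that("a synthetic slow sinusoid is ranked slowest", {
  t <- seq(0, 8000, by = 1)
  p <- default_params()
  gn <- gate_names(p)
  g <- matrix(0, length(t), length(gn), dimnames = list(NULL, gn))
  for (j in seq_along(gn)) g[, j] <- 0.5 + 0.3 * sin(2 * pi * 100 * t / 1000 + j)
  g[, "mNaP"] <- 0.5 + 0.3 * sin(2 * pi * 1 * t / 1000) # 1 Hz among 100 Hz
  spikes <- seq(500, 7500, by = 600) # fabricated cycles
  tr <- synthetic_trace(t, rep(-60, length(t)), g, spikes = spikes, params = p)
  rk <- identify_slow_variables(tr)
  expect_equal(rk$variable[1], "mNaP")
})

test_that("the bursting orbit's two slowest variables are mNaP and hKas", {
  rk <- identify_slow_variables(burst_trace())
  expect_setequal(attr(rk, "slow"), c("mNaP", "hKas"))
  # stable across re-computation on the second half of the trace
  tr <- burst_trace()
  half <- tr$t > max(tr$t) / 2
  tr2 <- synthetic_trace(tr$t[half], tr$V[half], tr$gating[half, ],
                         spikes = tr$spikes[tr$spikes > max(tr$t) / 2],
                         params = tr$params)
  expect_setequal(attr(identify_slow_variables(tr2), "slow"),
                  c("mNaP", "hKas"))
})

test_that("fit_slow_reduction recovers an exact linear relation", {
  t <- seq(0, 4000, by = 1)
  p <- default_params()
  gn <- gate_names(p)
  g <- matrix(0.3, length(t), length(gn), dimnames = list(NULL, gn))
  m <- 0.4 + 0.1 * sin(2 * pi * t / 2000)
  g[, "mNaP"] <- m
  g[, "hKas"] <- -0.5 * m + 0.3
  tr <- synthetic_trace(t, rep(-60, length(t)), g,
                        spikes = c(500, 600, 2500, 2600), params = p)
  fit <- fit_slow_reduction(tr)
  expect_equal(fit$slope, -0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-10)
  expect_lt(fit$rms, 1e-12)
})

test_that("the real orbit's slow plane relation is a negatively sloped line", {
  fit <- fit_slow_reduction(burst_trace())
  expect_lt(fit$slope, 0)
  expect_gt(fit$intercept, 0)
  expect_lt(fit$rms_rel, 0.5) # the hysteresis loop has finite width
})

test_that("degenerate slow input is rejected", {
  t <- 0:1000
  p <- default_params()
  gn <- gate_names(p)
  g <- matrix(0.3, length(t), length(gn), dimnames = list(NULL, gn))
  tr <- synthetic_trace(t, rep(-60, length(t)), g, spikes = c(100, 600),
                        params = p)
  expect_error(fit_slow_reduction(tr), "degenerate")
})

test_that("the fast subsystem shows SCH and HC bracketing a bistable window", {
  p <- bursting_params()
  h0 <- mean(burst_trace()$gating[, "hKas"])
  d <- fast_bif_diagram(p, hKas = h0, m_range = c(0.15, 0.55), n_po = 15)
  w <- bistability_window(d)
  expect_false(is.null(w))
  expect_lt(w[["HC"]], w[["SCH"]])
  # inside the window both attractors are reachable: the equilibrium branch
  # has a stable point there and the periodic branch covers it
  mid <- mean(w)
  eqV <- approx(d$eq$m, d$eq$V, xout = mid)$y
  expect_true(is.finite(eqV))
  expect_true(any(d$po$m <= w[["SCH"]] & d$po$m >= w[["HC"]]))
  # well below the homoclinic the kicked fast subsystem falls silent
  pr <- stellate:::fast_orbit_probe(
    p, list(mNaP = w[["HC"]] - 0.08, hKas = h0),
    stellate:::state_vector(p, spiking_init(p)))
  expect_null(pr)
})

test_that("the mslow collapse preserves the SCH/HC bracket", {
  fit <- fit_slow_reduction(burst_trace())
  d <- fast_bif_diagram(bursting_params(), slow_line = fit,
                        m_range = c(0.15, 0.55), n_po = 15)
  w <- bistability_window(d)
  expect_false(is.null(w))
  expect_lt(w[["HC"]], w[["SCH"]])
  # the orbit's slow excursion turning points lie inside the window
  m <- burst_trace()$gating[, "mNaP"]
  expect_gt(max(m), w[["HC"]])
  expect_lt(min(m), w[["SCH"]])
})

test_that("the burst orbit verifies as a subcritical Hopf/homoclinic loop", {
  tr <- burst_trace()
  p <- tr$params
  hr <- range(tr$gating[, "hKas"])
  cv <- hysteresis_curves(p, seq(hr[1] - 0.02, hr[2] + 0.02, length.out = 5),
                          m_range = c(0.15, 0.55), n_po = 12)
  expect_true(all(is.finite(cv$m_sch)))
  expect_true(all(is.finite(cv$m_hc)))
  expect_true(all(cv$m_hc < cv$m_sch)) # bistable band all along the grid
  # the curves vary smoothly along the hKas grid
  expect_true(all(abs(diff(cv$m_sch)) < 0.05))
  expect_true(all(abs(diff(cv$m_hc)) < 0.05))
  rep <- verify_hysteresis_loop(tr, cv)
  expect_true(rep$onset_ok)
  expect_true(rep$offset_ok)
  expect_true(rep$quiescent_ok)
  expect_equal(rep$classification, "subcritical Hopf/homoclinic")
  # negative control: a deliberately shifted SCH curve breaks the onset check
  cv2 <- cv
  cv2$m_sch <- cv2$m_sch + 0.05
  rep2 <- verify_hysteresis_loop(tr, cv2)
  expect_false(rep2$onset_ok)
  expect_equal(rep2$classification, "unclassified")
  # a tonic orbit has no quiescent branch segment and cannot classify
  tonic <- integrate_deterministic(set_params(p, gAHP = 0.01, gh = 3.4),
                                   spiking_init(p), duration = 6000,
                                   dt = 0.01, record_dt = 1, burn_in = 3000)
  expect_error(verify_hysteresis_loop(tonic, cv), "fewer than two bursts")
})

test_that("frozen-subsystem consistency at burst onset", {
  # freezing the slow variables at burst onset reproduces the first spike
  tr <- burst_trace()
  p <- tr$params
  onset <- tr$spikes[c(TRUE, diff(tr$spikes) >= 250)][2]
  i0 <- max(which(tr$t <= onset - 10))
  y0 <- c(V = unname(tr$V[i0]), tr$gating[i0, ])
  mod <- stellate:::as_cpp_model(p, freeze = c("mNaP", "hKas"),
                                 tabulate = TRUE)
  r <- heun_cpp(mod, unname(y0[c("V", mod$gate_names)]), 1e9, 60, 0.01, 10L)
  expect_gt(length(r$spikes), 0)
  expect_lt(abs((tr$t[i0] + r$spikes[1]) - onset), 5)
})
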