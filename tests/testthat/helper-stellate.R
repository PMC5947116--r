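# Shared fixtures: the default parameter set (kinetics compiled once per
# session) and small programmatic models/traces used as oracles.

default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- model_params()
    cache
  }
})

# minimal kinetics: leak only (closed-form equilibrium V = EL + Iapp/gL)
leak_only_kinetics <- function(gL = 0.15, EL = -88.5) {
  f <- tempfile(fileext = ".ini")
  writeLines(sprintf("version = 1\n[L]\ng = %g\nE = %g\n", gL, EL), f)
  f
}

# leak + one first-order sigmoid gate: a two-variable system with a
# closed-form equilibrium curve Iapp(V) = gL (V-EL) + gX minf(V) (V-EX),
# used as an independent continuation/Jacobian oracle
toy_two_var_kinetics <- function(gX = 1.2, EX = 50, v0 = -50, k = 5,
                                 tau = 20, gL = 0.15, EL = -88.5) {
  f <- tempfile(fileext = ".ini")
  writeLines(sprintf(
    "version = 1\n[X]\ng = %g\nE = %g\ngate m 1\nalpha_m = (1/%g)/(1+exp(-(V+%g)/%g))\nbeta_m = (1/%g)/(1+exp((V+%g)/%g))\n[L]\ng = %g\nE = %g\n",
    gX, EX, tau, -v0, k, tau, -v0, k, gL, EL), f)
  f
}

toy_two_var_closed_form <- function(V, gX = 1.2, EX = 50, v0 = -50, k = 5,
                                    gL = 0.15, EL = -88.5) {
  minf <- 1 / (1 + exp(-(V - v0) / k))
  gL * (V - EL) + gX * minf * (V - EX)
}

# fabricate a stellate_trace with given V/gating series (for spike-metric
# and fast-slow unit tests that need controlled inputs)
synthetic_trace <- function(t, V, gating = NULL, spikes = numeric(0),
                            params = default_params()) {
  gn <- gate_names(params)
  if (is.null(gating)) gating <- matrix(0.5, length(t), length(gn))
  colnames(gating) <- gn
  structure(list(t = t, V = V, gating = gating, spikes = spikes,
                 params = params, dt = diff(t[1:2]), seed = NA_integer_,
                 scheme = "synthetic", diverged = FALSE),
            class = "stellate_trace")
}

# spike train from a vector of ISIs, starting at t0
train_from_isis <- function(isis, t0 = 500, t_end = NULL) {
  times <- t0 + cumsum(c(0, isis))
  spike_train(times, t_start = 0,
              t_end = if (is.null(t_end)) max(times) + 500 else t_end)
}

# standard operating point of the bursting regime
bursting_params <- function() set_params(default_params(), gAHP = 0.425, gh = 2.8)
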