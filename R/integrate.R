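# Time-stepping: fixed-step Heun (deterministic and stochastic) and an
# adaptive high-order scheme with event interpolation for precision work.

#' Default initial state
#'
#' The package convention: start at the AHP-free subthreshold equilibrium
#' (with the AHP gate at 0) when one exists; otherwise, beyond the fold,
#' start from V = -65 mV with all gates at their voltage-local steady state.
#'
#' @param params a `stellate_params` object.
#' @return a [model_state()].
#' @export
default_init <- function(params) {
  eq <- tryCatch(find_equilibria(params), error = function(e) list())
  st <- NULL
  if (length(eq)) {
    stab <- vapply(eq, function(e) isTRUE(attr(e, "stable")), TRUE)
    cand <- if (any(stab)) eq[stab] else eq
    st <- cand[[which.min(vapply(cand, function(e) e$V, 0))]]
  }
  if (is.null(st))
    st <- model_state(-65, steady_gates(params, -65))
  st
}

new_trace <- function(t, y, spikes, params, dt, seed, scheme, diverged = FALSE) {
  gn <- gate_names(params)
  colnames(y) <- c("V", gn)
  structure(list(t = t, V = y[, 1], gating = y[, -1, drop = FALSE],
                 spikes = spikes, params = params, dt = dt, seed = seed,
                 scheme = scheme, diverged = diverged),
            class = "stellate_trace")
}

#' @export
print.stellate_trace <- function(x, ...) {
  cat(sprintf("<stellate_trace>  %.6g ms, %d samples, %d spikes, scheme %s%s\n",
              max(x$t), length(x$t), length(x$spikes), x$scheme,
              if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' @export
plot.stellate_trace <- function(x, ...) {
  graphics::plot(x$t, x$V, type = "l", xlab = "t (ms)", ylab = "V (mV)", ...)
  if (length(x$spikes))
    graphics::points(x$spikes, rep(x$params$spike_threshold, length(x$spikes)),
                     pch = 3, col = 2)
  invisible(x)
}

state_vector <- function(params, init) {
  if (is.null(init)) init <- default_init(params)
  gn <- gate_names(params)
  if (!all(gn %in% names(init$x)))
    stop("initial state is missing gates: ",
         paste(setdiff(gn, names(init$x)), collapse = ", "))
  c(init$V, init$x[gn])
}

#' Deterministic integration
#'
#' Integrates the noise-free model.  The default is fixed-step Heun (for
#' parity with the stochastic scheme); `adaptive = TRUE` uses an embedded
#' Dormand-Prince 5(4) pair at tolerance `tol` with event interpolation,
#' the configuration used for orbit-precision work.  At each detected
#' upward crossing of the spike threshold the spike clock driving the AHP
#' current resets and a spike is logged.
#'
#' @param params a `stellate_params` object (its `sigma` is ignored here).
#' @param init a [model_state()]; default per [default_init()].
#' @param duration integration time (ms).
#' @param dt fixed step (ms); also the recording interval.
#' @param adaptive use the adaptive scheme.
#' @param tol relative/absolute tolerance of the adaptive scheme.
#' @param record_dt sample spacing of the returned trace (ms).
#' @param burn_in initial span discarded from the returned trace (ms).
#' @return a `stellate_trace`; if the state diverges the trace is truncated
#'   and flagged (`$diverged`), not an error.
#' @export
integrate_deterministic <- function(params, init = NULL, duration, dt = 0.01,
                                    adaptive = FALSE, tol = 1e-12,
                                    record_dt = max(dt, 0.05), burn_in = 0) {
  y0 <- state_vector(params, init)
  mod <- as_cpp_model(params, tabulate = !adaptive)
  mod$sigma <- 0
  tss0 <- if (is.null(init) || !is.finite(init$t_since_spike)) TSS_NONE
          else init$t_since_spike
  total <- burn_in + duration
  if (adaptive) {
    r <- dopri_cpp(mod, y0, tss0, total, tol, tol, -1L, TRUE, 0.5, record_dt)
    tr <- new_trace(r$t, r$y, r$spikes, params, NA_real_, NA_integer_,
                    "dopri5(4)", r$failed)
  } else {
    stride <- max(1L, as.integer(round(record_dt / dt)))
    r <- heun_cpp(mod, y0, tss0, total, dt, stride)
    tr <- new_trace(r$t, r$y, r$spikes, params, dt, NA_integer_,
                    "heun", r$diverged)
  }
  drop_burn_in(tr, burn_in)
}

#' Stochastic integration (stochastic Heun)
#'
#' Additive white noise enters the voltage equation only, as
#' `(sigma/C) sqrt(dt) N(0,1)` per step, with the same increment applied in
#' the predictor and the corrector stage (the standard stochastic Heun
#' contract for additive noise).  With `sigma = 0` the output matches the
#' fixed-step deterministic Heun run bitwise.
#'
#' @inheritParams integrate_deterministic
#' @param seed integer seed (mandatory, for reproducibility).
#' @return a `stellate_trace`.
#' @export
integrate_stochastic <- function(params, init = NULL, duration, dt = 0.01,
                                 seed, record_dt = max(dt, 0.05),
                                 burn_in = 0) {
  stopifnot(!missing(seed))
  y0 <- state_vector(params, init)
  mod <- as_cpp_model(params, tabulate = TRUE)
  tss0 <- if (is.null(init) || !is.finite(init$t_since_spike)) TSS_NONE
          else init$t_since_spike
  stride <- max(1L, as.integer(round(record_dt / dt)))
  r <- with_seed(seed, heun_cpp(mod, y0, tss0, burn_in + duration, dt, stride))
  tr <- new_trace(r$t, r$y, r$spikes, params, dt, seed, "stochastic heun",
                  r$diverged)
  drop_burn_in(tr, burn_in)
}

drop_burn_in <- function(tr, burn_in) {
  if (burn_in <= 0) return(tr)
  keep <- tr$t >= burn_in
  tr$t <- tr$t[keep] - burn_in
  tr$V <- tr$V[keep]
  tr$gating <- tr$gating[keep, , drop = FALSE]
  tr$spikes <- tr$spikes[tr$spikes >= burn_in] - burn_in
  tr
}

# evaluate expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Spike detection on a recorded trace
#'
#' Returns the linearly interpolated upward crossing times of the spike
#' threshold, with a refractory guard against threshold chatter.  The
#' integrators log spikes online at full step resolution; this operation
#' re-derives them from the recorded samples (equal within one recording
#' interval).
#'
#' @param trace a `stellate_trace`.
#' @param threshold crossing level (mV); default the trace's own convention.
#' @param refract minimum spike separation (ms).
#' @return a [spike_train()].
#' @export
detect_spikes <- function(trace, threshold = trace$params$spike_threshold,
                          refract = trace$params$refract) {
  V <- trace$V
  t <- trace$t
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  times <- numeric(0)
  last <- -Inf
  for (i in up) {
    frac <- (threshold - V[i]) / (V[i + 1] - V[i])
    ts <- t[i] + frac * (t[i + 1] - t[i])
    if (ts - last >= refract) {
      times <- c(times, ts)
      last <- ts
    }
  }
  spike_train(times, t_start = t[1], t_end = t[length(t)])
}
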