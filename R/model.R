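# Model parameterisation and the membrane right-hand side.
#
# State layout: V (mV) followed by one gating fraction per gate, ordered as
# in the kinetics file.  Gate names are <label><channel> (mNaT, hNaT, mNaP,
# nKdr, mKaf, hKaf, mKas, hKas, nh, nAHP with the default kinetics),
# matching the conventional subscripted symbols for these currents.

TSS_NONE <- 1e9 # "no spike has occurred" sentinel for t_since_spike

#' Model parameters
#'
#' Assembles the full parameterisation of the stellate-cell model: membrane
#' capacitance, applied current, channel set (from a kinetics definition
#' file), noise amplitude and the AHP/spike conventions.  Defaults are the
#' published operating point of the model: `C = 1.46` uF/cm^2,
#' `Iapp = 0.3` uA/cm^2, `sigma = 0.197` uA/cm^2 (so `sigma/C = 0.135`
#' mV ms^-1/2 enters the voltage equation), AHP opening rate
#' `1.5 exp(-t/60)` with closing rate 1.6/ms, and a spike defined as the
#' membrane potential rising through 0 mV.
#'
#' Conductances and reversals can be overridden with the conventional
#' parameter-table names: `gNaT`, `gNaP`, `gKdr`, `gKaf`, `gKas`, `gh`,
#' `gAHP`, `gL` (mS/cm^2) and `ENa`, `EK`, `Eh`, `EL` (mV; `ENa` applies to
#' NaT and NaP, `EK` to Kdr, Kaf, Kas and AHP).
#'
#' @param kinetics a kinetics file path or the result of [read_kinetics()].
#' @param C membrane capacitance (uF/cm^2).
#' @param Iapp applied current (uA/cm^2).
#' @param sigma noise amplitude (uA/cm^2); 0 gives the deterministic model.
#' @param ahp_tau decay constant of the AHP opening rate (ms).
#' @param ahp_alpha0 amplitude of the AHP opening rate (1/ms).
#' @param ahp_beta AHP closing rate (1/ms).
#' @param spike_threshold membrane potential defining a spike event (mV).
#' @param refract minimum separation of logged spike events (ms).
#' @param ... conductance/reversal overrides, e.g. `gh = 2.8, gAHP = 0.425`.
#' @return an object of class `stellate_params`.
#' @examples
#' p <- model_params(gh = 2.8, gAHP = 0.425)
#' p
#' @export
model_params <- function(kinetics = default_kinetics_file(), C = 1.46,
                         Iapp = 0.3, sigma = 0.197, ahp_tau = 60,
                         ahp_alpha0 = 1.5, ahp_beta = 1.6,
                         spike_threshold = 0, refract = 1, ...) {
  if (is.character(kinetics)) kinetics <- read_kinetics(kinetics)
  stopifnot(C > 0, sigma >= 0, ahp_tau > 0)
  p <- structure(list(C = C, Iapp = Iapp, sigma = sigma, ahp_tau = ahp_tau,
                      ahp_alpha0 = ahp_alpha0, ahp_beta = ahp_beta,
                      spike_threshold = spike_threshold, refract = refract,
                      channels = kinetics),
                 class = "stellate_params")
  p <- sync_ahp_rates(p)
  set_params(p, ...)
}

# regenerate the AHP gate's rate expressions from the scalar AHP parameters
sync_ahp_rates <- function(p) {
  if (!is.null(p$channels[["AHP"]]) && length(p$channels[["AHP"]]$gates)) {
    lab <- p$channels[["AHP"]]$gates[[1]]$label
    a <- sprintf("%.17g*exp(-t/%.17g)", p$ahp_alpha0, p$ahp_tau)
    b <- sprintf("%.17g", p$ahp_beta)
    p$channels[["AHP"]]$gates[[1]]$alpha <- compile_rate(a, var = "t")
    p$channels[["AHP"]]$gates[[1]]$beta <- compile_rate(b, var = "t")
  }
  p
}

#' Modify model parameters
#'
#' @param params a `stellate_params` object.
#' @param ... any of `C`, `Iapp`, `sigma`, `ahp_tau`, `ahp_alpha0`,
#'   `ahp_beta`, `spike_threshold`, conductances `g<channel>` or reversals
#'   `ENa`, `EK`, `Eh`, `EL`.
#' @return the modified `stellate_params` object.
#' @export
set_params <- function(params, ...) {
  ov <- list(...)
  for (nm in names(ov)) {
    val <- ov[[nm]]
    if (nm %in% c("C", "Iapp", "sigma", "ahp_tau", "ahp_alpha0", "ahp_beta",
                  "spike_threshold", "refract")) {
      params[[nm]] <- val
      if (startsWith(nm, "ahp_")) params <- sync_ahp_rates(params)
    } else if (grepl("^g", nm) && substring(nm, 2) %in% names(params$channels)) {
      stopifnot(val >= 0)
      params$channels[[substring(nm, 2)]]$g <- val
    } else if (nm == "ENa") {
      for (ch in intersect(c("NaT", "NaP"), names(params$channels)))
        params$channels[[ch]]$E <- val
    } else if (nm == "EK") {
      for (ch in intersect(c("Kdr", "Kaf", "Kas", "AHP"), names(params$channels)))
        params$channels[[ch]]$E <- val
    } else if (nm == "Eh") {
      params$channels[["h"]]$E <- val
    } else if (nm == "EL") {
      params$channels[["L"]]$E <- val
    } else stop("unknown parameter: ", nm)
  }
  params
}

#' Read a parameter configuration file
#'
#' Plain-text `name = value` lines using the conventional parameter names
#' (`C`, `Iapp`, `gNaT`, ..., `ENa`, ..., `sigma`); unset names keep their
#' defaults.  Comments start with `#`.
#'
#' @param path configuration file path.
#' @param kinetics kinetics definition (file path or [read_kinetics()] result).
#' @return a `stellate_params` object.
#' @export
read_params <- function(path, kinetics = default_kinetics_file()) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(trimws(x[2])))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  do.call(model_params, c(list(kinetics = kinetics), vals))
}

#' @export
print.stellate_params <- function(x, ...) {
  cat(sprintf("<stellate_params>  C = %g uF/cm^2, Iapp = %g uA/cm^2, sigma = %g uA/cm^2\n",
              x$C, x$Iapp, x$sigma))
  cat(sprintf("  AHP: alpha(t) = %g exp(-t/%g), beta = %g; spike threshold %g mV\n",
              x$ahp_alpha0, x$ahp_tau, x$ahp_beta, x$spike_threshold))
  g <- vapply(x$channels, function(ch) ch$g, 0)
  cat("  conductances (mS/cm^2):",
      paste(sprintf("g%s=%g", names(g), g), collapse = ", "), "\n")
  invisible(x)
}

#' Gate names of a parameter set
#'
#' Global gating-variable names in state-vector order, formed as
#' `<label><channel>` (e.g. `mNaP`, `hKas`, `nh`, `nAHP`).
#'
#' @param params a `stellate_params` object.
#' @return character vector.
#' @export
gate_names <- function(params) {
  unlist(lapply(params$channels, function(ch)
    vapply(ch$gates, function(gt) paste0(gt$label, ch$name), "")),
    use.names = FALSE)
}

# flat list of gates in state order, each with channel back-reference
gate_list <- function(params) {
  out <- list()
  for (ch in params$channels)
    for (gt in ch$gates) out[[paste0(gt$label, ch$name)]] <- gt
  out
}

#' Model state
#'
#' @param V membrane potential (mV).
#' @param x named vector of gating fractions (one per gate, in [0, 1]).
#' @param t_since_spike elapsed time since the last spike event (ms);
#'   `Inf` if no spike has occurred.
#' @return an object of class `stellate_state`.
#' @export
model_state <- function(V, x, t_since_spike = Inf) {
  if (any(x < 0 | x > 1)) stop("gating fractions must lie in [0, 1]")
  structure(list(V = V, x = x, t_since_spike = t_since_spike),
            class = "stellate_state")
}

#' Gating-variable kinetics
#'
#' First-order opening/closing kinetics of a gating fraction:
#' `dx/dt = alpha (1 - x) - beta x`, with fixed point
#' `x* = alpha / (alpha + beta)`.
#'
#' @param x gating fraction in [0, 1].
#' @param alpha opening rate (1/ms), non-negative.
#' @param beta closing rate (1/ms), non-negative.
#' @return rate of change of `x` (1/ms).
#' @export
gating_rhs <- function(x, alpha, beta) {
  if (any(x < 0 | x > 1)) stop("gating fraction out of [0, 1]")
  if (any(alpha < 0) || any(beta < 0)) stop("rates must be non-negative")
  alpha * (1 - x) - beta * x
}

#' Spike-triggered AHP opening rate
#'
#' The AHP current's opening rate decays exponentially from the time of the
#' last spike: `alpha(t) = alpha0 exp(-t/tau)`; before any spike it is 0.
#'
#' @param t_since_spike time since the last spike (ms), or `Inf`.
#' @param params a `stellate_params` object.
#' @return opening rate (1/ms).
#' @export
ahp_alpha <- function(t_since_spike, params) {
  if (any(t_since_spike < 0)) stop("t_since_spike must be non-negative")
  ifelse(is.finite(t_since_spike),
         params$ahp_alpha0 * exp(-t_since_spike / params$ahp_tau), 0)
}

#' Ionic current of one channel
#'
#' `I_X = g_X psi_X (V - E_X)` with `psi_X` the product of the channel's
#' gating fractions raised to their exponents (1 for the gateless leak).
#' Positive values are outward.
#'
#' @param channel a [channel_spec()].
#' @param state a [model_state()]; gating fractions are looked up by
#'   `<label><channel>` name.
#' @return current density (uA/cm^2).
#' @export
ionic_current <- function(channel, state) {
  psi <- 1
  for (gt in channel$gates) {
    nm <- paste0(gt$label, channel$name)
    if (!nm %in% names(state$x)) stop("state has no gating variable ", nm)
    psi <- psi * state$x[[nm]]^gt$exponent
  }
  channel$g * psi * (state$V - channel$E)
}

#' Membrane right-hand side
#'
#' The deterministic vector field:
#' `C dV/dt = Iapp - sum_X I_X` with gating dynamics per [gating_rhs()],
#' the AHP gate driven by [ahp_alpha()], and the spike clock advancing at
#' unit rate.  This reference implementation mirrors the compiled
#' integrator kernels and is used for verification and equilibrium work.
#'
#' @param state a [model_state()].
#' @param params a `stellate_params` object.
#' @return list with `dV` (mV/ms), `dx` (named, 1/ms) and `dt_since_spike`.
#' @export
membrane_rhs <- function(state, params) {
  if (!is.finite(state$V)) stop("non-finite membrane potential")
  Isum <- sum(vapply(params$channels, ionic_current, 0, state = state))
  dx <- numeric(0)
  for (ch in params$channels) for (gt in ch$gates) {
    nm <- paste0(gt$label, ch$name)
    a <- if (gt$ahp) ahp_alpha(state$t_since_spike, params)
         else gt$alpha$fun(state$V)
    b <- if (gt$ahp) params$ahp_beta else gt$beta$fun(state$V)
    dx[nm] <- gating_rhs(state$x[[nm]], a, b)
  }
  list(dV = (params$Iapp - Isum) / params$C, dx = dx, dt_since_spike = 1)
}

#' Voltage-local steady-state gating fractions
#'
#' `x*(V) = alpha(V) / (alpha(V) + beta(V))` per gate; the AHP gate is 0 in
#' the absence of spikes.
#'
#' @param params a `stellate_params` object.
#' @param V membrane potential (mV), scalar.
#' @return named vector of gating fractions.
#' @export
steady_gates <- function(params, V) {
  gl <- gate_list(params)
  x <- vapply(gl, function(gt) {
    if (gt$ahp) return(0)
    a <- gt$alpha$fun(V)
    b <- gt$beta$fun(V)
    a / (a + b)
  }, 0)
  names(x) <- names(gl)
  x
}

# --- bridge to the compiled kernels ---------------------------------------
# freeze: character vector of gate names whose derivative is clamped to 0.
# tabulate: pre-tabulate voltage-dependent rates on a 0.02 mV grid inside
# the kernel (linear interpolation); used by fixed-step batch integration,
# never by the high-precision adaptive scheme or equilibrium work.
as_cpp_model <- function(params, freeze = character(0), drop_ahp = FALSE,
                         tabulate = FALSE) {
  chans <- params$channels
  if (drop_ahp) chans[["AHP"]] <- NULL
  gates <- list()
  gnames <- character(0)
  for (ch in chans) for (gt in ch$gates) {
    nm <- paste0(gt$label, ch$name)
    gnames <- c(gnames, nm)
    gates[[nm]] <- list(alpha = as.numeric(gt$alpha$code),
                        beta = as.numeric(gt$beta$code),
                        ahp = isTRUE(gt$ahp), frozen = nm %in% freeze)
  }
  channels <- lapply(chans, function(ch) {
    gidx <- vapply(ch$gates, function(gt)
      match(paste0(gt$label, ch$name), gnames), 0L)
    list(g = ch$g, E = ch$E, gidx = as.integer(gidx),
         expo = as.integer(vapply(ch$gates, function(gt) gt$exponent, 0L)))
  })
  list(C = params$C, Iapp = params$Iapp, sigma = params$sigma,
       spike_threshold = params$spike_threshold, refract = params$refract,
       gates = unname(gates), channels = unname(channels),
       gate_names = gnames, tabulate = isTRUE(tabulate))
}
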