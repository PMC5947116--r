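# Equilibria of the AHP-free deterministic system, stability/eigenstructure,
# and one-parameter continuation with saddle-node and Hopf detection.
#
# Key reduction: with the AHP current removed (it is spike-dependent and
# decays to zero in the absence of spikes) every gating variable sits at its
# voltage-local steady state x*(V) at an equilibrium, so the equilibrium
# condition collapses to a scalar current balance in V:
#     F(V) = Iapp - sum_X I_X(V, x*(V)) = 0.
# Moreover F is affine in Iapp and in each maximal conductance, so the
# continuation branch in those parameters has an explicit parameterisation
# by V; folds are extrema of param(V) and are localised by golden-section
# refinement rather than arclength stepping.

# steady-state gating fractions at V with optional frozen overrides
steady_gates_frozen <- function(params, V, frozen = NULL) {
  x <- steady_gates(params, V)
  if (!is.null(frozen)) x[names(frozen)] <- unlist(frozen)
  x
}

# total ionic current at voltage-local steady state (vectorised over V);
# channels in `exclude` are omitted, frozen gates held at given values
total_current_ss <- function(params, V, exclude = "AHP", frozen = NULL) {
  out <- 0
  for (ch in params$channels) {
    if (ch$name %in% exclude) next
    psi <- 1
    for (gt in ch$gates) {
      nm <- paste0(gt$label, ch$name)
      if (!is.null(frozen) && nm %in% names(frozen)) {
        xv <- rep(frozen[[nm]], length(V))
      } else if (gt$ahp) {
        xv <- rep(0, length(V))
      } else {
        a <- gt$alpha$fun(V)
        b <- gt$beta$fun(V)
        xv <- a / (a + b)
      }
      psi <- psi * xv^gt$exponent
    }
    out <- out + ch$g * psi * (V - ch$E)
  }
  out
}

#' Find equilibria of the AHP-free system
#'
#' Seeds a voltage grid, brackets sign changes of the scalar current
#' balance and polishes each root; gating variables are at their
#' voltage-local steady state, the AHP gate at 0.  States are deduplicated
#' within 1e-6 mV and verified to satisfy the reduced right-hand side to
#' 1e-10.
#'
#' @param params a `stellate_params` object.
#' @param V_range voltage window searched (mV).
#' @param n_grid seed-grid resolution.
#' @param frozen optional named list of gate values held fixed (fast-slow
#'   use); frozen gates are treated as parameters, not states.
#' @return list of [model_state()] objects, each with attributes `stable`
#'   (logical) and `eigenvalues` (complex, reduced Jacobian); empty if no
#'   equilibrium exists in the window (e.g. beyond the fold).
#' @export
find_equilibria <- function(params, V_range = c(-120, -20), n_grid = 721,
                            frozen = NULL) {
  Vg <- seq(V_range[1], V_range[2], length.out = n_grid)
  Fg <- params$Iapp - total_current_ss(params, Vg, frozen = frozen)
  roots <- numeric(0)
  sgn <- sign(Fg)
  for (i in which(sgn[-1] * sgn[-length(sgn)] < 0)) {
    r <- uniroot(function(v) params$Iapp - total_current_ss(params, v, frozen = frozen),
                 c(Vg[i], Vg[i + 1]), tol = 1e-13)
    roots <- c(roots, r$root)
  }
  roots <- c(roots, Vg[Fg == 0])
  if (length(roots) == 0) return(list())
  roots <- sort(roots)
  roots <- roots[c(TRUE, diff(roots) > 1e-6)]
  lapply(roots, function(V) {
    x <- steady_gates_frozen(params, V, frozen)
    st <- model_state(V, x)
    ei <- jacobian_eigs(st, params, frozen = frozen, check = FALSE)
    attr(st, "stable") <- all(Re(ei) < 0)
    attr(st, "eigenvalues") <- ei
    attr(st, "rhs_norm") <- reduced_rhs_norm(params, st, frozen)
    st
  })
}

# sup-norm of the AHP-free right-hand side at a state (active coords only)
reduced_rhs_norm <- function(params, state, frozen = NULL) {
  mod <- as_cpp_model(params, drop_ahp = TRUE,
                      freeze = if (is.null(frozen)) character(0) else names(frozen))
  y <- c(state$V, state$x[mod$gate_names])
  max(abs(rhs_cpp(mod, y, TSS_NONE)))
}

#' Jacobian eigenvalues at an equilibrium
#'
#' Central finite-difference Jacobian (step `1e-6 * max(1, |coordinate|)`)
#' of the AHP-free system, linearised in V and all non-frozen gating
#' variables.  For a focus (leading complex-conjugate pair) the resonant
#' frequency is `|Im lambda| / (2 pi)` converted from 1/ms to Hz.
#'
#' @param state a [model_state()] at (or near) an equilibrium.
#' @param params a `stellate_params` object.
#' @param frozen optional named list of gate values treated as parameters.
#' @param check warn if the state is not an equilibrium to tolerance.
#' @return complex eigenvalue vector (1/ms), with attribute
#'   `focus_frequency_hz` (`NA` if the spectrum is purely real).
#' @export
jacobian_eigs <- function(state, params, frozen = NULL, check = TRUE) {
  mod <- as_cpp_model(params, drop_ahp = TRUE,
                      freeze = if (is.null(frozen)) character(0) else names(frozen))
  gn <- mod$gate_names
  active <- c(TRUE, !(gn %in% names(frozen)))
  y0 <- c(state$V, state$x[gn])
  if (check && max(abs(rhs_cpp(mod, y0, TSS_NONE))[active]) > 1e-8)
    warning("state is not an equilibrium to tolerance; eigenvalues are indicative only")
  idx <- which(active)
  n <- length(idx)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, abs(y0[idx[j]]))
    yp <- y0; yp[idx[j]] <- yp[idx[j]] + h
    ym <- y0; ym[idx[j]] <- ym[idx[j]] - h
    J[, j] <- (rhs_cpp(mod, yp, TSS_NONE)[idx] - rhs_cpp(mod, ym, TSS_NONE)[idx]) / (2 * h)
  }
  ei <- eigen(J, only.values = TRUE)$values
  cplx <- ei[abs(Im(ei)) > 1e-9]
  f <- if (length(cplx)) abs(Im(cplx[which.max(Re(cplx))])) * 1000 / (2 * pi) else NA_real_
  attr(ei, "focus_frequency_hz") <- f
  ei
}

#' Focus resonant frequency
#'
#' @param eigs result of [jacobian_eigs()].
#' @return frequency in Hz, or `NA` for an all-real spectrum (a node).
#' @export
focus_frequency <- function(eigs) attr(eigs, "focus_frequency_hz")

#' Continue the equilibrium branch in one parameter
#'
#' Supported parameters: `"Iapp"` and any maximal conductance
#' (`"gh"`, `"gAHP"`, `"gNaP"`, ...).  The branch (stable and unstable
#' segments alike) is swept via its explicit V-parameterisation; saddle-node
#' folds are extrema of param(V), localised to better than 1e-6, and Hopf
#' points are zero crossings of the leading complex pair's real part.
#'
#' @param params a `stellate_params` object (the continued parameter's
#'   current value is ignored).
#' @param param parameter name.
#' @param range numeric length-2: parameter window of interest.
#' @param V_range voltage window swept.
#' @param n grid resolution in V.
#' @return an object of class `equilibrium_branch`: a data frame
#'   (`param`, `V`, `stable`, `re_lead`, `im_lead`, `focus_hz`) with
#'   attributes `folds` and `hopf` (data frames of localised events),
#'   `param_name`, and `params`.
#' @export
continue_branch <- function(params, param, range, V_range = c(-120, 40),
                            n = 1601) {
  pfun <- branch_param_fun(params, param)
  Vg <- seq(V_range[1], V_range[2], length.out = n)
  pv <- pfun(Vg)
  keep <- is.finite(pv) & pv >= range[1] & pv <= range[2]
  # events are localised on the full window, then filtered to `range`
  folds <- data.frame(param = numeric(0), V = numeric(0), min_abs_eig = numeric(0))
  dpv <- diff(pv)
  for (i in which(is.finite(dpv[-1]) & is.finite(dpv[-length(dpv)]) &
                  dpv[-1] * dpv[-length(dpv)] < 0) + 1L) {
    lo <- Vg[i - 1]; hi <- Vg[i + 1]
    maximum <- pv[i] >= pv[i - 1] # local max vs min
    o <- optimize(pfun, c(lo, hi), maximum = maximum, tol = 1e-10)
    Vf <- if (maximum) o$maximum else o$minimum
    pf <- if (maximum) o$objective else o$objective
    if (pf >= range[1] && pf <= range[2]) {
      prm <- set_branch_param(params, param, pf)
      st <- model_state(Vf, steady_gates(prm, Vf))
      ei <- jacobian_eigs(st, prm, check = FALSE)
      folds <- rbind(folds, data.frame(param = pf, V = Vf,
                                       min_abs_eig = min(abs(ei))))
    }
  }
  Vb <- Vg[keep]
  pb <- pv[keep]
  stab <- logical(length(Vb))
  re1 <- im1 <- fhz <- numeric(length(Vb))
  for (k in seq_along(Vb)) {
    prm <- set_branch_param(params, param, pb[k])
    st <- model_state(Vb[k], steady_gates(prm, Vb[k]))
    ei <- jacobian_eigs(st, prm, check = FALSE)
    lead <- ei[which.max(Re(ei))]
    cplx <- ei[abs(Im(ei)) > 1e-9]
    stab[k] <- all(Re(ei) < 0)
    re1[k] <- if (length(cplx)) max(Re(cplx)) else Re(lead)
    im1[k] <- if (length(cplx)) abs(Im(cplx[which.max(Re(cplx))])) else 0
    fhz[k] <- focus_frequency(ei)
  }
  hopf <- data.frame(param = numeric(0), V = numeric(0), freq_hz = numeric(0))
  if (length(Vb) > 1) {
    cross <- which(re1[-1] * re1[-length(re1)] < 0 &
                   im1[-1] > 1e-9 & im1[-length(im1)] > 1e-9)
    for (i in cross) {
      r <- uniroot(function(v) {
        p <- pfun(v)
        prm <- set_branch_param(params, param, p)
        st <- model_state(v, steady_gates(prm, v))
        ei <- jacobian_eigs(st, prm, check = FALSE)
        cp <- ei[abs(Im(ei)) > 1e-9]
        if (!length(cp)) return(Re(ei[which.max(Re(ei))]))
        max(Re(cp))
      }, c(Vb[i], Vb[i + 1]), tol = 1e-10)
      ph <- pfun(r$root)
      if (!is.finite(ph) || ph < range[1] || ph > range[2]) next
      prm <- set_branch_param(params, param, ph)
      ei <- jacobian_eigs(model_state(r$root, steady_gates(prm, r$root)),
                          prm, check = FALSE)
      fhz <- focus_frequency(ei)
      if (!is.finite(fhz) || fhz <= 0) next # not a complex-pair crossing
      hopf <- rbind(hopf, data.frame(param = ph, V = r$root, freq_hz = fhz))
    }
  }
  br <- data.frame(param = pb, V = Vb, stable = stab, re_lead = re1,
                   im_lead = im1, focus_hz = fhz)
  structure(br, folds = folds, hopf = hopf, param_name = param,
            params = params, class = c("equilibrium_branch", "data.frame"))
}

#' @export
print.equilibrium_branch <- function(x, ...) {
  cat(sprintf("<equilibrium_branch> in %s: %d points, %d fold(s), %d Hopf point(s)\n",
              attr(x, "param_name"), nrow(x), nrow(attr(x, "folds")),
              nrow(attr(x, "hopf"))))
  f <- attr(x, "folds")
  if (nrow(f)) for (i in seq_len(nrow(f)))
    cat(sprintf("  fold: %s = %.6g at V = %.4f mV (min |eig| %.2g)\n",
                attr(x, "param_name"), f$param[i], f$V[i], f$min_abs_eig[i]))
  h <- attr(x, "hopf")
  if (nrow(h)) for (i in seq_len(nrow(h)))
    cat(sprintf("  Hopf: %s = %.6g at V = %.4f mV (%.3f Hz)\n",
                attr(x, "param_name"), h$param[i], h$V[i], h$freq_hz[i]))
  invisible(x)
}

# explicit parameterisation param(V) of the equilibrium branch
branch_param_fun <- function(params, param) {
  if (param == "Iapp")
    return(function(V) total_current_ss(params, V))
  if (grepl("^g", param) && substring(param, 2) %in% names(params$channels)) {
    chn <- substring(param, 2)
    ch <- params$channels[[chn]]
    return(function(V) {
      rest <- total_current_ss(params, V, exclude = c("AHP", chn))
      psi <- 1
      for (gt in ch$gates) {
        if (gt$ahp) { psi <- psi * 0; next }
        a <- gt$alpha$fun(V); b <- gt$beta$fun(V)
        psi <- psi * (a / (a + b))^gt$exponent
      }
      den <- psi * (V - ch$E)
      out <- (params$Iapp - rest) / den
      out[abs(den) < 1e-12] <- NA_real_
      out
    })
  }
  stop("continuation parameter must be 'Iapp' or a conductance, got ", param)
}

set_branch_param <- function(params, param, value) {
  if (param == "Iapp") return(set_params(params, Iapp = value))
  args <- list(params)
  args[[param]] <- value
  do.call(set_params, args)
}
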