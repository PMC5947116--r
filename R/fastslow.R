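# Fast-slow decomposition of the bursting dynamics: the persistent-sodium
# activation (mNaP) and slow A-type potassium inactivation (hKas) are the
# slow variables; freezing them leaves a fast subsystem whose bifurcation
# structure (subcritical Hopf SCH, homoclinic HC) organises the burst as a
# hysteresis loop.  Convention: the AHP gate stays in the fast subsystem
# with its clock driven by the fast subsystem's own spikes; on quiescent
# (equilibrium) branches it is clamped to 0.

SLOW_VARS <- c("mNaP", "hKas")

#' Rank gating variables by slowness
#'
#' Scores each gating variable on a bursting trace by its total variation
#' per burst cycle normalised by its range: a slow variable drifts smoothly
#' (one up-down sweep per cycle, score near 1), a fast spiking variable
#' oscillates every spike (score roughly the number of spikes per cycle).
#'
#' @param trace a deterministic bursting `stellate_trace` spanning at least
#'   4 burst cycles.
#' @param isi_max burst-chaining threshold (ms).
#' @return data frame (`variable`, `score`, `range`) sorted slowest first,
#'   with attribute `slow` (the top-2 variable names).
#' @export
identify_slow_variables <- function(trace, isi_max = 250) {
  spk <- trace$spikes
  if (length(spk) < 4) stop("need a bursting trace (too few spikes)")
  gaps <- which(diff(spk) >= isi_max)
  n_cycles <- length(gaps) + 1L
  if (n_cycles < 4) stop("need at least 4 burst cycles for a slowness ranking")
  g <- trace$gating
  tv <- apply(g, 2, function(x) sum(abs(diff(x))))
  rng <- apply(g, 2, function(x) diff(range(x)))
  score <- tv / (2 * pmax(rng, 1e-12) * n_cycles)
  out <- data.frame(variable = colnames(g), score = score, range = rng,
                    row.names = NULL)
  out <- out[order(out$score), ]
  attr(out, "slow") <- out$variable[1:2]
  out
}

# total ionic current with mNaP entering linearly: returns intercept c0(V)
# and coefficient c1(V) such that  G(V, m) = c0 + c1 * m , with hKas either
# frozen at a value or tied to m by hKas = a m + b (mslow mode).
fast_balance_coeffs <- function(params, V, hKas = NULL, slow_line = NULL) {
  base <- total_current_ss(params, V, exclude = c("AHP", "NaP", "Kas"))
  np <- params$channels[["NaP"]]
  kas <- params$channels[["Kas"]]
  mKas_inf <- {
    gt <- kas$gates[[which(vapply(kas$gates, function(g) g$label == "m", TRUE))]]
    a <- gt$alpha$fun(V); b <- gt$beta$fun(V)
    (a / (a + b))^gt$exponent
  }
  kas_fac <- kas$g * mKas_inf * (V - kas$E)
  nap_fac <- np$g * (V - np$E)
  if (!is.null(slow_line)) {
    c0 <- base + kas_fac * slow_line[["intercept"]]
    c1 <- nap_fac + kas_fac * slow_line[["slope"]]
  } else {
    c0 <- base + kas_fac * hKas
    c1 <- nap_fac
  }
  list(c0 = c0, c1 = c1)
}

# frozen slow values for a given (m, mode)
frozen_slow <- function(m, hKas = NULL, slow_line = NULL) {
  h <- if (!is.null(slow_line)) slow_line[["slope"]] * m + slow_line[["intercept"]]
       else hKas
  list(mNaP = m, hKas = h)
}

# does the frozen fast subsystem sustain a spiking orbit? (fixed-step probe,
# trajectory continued from `init`); returns orbit stats or NULL
fast_orbit_probe <- function(params, frozen, init_y, t_probe = 4000,
                             dt = 0.01, gap_max = 1500) {
  mod <- as_cpp_model(params, freeze = names(frozen), tabulate = TRUE)
  mod$sigma <- 0
  y <- init_y
  gn <- mod$gate_names
  y[1 + match(names(frozen), gn)] <- unlist(frozen)
  r <- heun_cpp(mod, y, 0, t_probe, dt, 50L)
  sp <- r$spikes
  ok <- length(sp) >= 3 && (t_probe - sp[length(sp)]) < gap_max &&
    max(diff(c(0, sp))) < gap_max
  if (!ok) return(NULL)
  tail_win <- r$t > sp[length(sp)] - mean(tail(diff(sp), 3)) # last cycle
  list(y_end = r$y_end, period = mean(tail(diff(sp), 3)),
       Vmax = max(r$y[tail_win, 1]), Vmin = min(r$y[tail_win, 1]))
}

#' Bifurcation diagram of the frozen fast subsystem
#'
#' Sweeps the slow coordinate (frozen `mNaP` at fixed `hKas`, or the single
#' collapsed slow variable along a [fit_slow_reduction()] line) and
#' assembles: the equilibrium branch with stability and subcritical-Hopf
#' points (eigenvalue real-part crossings, AHP gate clamped to 0), and the
#' stable periodic-orbit branch by direct integration with its homoclinic
#' end localised by bisection.  Unstable periodic-orbit branches are not
#' computed and are reported as unavailable.
#'
#' @param params a `stellate_params` object.
#' @param hKas frozen slow-potassium inactivation (ignored if `slow_line`).
#' @param slow_line optional [fit_slow_reduction()] result (or list with
#'   `slope`, `intercept`): sweep along `hKas = slope * m + intercept`.
#' @param m_range swept range of the slow coordinate.
#' @param n_eq equilibrium-branch resolution.
#' @param n_po periodic-branch grid resolution.
#' @param hc_tol bisection tolerance for the homoclinic end.
#' @return an object of class `fast_bif_diagram` with elements `eq`
#'   (data frame `m`, `V`, `stable`, `re_lead`, `im_lead`), `events`
#'   (`label`, `m`, `V`), `po` (`m`, `Vmax`, `Vmin`, `period`),
#'   `unavailable` (character), and `mode`.
#' @export
fast_bif_diagram <- function(params, hKas = NULL, slow_line = NULL,
                             m_range = c(0.05, 0.6), n_eq = 501, n_po = 25,
                             hc_tol = 1e-3) {
  if (is.null(hKas) && is.null(slow_line))
    stop("give either a frozen hKas value or a slow_line")
  mode <- if (is.null(slow_line)) sprintf("mNaP at hKas = %.4g", hKas)
          else "mslow along the slow-reduction line"
  # --- equilibrium branch: explicit m(V) ---
  Vg <- seq(-90, -20, length.out = 2001)
  cf <- fast_balance_coeffs(params, Vg, hKas = hKas, slow_line = slow_line)
  mV <- (params$Iapp - cf$c0) / cf$c1
  keep <- is.finite(mV) & mV >= m_range[1] & mV <= m_range[2]
  Vb <- Vg[keep]; mb <- mV[keep]
  stab <- logical(length(Vb)); re1 <- im1 <- numeric(length(Vb))
  for (k in seq_along(Vb)) {
    fr <- frozen_slow(mb[k], hKas, slow_line)
    st <- model_state(Vb[k], steady_gates_frozen(params, Vb[k], fr))
    ei <- jacobian_eigs(st, params, frozen = fr, check = FALSE)
    cplx <- ei[abs(Im(ei)) > 1e-9]
    stab[k] <- all(Re(ei) < 0)
    re1[k] <- if (length(cplx)) max(Re(cplx)) else max(Re(ei))
    im1[k] <- if (length(cplx)) abs(Im(cplx[which.max(Re(cplx))])) else 0
  }
  eq <- data.frame(m = mb, V = Vb, stable = stab, re_lead = re1, im_lead = im1)
  events <- data.frame(label = character(0), m = numeric(0), V = numeric(0))
  sch_n <- 0L
  if (length(Vb) > 1) {
    cross <- which(re1[-1] * re1[-length(re1)] < 0 &
                   (im1[-1] > 1e-9 | im1[-length(im1)] > 1e-9))
    for (i in cross) {
      r <- uniroot(function(v) {
        cc <- fast_balance_coeffs(params, v, hKas = hKas, slow_line = slow_line)
        m <- (params$Iapp - cc$c0) / cc$c1
        fr <- frozen_slow(m, hKas, slow_line)
        st <- model_state(v, steady_gates_frozen(params, v, fr))
        ei <- jacobian_eigs(st, params, frozen = fr, check = FALSE)
        cp <- ei[abs(Im(ei)) > 1e-9]
        if (!length(cp)) return(max(Re(ei)))
        max(Re(cp))
      }, c(Vb[i], Vb[i + 1]), tol = 1e-10)
      cc <- fast_balance_coeffs(params, r$root, hKas = hKas, slow_line = slow_line)
      sch_n <- sch_n + 1L
      lab <- paste0("SCH", if (is.null(slow_line)) sch_n else sch_n + 1L)
      events <- rbind(events, data.frame(
        label = lab, m = (params$Iapp - cc$c0) / cc$c1, V = r$root))
    }
  }
  # --- stable periodic-orbit branch: sweep m downward, continued init ---
  po <- data.frame(m = numeric(0), Vmax = numeric(0), Vmin = numeric(0),
                   period = numeric(0))
  mg <- seq(m_range[2], m_range[1], length.out = n_po)
  init0 <- state_vector(params, spiking_init(params))
  y <- init0
  last_exists <- NA_real_
  first_gone <- NA_real_
  for (m in mg) {
    pr <- fast_orbit_probe(params, frozen_slow(m, hKas, slow_line), y)
    if (is.null(pr)) { first_gone <- m; break }
    po <- rbind(po, data.frame(m = m, Vmax = pr$Vmax, Vmin = pr$Vmin,
                               period = pr$period))
    y <- pr$y_end
    last_exists <- m
  }
  if (!is.na(last_exists) && !is.na(first_gone)) {
    lo <- first_gone; hi <- last_exists # orbit exists at hi
    y_hi <- y
    while (hi - lo > hc_tol) {
      mid <- (lo + hi) / 2
      pr <- fast_orbit_probe(params, frozen_slow(mid, hKas, slow_line), y_hi)
      if (is.null(pr)) lo <- mid else { hi <- mid; y_hi <- pr$y_end }
    }
    hc <- (lo + hi) / 2
    events <- rbind(events, data.frame(
      label = paste0("HC", if (is.null(slow_line)) 1L else 2L),
      m = hc, V = NA_real_))
  }
  structure(list(eq = eq, events = events, po = po, mode = mode,
                 hKas = hKas, slow_line = slow_line,
                 unavailable = c("unstable periodic-orbit branches (SCH3/HC3/SNP1 fine structure)"),
                 params = params),
            class = "fast_bif_diagram")
}

#' @export
print.fast_bif_diagram <- function(x, ...) {
  cat(sprintf("<fast_bif_diagram>  %s\n", x$mode))
  cat(sprintf("  equilibrium branch: %d points (%d stable)\n", nrow(x$eq),
              sum(x$eq$stable)))
  if (nrow(x$events)) for (i in seq_len(nrow(x$events)))
    cat(sprintf("  %s at m = %.4f\n", x$events$label[i], x$events$m[i]))
  cat(sprintf("  stable periodic branch: %d points\n", nrow(x$po)))
  cat("  unavailable:", x$unavailable, "\n")
  invisible(x)
}

#' Bistability window of a fast-subsystem diagram
#'
#' The interval between the homoclinic end of the stable periodic orbit and
#' the subcritical Hopf of the equilibrium (empty if either is missing).
#'
#' @param diagram a `fast_bif_diagram`.
#' @return numeric length-2 (lower = HC, upper = SCH) or `NULL`.
#' @export
bistability_window <- function(diagram) {
  ev <- diagram$events
  hc <- ev$m[grepl("^HC", ev$label)]
  sch <- ev$m[grepl("^SCH", ev$label)]
  if (!length(hc) || !length(sch)) return(NULL)
  # the relevant pair: lowest HC and the SCH above it
  hc <- min(hc)
  sch <- sch[sch > hc]
  if (!length(sch)) return(NULL)
  c(HC = hc, SCH = min(sch))
}

#' Fit the one-dimensional slow reduction
#'
#' Ordinary least squares of `hKas` on `mNaP` over one full burst cycle of
#' a deterministic bursting orbit, collapsing the two slow variables onto
#' the line `hKas = slope * mslow + intercept` with `mslow = mNaP`.
#'
#' @param trace a deterministic bursting `stellate_trace` (at least one
#'   full burst period after burn-in).
#' @param isi_max burst-chaining threshold (ms), used to delimit one cycle.
#' @return an object of class `slow_reduction`: `slope`, `intercept`,
#'   `rms` (residual RMS), `rms_rel` (RMS / hKas range), `m_range`, `n`.
#' @export
fit_slow_reduction <- function(trace, isi_max = 250) {
  spk <- trace$spikes
  if (length(spk) < 2) stop("need a bursting trace")
  bstart <- spk[c(TRUE, diff(spk) >= isi_max)]
  if (length(bstart) < 2)
    stop("need at least two burst onsets to delimit one full cycle")
  win <- trace$t >= bstart[1] & trace$t < bstart[2]
  m <- trace$gating[win, "mNaP"]
  h <- trace$gating[win, "hKas"]
  if (diff(range(m)) < 1e-8) stop("degenerate (constant) slow trajectory")
  fit <- lm(h ~ m)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 rms = sqrt(mean(fit$residuals^2)),
                 rms_rel = sqrt(mean(fit$residuals^2)) / diff(range(h)),
                 m_range = range(m), n = sum(win)),
            class = "slow_reduction")
}

#' @export
print.slow_reduction <- function(x, ...) {
  cat(sprintf("<slow_reduction>  hKas = %.4f * mslow + %.4f  (residual RMS %.2g, %.1f%% of range)\n",
              x$slope, x$intercept, x$rms, 100 * x$rms_rel))
  invisible(x)
}

#' Subcritical-Hopf and homoclinic curves over a grid of hKas values
#'
#' Runs [fast_bif_diagram()] per `hKas` value and collects the SCH1 and HC1
#' locations, giving the two bifurcation curves of the fast subsystem in
#' the (mNaP, hKas) slow plane.
#'
#' @param params a `stellate_params` object.
#' @param hKas_values grid of frozen hKas values.
#' @param ... passed to [fast_bif_diagram()].
#' @return data frame (`hKas`, `m_sch`, `m_hc`).
#' @export
hysteresis_curves <- function(params, hKas_values, ...) {
  out <- lapply(hKas_values, function(h) {
    d <- fast_bif_diagram(params, hKas = h, ...)
    ev <- d$events
    sch <- ev$m[grepl("^SCH", ev$label)]
    hc <- ev$m[grepl("^HC", ev$label)]
    data.frame(hKas = h,
               m_sch = if (length(sch)) min(sch) else NA_real_,
               m_hc = if (length(hc)) min(hc) else NA_real_)
  })
  do.call(rbind, out)
}

#' Verify the subHopf/homoclinic hysteresis loop on a burst orbit
#'
#' Checks, against fast-subsystem bifurcation curves from
#' [hysteresis_curves()], that (a) each burst onset occurs where the slow
#' trajectory crosses the SCH curve from the stable-equilibrium side,
#' (b) each burst offset occurs at the HC curve, and (c) the inter-burst
#' segment tracks the fast equilibrium branch in V.  All three together
#' support the subcritical-Hopf/homoclinic burster classification.
#'
#' @param trace a deterministic bursting `stellate_trace`.
#' @param curves result of [hysteresis_curves()] covering the orbit's hKas
#'   excursion.
#' @param params the `stellate_params` used for the trace.
#' @param tol crossing tolerance in slow-variable units.
#' @param v_tol inter-burst voltage tracking tolerance (mV).
#' @param isi_max burst-chaining threshold (ms).
#' @return an object of class `hysteresis_report`: logical checks
#'   `onset_ok`, `offset_ok`, `quiescent_ok`, per-burst detail, and
#'   `classification` (`"subcritical Hopf/homoclinic"` when all hold).
#' @export
verify_hysteresis_loop <- function(trace, curves, params = trace$params,
                                   tol = 0.01, v_tol = 2, isi_max = 250) {
  spk <- trace$spikes
  if (length(spk) < 4) stop("not a bursting trace")
  if (any(!is.finite(curves$m_sch)) || any(!is.finite(curves$m_hc)))
    stop("curves grid has gaps; widen or refine the hKas grid")
  starts <- spk[c(TRUE, diff(spk) >= isi_max)]
  ends <- spk[c(diff(spk) >= isi_max, TRUE)]
  if (length(starts) < 2) stop("fewer than two bursts in the trace")
  sch_at <- function(h) approx(curves$hKas, curves$m_sch, xout = h, rule = 2)$y
  hc_at <- function(h) approx(curves$hKas, curves$m_hc, xout = h, rule = 2)$y
  slow_at <- function(tt) c(m = approx(trace$t, trace$gating[, "mNaP"], tt)$y,
                            h = approx(trace$t, trace$gating[, "hKas"], tt)$y)
  onset_d <- offset_d <- numeric(0)
  for (k in seq_along(starts)) {
    on <- slow_at(starts[k])
    onset_d <- c(onset_d, on[["m"]] - sch_at(on[["h"]]))
    off <- slow_at(ends[k])
    offset_d <- c(offset_d, off[["m"]] - hc_at(off[["h"]]))
  }
  # quiescent tracking: sample the middle of inter-burst gaps
  quiet_d <- numeric(0)
  for (k in seq_len(length(starts) - 1)) {
    tm <- seq(ends[k] + 100, starts[k + 1] - 50, length.out = 8)
    for (tt in tm) {
      sl <- slow_at(tt)
      eqs <- find_equilibria(params, frozen = list(mNaP = sl[["m"]],
                                                   hKas = sl[["h"]]))
      stab <- vapply(eqs, function(e) isTRUE(attr(e, "stable")), TRUE)
      if (!any(stab)) { quiet_d <- c(quiet_d, Inf); next }
      Veq <- eqs[stab][[1]]$V
      quiet_d <- c(quiet_d, abs(approx(trace$t, trace$V, tt)$y - Veq))
    }
  }
  onset_ok <- all(abs(onset_d) < tol)
  offset_ok <- all(abs(offset_d) < tol)
  quiescent_ok <- all(quiet_d < v_tol)
  structure(list(onset_ok = onset_ok, offset_ok = offset_ok,
                 quiescent_ok = quiescent_ok,
                 onset_mismatch = onset_d, offset_mismatch = offset_d,
                 quiescent_dist = quiet_d,
                 classification = if (onset_ok && offset_ok && quiescent_ok)
                   "subcritical Hopf/homoclinic" else "unclassified"),
            class = "hysteresis_report")
}

#' @export
print.hysteresis_report <- function(x, ...) {
  cat(sprintf("<hysteresis_report>  onset %s | offset %s | quiescent tracking %s\n",
              ifelse(x$onset_ok, "ok", "FAIL"), ifelse(x$offset_ok, "ok", "FAIL"),
              ifelse(x$quiescent_ok, "ok", "FAIL")))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}
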