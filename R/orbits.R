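# Poincare return-map machinery on the section V = 0 (the spike threshold
# surface, where the AHP clock resets): crossing sequences from the
# high-precision integrator, periodic-orbit detection by Picard iteration,
# map Jacobians by numerical Frechet derivatives, multipliers, map Lyapunov
# exponents, and flip/homoclinic localisation by bisection.
#
# Coordinate convention: because the spike clock resets to zero at every
# upward crossing, the return map acts on the gating vector alone; the
# incoming inter-spike interval is recorded with each crossing as a
# diagnostic but is a function of the previous crossing, not a map
# coordinate.

#' A suprathreshold initial state
#'
#' Spike-like kick used to reach the spiking attractor in regimes where the
#' rest state coexists with (or has replaced) the periodic orbit.
#'
#' @param params a `stellate_params` object.
#' @return a [model_state()].
#' @export
spiking_init <- function(params) {
  x <- steady_gates(params, -55)
  if ("mNaT" %in% names(x)) x[["mNaT"]] <- 0.9
  model_state(20, x, t_since_spike = Inf)
}

# stream crossings of the section in chunks, continuing the trajectory;
# stop_fun(cross_matrix) may end the stream early
stream_crossings <- function(params, init, max_crossings, t_max, tol,
                             chunk = 25L, stop_fun = NULL) {
  mod <- as_cpp_model(params)
  mod$sigma <- 0
  y <- state_vector(params, init)
  tss <- if (is.finite(init$t_since_spike)) init$t_since_spike else TSS_NONE
  t0 <- 0
  cross <- NULL
  times <- isi <- numeric(0)
  while (t0 < t_max && length(times) < max_crossings) {
    r <- dopri_cpp(mod, y, tss, min(t_max - t0, 60000),
                   tol, tol, as.integer(min(chunk, max_crossings - length(times))),
                   FALSE, 0.5, 1)
    if (r$failed)
      return(list(cross = cross, times = times, isi = isi, failed = TRUE))
    if (length(r$cross_t)) {
      cross <- rbind(cross, r$cross_y[, -1, drop = FALSE])
      times <- c(times, t0 + r$cross_t)
      isi <- c(isi, r$cross_isi)
    }
    if (length(r$cross_t) == 0) break # quiescent: no crossing within the cap
    if (!is.null(stop_fun) && isTRUE(stop_fun(cross))) break
    y <- r$y_end
    tss <- r$tss_end
    t0 <- t0 + r$t_end
  }
  if (!is.null(cross)) colnames(cross) <- gate_names(params)
  list(cross = cross, times = times, isi = isi, failed = FALSE)
}

#' Poincare-section crossing sequence
#'
#' Successive upward crossings of the section, integrated at tolerance
#' `tol` with event interpolation, recorded in the full non-V state
#' (gating vector; the incoming inter-spike interval is attached).
#'
#' @param params a `stellate_params` object.
#' @param init initial [model_state()]; defaults to [spiking_init()].
#' @param max_crossings crossings to collect.
#' @param t_max time cap (ms); an empty result within the cap means the
#'   trajectory is quiescent.
#' @param tol integrator tolerance.
#' @return an object of class `section_sequence`: list with `states`
#'   (crossings x gates matrix), `times`, `isi`, `quiescent`, `failed`.
#' @export
return_map_sequence <- function(params, init = spiking_init(params),
                                max_crossings = 100, t_max = 120000,
                                tol = 1e-12) {
  s <- stream_crossings(params, init, max_crossings, t_max, tol)
  structure(list(states = s$cross, times = s$times, isi = s$isi,
                 quiescent = is.null(s$cross), failed = s$failed,
                 params = params),
            class = "section_sequence")
}

#' @export
print.section_sequence <- function(x, ...) {
  cat(sprintf("<section_sequence>  %d crossings%s%s\n",
              if (is.null(x$states)) 0L else nrow(x$states),
              if (x$quiescent) " [quiescent]" else "",
              if (x$failed) " [FAILED]" else ""))
  invisible(x)
}

#' Find a periodic orbit of the return map (Picard iteration)
#'
#' Streams section crossings and, for each new crossing, computes the
#' Euclidean distance to past crossings (rolling window); a periodic orbit
#' of period n is identified when the distance between crossings k and
#' k+n falls below `tol`.  Non-convergence within `max_crossings` yields an
#' aperiodic/chaotic candidate carrying the raw sequence; a quiescent
#' trajectory is an error distinct from non-convergence.
#'
#' @inheritParams return_map_sequence
#' @param tol closure tolerance in the gating coordinates.
#' @param window how many past crossings are kept for comparison.
#' @return an object of class `return_map_orbit`: `period`, `states`
#'   (period x gates), `isi` (per crossing), `converged`, `closure`
#'   (achieved distance), plus the raw crossing sequence.
#' @export
find_periodic_orbit <- function(params, init = spiking_init(params),
                                max_crossings = 400, t_max = 400000,
                                tol = 1e-12, window = 500) {
  found <- NULL
  check <- function(cross) {
    n <- nrow(cross)
    if (n < 2) return(FALSE)
    lo <- max(1, n - window)
    d <- sqrt(colSums((t(cross[lo:(n - 1), , drop = FALSE]) - cross[n, ])^2))
    j <- which(d < tol)
    if (length(j)) {
      # most recent match gives the minimal period
      found <<- list(k = lo + j[length(j)] - 1, n_cross = n)
      return(TRUE)
    }
    FALSE
  }
  s <- stream_crossings(params, init, max_crossings, t_max, tol = 1e-12,
                        stop_fun = check)
  if (s$failed) stop("integration failure while searching for a periodic orbit")
  if (is.null(s$cross))
    stop("trajectory is quiescent: no section crossing within the time cap")
  if (is.null(found)) {
    return(structure(list(period = NA_integer_, states = NULL,
                          isi = s$isi, converged = FALSE, closure = NA_real_,
                          crossings = s$cross, times = s$times,
                          params = params, label = "aperiodic/chaotic candidate"),
                     class = "return_map_orbit"))
  }
  k <- found$k
  n <- found$n_cross - k
  idx <- k:(k + n - 1)
  closure <- sqrt(sum((s$cross[k + n, ] - s$cross[k, ])^2))
  structure(list(period = as.integer(n),
                 states = s$cross[idx, , drop = FALSE],
                 times = s$times[idx], isi = s$isi[k + seq_len(n)],
                 converged = TRUE, closure = closure,
                 crossings = s$cross, params = params,
                 label = sprintf("period-%d orbit", n)),
            class = "return_map_orbit")
}

#' @export
print.return_map_orbit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<return_map_orbit>  period %d, closure %.2e, ISIs %s ms\n",
                x$period, x$closure,
                paste(sprintf("%.1f", x$isi), collapse = " ")))
  else
    cat(sprintf("<return_map_orbit>  %s (%d crossings)\n", x$label,
                nrow(x$crossings)))
  invisible(x)
}

# n-fold return map: gating vector at a crossing -> gating vector after n
# further crossings (time cap proportional to the expected period)
nfold_map <- function(params, x, n, tol, t_cap) {
  mod <- as_cpp_model(params)
  mod$sigma <- 0
  y <- c(params$spike_threshold, x)
  r <- dopri_cpp(mod, y, 0, t_cap, tol, tol, as.integer(n), FALSE, 0.5, 1)
  if (r$failed || length(r$cross_t) < n) return(NULL)
  list(x = r$cross_y[n, -1], t = r$cross_t[n])
}

#' Jacobian and multipliers of the n-fold return map
#'
#' Central finite differences of the n-fold map about the orbit's first
#' crossing state (per-coordinate step `delta * max(1, |x_i|)`); the
#' multipliers are the Jacobian's eigenvalues.  A stable orbit has all
#' multipliers strictly inside the unit circle.
#'
#' @param orbit a converged `return_map_orbit`.
#' @param params a `stellate_params` object.
#' @param delta finite-difference step scale.
#' @param tol integrator tolerance.
#' @return list with `J`, `multipliers` (sorted by modulus, decreasing) and
#'   `stable`.
#' @export
map_jacobian <- function(orbit, params = orbit$params, delta = 1e-6,
                         tol = 1e-12) {
  if (!isTRUE(orbit$converged)) stop("map_jacobian needs a converged periodic orbit")
  x0 <- orbit$states[1, ]
  n <- orbit$period
  t_cap <- 10 * max(sum(orbit$isi), 1000)
  ng <- length(x0)
  J <- matrix(0, ng, ng, dimnames = list(names(x0), names(x0)))
  for (j in seq_len(ng)) {
    h <- delta * max(1, abs(x0[j]))
    xp <- x0; xp[j] <- min(xp[j] + h, 1)
    xm <- x0; xm[j] <- max(xm[j] - h, 0)
    fp <- nfold_map(params, xp, n, tol, t_cap)
    fm <- nfold_map(params, xm, n, tol, t_cap)
    if (is.null(fp) || is.null(fm))
      stop("derivative evaluation left the section's basin (coordinate ",
           names(x0)[j], ")")
    J[, j] <- (fp$x - fm$x) / (xp[j] - xm[j])
  }
  mult <- eigen(J, only.values = TRUE)$values
  mult <- mult[order(Mod(mult), decreasing = TRUE)]
  list(J = J, multipliers = mult, stable = all(Mod(mult) < 1))
}

#' Largest Lyapunov exponent of a discrete map (QR method)
#'
#' Accumulates QR factorisations of per-iterate Jacobian products along a
#' trajectory of a supplied map and returns all Lyapunov exponents (per
#' iterate).  Used with the flow-induced return map by [mle_map()] and
#' directly testable against closed-form map oracles.
#'
#' @param step_fun function of the state returning `list(x = next state,
#'   J = Jacobian at the current state)`.
#' @param x0 initial state (numeric vector).
#' @param n_iter iterates to accumulate.
#' @param discard initial iterates discarded as transient.
#' @return numeric vector of Lyapunov exponents, decreasing.
#' @export
lyapunov_qr <- function(step_fun, x0, n_iter = 200, discard = 0) {
  x <- x0
  for (i in seq_len(discard)) x <- step_fun(x)$x
  d <- length(x0)
  Q <- diag(d)
  acc <- numeric(d)
  for (i in seq_len(n_iter)) {
    s <- step_fun(x)
    qr_ <- qr(s$J %*% Q)
    Q <- qr.Q(qr_)
    rd <- diag(qr.R(qr_))
    # fix signs so Q columns keep consistent orientation
    Q <- Q %*% diag(sign(rd), d)
    acc <- acc + log(abs(rd))
    x <- s$x
  }
  sort(acc / n_iter, decreasing = TRUE)
}

#' Map Lyapunov exponent of the Poincare return map
#'
#' Follows the crossing sequence from `init`, computes per-iterate map
#' Jacobians by forward finite differences, and accumulates the largest
#' exponent by the QR method.  Negative values indicate a stable periodic
#' orbit (a fixed point of the iterated map); positive values a chaotic
#' regime.
#'
#' @param params a `stellate_params` object.
#' @param init initial state; defaults to [spiking_init()].
#' @param n_iter measured iterates (after `transient_t` of plain
#'   integration); fewer than `min_iter` available crossings is an error.
#' @param transient_t transient integration time discarded (ms).
#' @param delta finite-difference step.
#' @param tol integrator tolerance for the Jacobian integrations (looser
#'   than orbit detection; the exponent needs only moderate accuracy).
#' @param min_iter minimum usable iterates.
#' @return scalar MLE (log units per map iterate), with attribute
#'   `n_iter`.
#' @export
mle_map <- function(params, init = spiking_init(params), n_iter = 200,
                    transient_t = 30000, delta = 1e-6, tol = 1e-9,
                    min_iter = 50) {
  mod <- as_cpp_model(params)
  mod$sigma <- 0
  # settle onto the attractor
  y <- state_vector(params, init)
  r <- dopri_cpp(mod, y, TSS_NONE, transient_t, tol, tol, -1L, FALSE, 0.5, 1)
  if (r$failed) stop("integration failure during transient")
  if (length(r$cross_t) == 0) stop("quiescent trajectory: MLE undefined")
  # land exactly on a crossing
  r2 <- dopri_cpp(mod, r$y_end, r$tss_end, 60000, tol, tol, 1L, FALSE, 0.5, 1)
  if (length(r2$cross_t) == 0) stop("trajectory stopped crossing the section")
  x <- r2$cross_y[1, -1]
  ng <- length(x)
  t_cap <- 30 * max(mean(diff(r$cross_t)), 500)
  count <- 0L
  step_fun <- function(xc) {
    f0 <- nfold_map(params, xc, 1, tol, t_cap)
    if (is.null(f0)) stop("trajectory left the spiking regime after ", count,
                          " iterates")
    J <- matrix(0, ng, ng)
    for (j in seq_len(ng)) {
      h <- delta * max(1, abs(xc[j]))
      xp <- xc; xp[j] <- min(xp[j] + h, 1)
      fp <- nfold_map(params, xp, 1, tol, t_cap)
      if (is.null(fp)) stop("perturbed trajectory left the section's basin")
      J[, j] <- (fp$x - f0$x) / (xp[j] - xc[j])
    }
    count <<- count + 1L
    list(x = f0$x, J = J)
  }
  exps <- tryCatch(lyapunov_qr(step_fun, x, n_iter = n_iter),
                   error = function(e) {
                     if (count < min_iter) stop(e)
                     warning("MLE truncated at ", count, " iterates")
                     NA_real_
                   })
  out <- max(exps)
  attr(out, "n_iter") <- count
  out
}

# integer period of the attractor by fixed-step classification:
# 0 = quiescent, 1 = tonic, n = spikes per burst, NA = chaotic/inconclusive
quick_period <- function(params, init = spiking_init(params),
                         duration = 12000, burn_in = 6000, dt = 0.01) {
  tr <- integrate_deterministic(params, init, duration = duration, dt = dt,
                                record_dt = 1, burn_in = burn_in)
  lab <- classify_deterministic(tr)
  out <- switch(lab, SS = 0L, T = 1L, C = NA_integer_,
                inconclusive = NA_integer_, as.integer(lab))
  attr(out, "trace") <- tr
  out
}

#' Locate a flip (period-doubling / spike-adding) bifurcation
#'
#' Bisection on the attractor's integer period (spikes per burst) between
#' bracket endpoints with different periods; backed, where computable, by
#' the leading multiplier approaching -1 on the lower-period side.
#'
#' @param params a `stellate_params` object.
#' @param param parameter name (any [set_params()] scalar).
#' @param bracket numeric length-2 straddling the period change.
#' @param tol bisection tolerance in the parameter.
#' @param duration,burn_in classification run lengths (ms).
#' @return located parameter value, with attributes `period_lo`,
#'   `period_hi` (periods at the final bracket ends).
#' @export
locate_flip <- function(params, param, bracket, tol = 1e-4,
                        duration = 12000, burn_in = 6000) {
  pval <- function(v) {
    args <- list(params); args[[param]] <- v
    do.call(set_params, args)
  }
  per <- function(v) quick_period(pval(v), duration = duration, burn_in = burn_in)
  lo <- bracket[1]; hi <- bracket[2]
  plo <- per(lo); phi <- per(hi)
  if (identical(as.integer(plo), as.integer(phi)))
    stop("bracket endpoints have the same period (", plo, "); no flip inside")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    pm <- per(mid)
    same_as_lo <- identical(as.integer(pm), as.integer(plo))
    if (same_as_lo) { lo <- mid; plo <- pm } else { hi <- mid; phi <- pm }
  }
  out <- (lo + hi) / 2
  attr(out, "period_lo") <- as.integer(plo)
  attr(out, "period_hi") <- as.integer(phi)
  out
}

#' Locate a homoclinic bifurcation (orbit destruction)
#'
#' Bisection on the existence of a sustained spiking orbit: one bracket end
#' must spike persistently, the other be quiescent.  The trajectory is
#' continued from the spiking side's state across bisection steps so that
#' the orbit (not the rest state of the bistable pair) is tracked.  Near
#' the located value the orbit's period diverges, the signature of a
#' homoclinic; the achieved period growth is attached.
#'
#' @param params a `stellate_params` object.
#' @param param parameter name.
#' @param bracket numeric length-2; orbit must exist at exactly one end.
#' @param tol bisection tolerance in the parameter.
#' @param t_probe integration span used to test persistence (ms).
#' @param gap_max a silent span longer than this declares the orbit gone (ms).
#' @param tol_int integrator tolerance.
#' @return located parameter value, with attributes `exists_lo` and
#'   `period_near` (mean ISI of the surviving orbit at the last existing
#'   parameter probed).
#' @export
locate_homoclinic <- function(params, param, bracket, tol = 1e-4,
                              t_probe = 25000, gap_max = 8000,
                              tol_int = 1e-8) {
  pval <- function(v) {
    args <- list(params); args[[param]] <- v
    do.call(set_params, args)
  }
  carry <- spiking_init(params) # continued across steps from the existing side
  period_near <- NA_real_
  probe <- function(v, init) {
    s <- stream_crossings(pval(v), init, max_crossings = 200,
                          t_max = t_probe, tol = tol_int)
    n <- if (is.null(s$cross)) 0L else nrow(s$cross)
    # persistent: keeps crossing through the probe span with bounded gaps
    exists <- n >= 3 && (t_probe - s$times[n]) < gap_max &&
      max(diff(c(0, s$times))) < gap_max
    list(exists = exists, s = s)
  }
  n_probes <- 2L
  lo <- bracket[1]; hi <- bracket[2]
  rlo <- probe(lo, carry); rhi <- probe(hi, carry)
  if (rlo$exists == rhi$exists)
    stop("bracket ends are in the same regime (orbit ",
         if (rlo$exists) "exists" else "absent", " at both)")
  exists_lo <- rlo$exists
  grab_state <- function(r) {
    n <- nrow(r$s$cross)
    model_state(params$spike_threshold, r$s$cross[n, ], t_since_spike = 0)
  }
  carry <- grab_state(if (exists_lo) rlo else rhi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    rm_ <- probe(mid, carry)
    n_probes <- n_probes + 1L
    if (rm_$exists) {
      carry <- grab_state(rm_)
      period_near <- mean(tail(diff(rm_$s$times), 3))
      if (exists_lo) lo <- mid else hi <- mid
    } else {
      if (exists_lo) hi <- mid else lo <- mid
    }
  }
  out <- (lo + hi) / 2
  attr(out, "exists_lo") <- exists_lo
  attr(out, "period_near") <- period_near
  attr(out, "n_probes") <- n_probes
  out
}
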