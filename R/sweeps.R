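# Orchestration of the model's computational experiments: two-parameter
# (gAHP, gh) sweeps of the stochastic clustering statistic and of the
# deterministic regime, deterministic-stochastic concordance,
# distance-to-reference maps, and the subthreshold Iapp sweep.

#' Reference clustering fractions
#'
#' Experimental mean P_C of dorsal stellate cells: wild-type (`WT`) and
#' rTg4510 transgenic (`TG`) animals.  Reference constants for
#' [reference_distance_map()], not model outputs.
#' @export
pc_reference <- c(WT = 0.69, TG = 0.37)

#' Sweep specification
#'
#' @param gAHP,gh grid coordinate vectors (mS/cm^2).
#' @param n_cells replicate stochastic simulations per grid point.
#' @param duration measured span per simulation (ms, after burn-in).
#' @param burn_in discarded initial span (ms).
#' @param sigma noise amplitude (uA/cm^2).
#' @param dt integration step (ms).
#' @param base_seed seed root; per-cell seeds are derived deterministically
#'   as `base_seed + 97 * cell_index + replicate`.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(gAHP = seq(0, 1.6, length.out = 11),
                       gh = seq(1, 4, length.out = 11), n_cells = 10,
                       duration = 20000, burn_in = 1000, sigma = 0.197,
                       dt = 0.01, base_seed = 1) {
  stopifnot(length(gAHP) >= 1, length(gh) >= 1, n_cells >= 1, duration > 0)
  structure(list(gAHP = gAHP, gh = gh, n_cells = n_cells,
                 duration = duration, burn_in = burn_in, sigma = sigma,
                 dt = dt, base_seed = base_seed),
            class = "sweep_spec")
}

cell_seed <- function(spec, cell_index, replicate) {
  (spec$base_seed + 97L * cell_index + replicate) %% .Machine$integer.max
}

sweep_grid <- function(spec) {
  expand.grid(gAHP = spec$gAHP, gh = spec$gh, KEEP.OUT.ATTRS = FALSE)
}

#' Stochastic P_C sweep
#'
#' For every (gAHP, gh) grid point, runs `n_cells` stochastic simulations
#' (burn-in discarded), partitions each spike train with the cluster rule
#' and records the mean P_C; per-point integration failures are recorded
#' and the point marked invalid rather than aborting the sweep.
#'
#' @param spec a [sweep_spec()].
#' @param params base `stellate_params` (gAHP, gh, sigma overridden per point).
#' @param progress print per-row progress.
#' @return a data frame of class `pc_sweep` with columns `gAHP`, `gh`,
#'   `pc` (mean over replicates with defined P_C), `pc_se`, `n_defined`,
#'   `spikes_per_cluster` (replicate-mean cluster size), `n_spikes`,
#'   `failed`.
#' @export
run_pc_sweep <- function(spec, params = model_params(), progress = FALSE) {
  grid <- sweep_grid(spec)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    prm <- set_params(params, gAHP = grid$gAHP[i], gh = grid$gh[i],
                      sigma = spec$sigma)
    init <- default_init(prm)
    pcs <- spc <- nsp <- numeric(0)
    failed <- 0L
    for (r in seq_len(spec$n_cells)) {
      tr <- integrate_stochastic(prm, init, duration = spec$duration,
                                 dt = spec$dt, seed = cell_seed(spec, i, r),
                                 record_dt = 1, burn_in = spec$burn_in)
      if (tr$diverged) { failed <- failed + 1L; next }
      part <- partition_clusters(spike_train(tr$spikes, 0, spec$duration))
      pcs <- c(pcs, part$pc)
      spc <- c(spc, if (length(part$spikes_per_cluster))
        mean(part$spikes_per_cluster) else 0)
      nsp <- c(nsp, part$n_spikes)
    }
    ok <- !is.nan(pcs)
    rows[[i]] <- data.frame(
      gAHP = grid$gAHP[i], gh = grid$gh[i],
      pc = if (any(ok)) mean(pcs[ok]) else NaN,
      pc_se = if (sum(ok) > 1) sd(pcs[ok]) / sqrt(sum(ok)) else NA_real_,
      n_defined = sum(ok),
      spikes_per_cluster = if (length(spc)) mean(spc) else NaN,
      n_spikes = if (length(nsp)) mean(nsp) else 0,
      failed = failed)
    if (progress && i %% length(spec$gAHP) == 0)
      message(sprintf("pc sweep: %d/%d points", i, nrow(grid)))
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("pc_sweep", "data.frame"), spec = spec)
}

#' Deterministic regime sweep
#'
#' Classifies the noise-free attractor at each grid point (steady state,
#' tonic, n spikes per burst, or chaotic/irregular) from a fixed-step
#' deterministic run started from a suprathreshold state.
#'
#' @param spec a [sweep_spec()] (its `duration`/`burn_in` are used; noise
#'   fields ignored).
#' @param params base `stellate_params`.
#' @param progress print per-row progress.
#' @return data frame of class `regime_sweep` with columns `gAHP`, `gh`,
#'   `label`, `spikes_per_cluster` (numeric encoding: SS 0, otherwise the
#'   replicate cluster-rule mean, see [concordance()]), `n_spikes`.
#' @export
run_regime_sweep <- function(spec, params = model_params(), progress = FALSE) {
  grid <- sweep_grid(spec)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    prm <- set_params(params, gAHP = grid$gAHP[i], gh = grid$gh[i], sigma = 0)
    tr <- integrate_deterministic(prm, spiking_init(prm),
                                  duration = spec$duration, dt = spec$dt,
                                  record_dt = 1, burn_in = spec$burn_in)
    lab <- if (tr$diverged) "failed" else classify_deterministic(tr)
    part <- partition_clusters(spike_train(tr$spikes, 0, spec$duration))
    spc <- if (length(part$spikes_per_cluster)) mean(part$spikes_per_cluster)
           else 0
    rows[[i]] <- data.frame(gAHP = grid$gAHP[i], gh = grid$gh[i],
                            label = lab, spikes_per_cluster = spc,
                            n_spikes = part$n_spikes)
    if (progress && i %% length(spec$gAHP) == 0)
      message(sprintf("regime sweep: %d/%d points", i, nrow(grid)))
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("regime_sweep", "data.frame"), spec = spec)
}

#' Deterministic-stochastic concordance
#'
#' Pearson correlation between the deterministic spikes-per-cluster and the
#' stochastic replicate-mean spikes-per-cluster over a shared grid.  Both
#' sides are encoded with the same cluster rule (a tonic train is a single
#' cluster containing all its spikes; a quiescent point contributes 0), so
#' the deterministic encoding for tonic/chaotic points is the measured
#' cluster-rule value rather than a symbolic constant.
#'
#' @param det a `regime_sweep`.
#' @param stoch a `pc_sweep` on the same grid.
#' @return Pearson correlation with attribute `n` (shared valid points).
#' @export
concordance <- function(det, stoch) {
  key_d <- paste(signif(det$gAHP, 10), signif(det$gh, 10))
  key_s <- paste(signif(stoch$gAHP, 10), signif(stoch$gh, 10))
  shared <- intersect(key_d, key_s)
  d <- det$spikes_per_cluster[match(shared, key_d)]
  s <- stoch$spikes_per_cluster[match(shared, key_s)]
  ok <- is.finite(d) & is.finite(s)
  if (sum(ok) < 10) stop("fewer than 10 shared valid grid points")
  r <- cor(d[ok], s[ok])
  attr(r, "n") <- sum(ok)
  r
}

#' Distance-to-reference P_C map
#'
#' Per-cell `|P_C - reference|`, the map used to read plausible parameter
#' paths against experimental clustering levels (see [pc_reference]).
#'
#' @param map a `pc_sweep`.
#' @param reference scalar reference P_C (e.g. `pc_reference["WT"]`).
#' @return the sweep data frame with a `distance` column.
#' @export
reference_distance_map <- function(map, reference) {
  stopifnot(is.numeric(reference), length(reference) == 1)
  map$distance <- abs(map$pc - reference)
  map
}

#' Subthreshold Iapp sweep with ensemble spectra
#'
#' For each applied-current level, simulates `n_cells` stochastic
#' subthreshold traces, excludes spike-contaminated replicates (flagging
#' the level when they exceed 10 percent), and returns the ensemble-mean
#' multitaper spectrum, theta spectral ratio and peak frequency per level.
#'
#' @param levels Iapp values (uA/cm^2), below the spiking threshold region.
#' @param params base `stellate_params`.
#' @param n_cells replicates per level.
#' @param duration measured span (ms).
#' @param sigma noise amplitude (uA/cm^2); the published subthreshold
#'   analyses use `sigma/C = 0.005`.
#' @param base_seed seed root.
#' @param dt integration step (ms).
#' @param burn_in discarded span (ms).
#' @return data frame of class `iapp_sweep` (`Iapp`, `theta_ratio`,
#'   `theta_se`, `peak_hz`, `peak_se`, `n_used`, `n_spiking`, `flagged`)
#'   with attribute `spectra` (list of per-level mean `power_spectrum`).
#' @export
run_iapp_sweep <- function(levels, params = model_params(), n_cells = 10,
                           duration = 20000, sigma = 0.005 * params$C,
                           base_seed = 1, dt = 0.01, burn_in = 1000) {
  spectra <- list()
  rows <- vector("list", length(levels))
  for (j in seq_along(levels)) {
    prm <- set_params(params, Iapp = levels[j], sigma = sigma)
    init <- default_init(prm)
    th <- pk <- numeric(0)
    n_spiking <- 0L
    mean_power <- NULL
    for (r in seq_len(n_cells)) {
      tr <- integrate_stochastic(prm, init, duration = duration, dt = dt,
                                 seed = base_seed + 97L * j + r,
                                 record_dt = 1, burn_in = burn_in)
      if (length(tr$spikes) > 0) { n_spiking <- n_spiking + 1L; next }
      ps <- multitaper_psd(tr)
      th <- c(th, theta_ratio(ps))
      pk <- c(pk, as.numeric(peak_frequency(ps, band = c(1, 50))))
      mean_power <- if (is.null(mean_power)) ps$power else mean_power + ps$power
      if (is.null(spectra[[as.character(levels[j])]]))
        spectra[[as.character(levels[j])]] <- ps
    }
    n_used <- length(th)
    if (!is.null(mean_power)) {
      sp <- spectra[[as.character(levels[j])]]
      sp$power <- mean_power / n_used
      spectra[[as.character(levels[j])]] <- sp
    }
    rows[[j]] <- data.frame(
      Iapp = levels[j],
      theta_ratio = if (n_used) mean(th) else NaN,
      theta_se = if (n_used > 1) sd(th) / sqrt(n_used) else NA_real_,
      peak_hz = if (n_used) mean(pk) else NaN,
      peak_se = if (n_used > 1) sd(pk) / sqrt(n_used) else NA_real_,
      n_used = n_used, n_spiking = n_spiking,
      flagged = n_spiking > 0.1 * n_cells)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("iapp_sweep", "data.frame"), spectra = spectra)
}
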