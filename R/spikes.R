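# Spike trains, the cluster rule and the clustered-firing statistic P_C.
#
# A cluster is a maximal run of >= 2 spikes with every internal inter-spike
# interval strictly < isi_max (250 ms), preceded and followed by quiescent
# gaps strictly > quiet_min (300 ms); recording edges count as quiescence.
# Gaps in [isi_max, quiet_min] neither chain spikes nor qualify as
# quiescence, so runs flanked by such gaps are unclustered.

#' Spike train
#'
#' @param times ordered spike times (ms), strictly increasing.
#' @param t_start,t_end recording bounds (ms).
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, t_start = 0,
                        t_end = if (length(times)) max(times) else 0) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < t_start || times[length(times)] > t_end))
    stop("spike times outside [t_start, t_end]")
  structure(list(times = times, t_start = t_start, t_end = t_end),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train>  %d spikes in [%g, %g] ms\n", length(x$times),
              x$t_start, x$t_end))
  invisible(x)
}

#' Partition a spike train into clusters
#'
#' Applies the cluster definition above and computes `P_C`, the fraction of
#' spikes belonging to clusters.  An empty train yields `pc = NaN`
#' (undefined, excluded from ensemble averages); a train whose spikes form
#' no cluster yields `pc = 0`.
#'
#' @param train a [spike_train()].
#' @param isi_max chaining threshold (ms): internal ISIs must be `< isi_max`.
#' @param quiet_min quiescence threshold (ms): flanking gaps must be
#'   `> quiet_min`.
#' @return an object of class `cluster_partition` with elements `clusters`
#'   (list of spike-index vectors), `unclustered` (indices), `pc`,
#'   `spikes_per_cluster` and `n_spikes`.
#' @examples
#' tr <- spike_train(c(1000, 1100, 1200, 1600), t_start = 0, t_end = 2000)
#' partition_clusters(tr)$pc # 0.75
#' @export
partition_clusters <- function(train, isi_max = 250, quiet_min = 300) {
  times <- train$times
  n <- length(times)
  out <- structure(list(clusters = list(), unclustered = integer(0),
                        pc = NaN, spikes_per_cluster = integer(0),
                        n_spikes = n, isi_max = isi_max,
                        quiet_min = quiet_min),
                   class = "cluster_partition")
  if (n == 0) return(out)
  isi <- diff(times)
  # maximal runs chained by ISI < isi_max
  breaks <- which(!(isi < isi_max))
  starts <- c(1, breaks + 1)
  ends <- c(breaks, n)
  clusters <- list()
  unclustered <- integer(0)
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    gap_before <- if (starts[k] == 1) Inf else times[starts[k]] - times[starts[k] - 1]
    gap_after <- if (ends[k] == n) Inf else times[ends[k] + 1] - times[ends[k]]
    if (length(idx) >= 2 && gap_before > quiet_min && gap_after > quiet_min)
      clusters[[length(clusters) + 1]] <- idx
    else unclustered <- c(unclustered, idx)
  }
  out$clusters <- clusters
  out$unclustered <- unclustered
  out$spikes_per_cluster <- vapply(clusters, length, 0L)
  out$pc <- sum(out$spikes_per_cluster) / n
  out
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition>  %d spikes, %d clusters, P_C = %.4g\n",
              x$n_spikes, length(x$clusters), x$pc))
  if (length(x$spikes_per_cluster))
    cat("  spikes per cluster:", paste(x$spikes_per_cluster, collapse = " "), "\n")
  invisible(x)
}

#' Ensemble mean of P_C
#'
#' @param ensemble list of [spike_train()] objects (or `cluster_partition`s).
#' @param ... passed to [partition_clusters()].
#' @return list with `mean`, `se`, `n` (trains with defined `pc`) and
#'   `n_undefined`.
#' @export
mean_pc <- function(ensemble, ...) {
  pcs <- vapply(ensemble, function(tr) {
    if (inherits(tr, "cluster_partition")) tr$pc
    else partition_clusters(tr, ...)$pc
  }, 0)
  ok <- !is.nan(pcs)
  list(mean = if (any(ok)) mean(pcs[ok]) else NaN,
       se = if (sum(ok) > 1) sd(pcs[ok]) / sqrt(sum(ok)) else if (any(ok)) 0 else NaN,
       n = sum(ok), n_undefined = sum(!ok))
}

#' Classify a deterministic firing regime
#'
#' Labels a burn-in-free deterministic trace as a steady state (`"SS"`, no
#' spikes), tonic firing (`"T"`, all inter-spike intervals within 1 percent),
#' periodic bursting with a constant number of spikes per burst (the label
#' is that integer), or chaotic/irregular firing (`"C"`).  Bursts are runs
#' of spikes chained by ISIs `< isi_max`; the first and last (possibly
#' truncated) runs are ignored when judging constancy.
#'
#' @param trace a `stellate_trace` (or a [spike_train()]).
#' @param isi_max burst-chaining threshold (ms).
#' @param tonic_tol relative ISI spread below which firing is tonic.
#' @return character label: `"SS"`, `"T"`, an integer as character, `"C"`,
#'   or `"inconclusive"` (spiking present but fewer than 10 ISIs).
#' @export
classify_deterministic <- function(trace, isi_max = 250, tonic_tol = 0.01) {
  train <- if (inherits(trace, "spike_train")) trace else
    spike_train(trace$spikes, t_start = min(trace$t), t_end = max(trace$t))
  times <- train$times
  if (length(times) == 0) return("SS")
  if (length(times) < 11) return("inconclusive")
  isi <- diff(times)
  if ((max(isi) - min(isi)) / mean(isi) < tonic_tol) return("T")
  breaks <- which(!(isi < isi_max))
  if (length(breaks) == 0) return("T") # single uninterrupted run, ISIs vary
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(times))
  sizes <- ends - starts + 1
  if (length(sizes) > 2) sizes <- sizes[2:(length(sizes) - 1)] # drop truncated edge runs
  if (length(sizes) < 3) return("inconclusive")
  if (all(sizes == sizes[1])) {
    if (sizes[1] == 1) return("T")
    return(as.character(sizes[1]))
  }
  "C"
}
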