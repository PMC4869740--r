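#' @importFrom rlang abort
#' @importFrom stats prcomp kmeans
NULL

as_trace <- function(trace, sampling_rate = NULL) {
  if (inherits(trace, "plb_recording")) {
    list(samples = trace$trace, sampling_rate = trace$sampling_rate, band = NULL)
  } else if (inherits(trace, "plb_trace")) {
    trace
  } else {
    if (is.null(sampling_rate)) abort("Supply `sampling_rate` with a bare numeric trace.")
    list(samples = as.numeric(trace), sampling_rate = sampling_rate, band = NULL)
  }
}

#' Band-pass filter a continuous trace
#'
#' Zero-phase 4th-order Butterworth band-pass (applied forward and backward
#' with [signal::filtfilt()]), 300-9000 Hz by default: the high-pass edge
#' removes slow field-potential components, the low-pass edge the
#' high-frequency noise that obscures action-potential shape. Zero-phase
#' filtering leaves spike times, and hence latency measurements, unshifted.
#'
#' @param trace Numeric trace, `plb_trace` or `plb_recording`.
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < Nyquist.
#' @param sampling_rate Samples per second (taken from the object when a
#'   recording/trace is supplied).
#' @param order Butterworth order of each pass (default 4).
#' @return A `plb_trace`: list with `samples`, `sampling_rate`, `band`.
#' @export
bandpass_filter <- function(trace, low = 300, high = 9000,
                            sampling_rate = NULL, order = 4) {
  tr <- as_trace(trace, sampling_rate)
  fs <- tr$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("Band edges must satisfy 0 < low < high < sampling_rate / 2.")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  structure(
    list(
      samples = as.numeric(signal::filtfilt(bf, tr$samples - mean(tr$samples))),
      sampling_rate = fs,
      band = c(low, high)
    ),
    class = "plb_trace"
  )
}

#' @export
print.plb_trace <- function(x, ...) {
  cat(sprintf("<plb_trace> %d samples at %d Hz, band %s\n",
              length(x$samples), x$sampling_rate,
              if (is.null(x$band)) "none" else paste(x$band, collapse = "-")))
  invisible(x)
}

#' Robust noise estimate of a filtered trace
#'
#' Median absolute deviation scaled to the Gaussian SD (MAD / 0.6745),
#' insensitive to the spikes riding on the noise; `estimator = "sd"` gives
#' the plain standard deviation instead.
#'
#' @param x Numeric samples.
#' @param estimator `"mad"` (default) or `"sd"`.
#' @return Noise SD in trace units.
#' @export
noise_sd <- function(x, estimator = c("mad", "sd")) {
  estimator <- match.arg(estimator)
  if (estimator == "mad") stats::mad(x) else stats::sd(x)
}

#' Detect spikes by negative threshold crossing
#'
#' Marks local minima of the filtered trace that cross an amplitude threshold
#' of `k_sd` noise standard deviations below zero (3 SD by default), merges
#' events closer than the lockout keeping the deeper minimum, and extracts
#' fixed-length snippets aligned on the waveform minimum (0.8 ms before to
#' 1.6 ms after). Events too close to the trace edges for a full snippet are
#' dropped.
#'
#' @param filtered A `plb_trace` from [bandpass_filter()] (or a bare numeric
#'   vector with `sampling_rate`).
#' @param k_sd Threshold in noise SDs (default 3); `Inf` detects nothing.
#' @param lockout Minimum separation between events, seconds.
#' @param estimator Noise estimator passed to [noise_sd()].
#' @param window_ms Snippet extent (pre, post) around the minimum, ms.
#' @param interpolate When `TRUE` (default), snippets are re-sampled with a
#'   spline at a parabolically interpolated sub-sample trough position,
#'   removing the one-sample alignment jitter that otherwise inflates
#'   within-unit waveform variance.
#' @param sampling_rate Needed only for bare numeric input.
#' @return A `plb_spikes` tibble: `time_s`, `amplitude` (trough value) and a
#'   `snippet` list-column; attributes `sampling_rate`, `threshold`,
#'   `alignment` (index of the minimum within each snippet).
#' @export
detect_spikes <- function(filtered, k_sd = 3, lockout = 0.001,
                          estimator = c("mad", "sd"),
                          window_ms = c(0.8, 1.6),
                          interpolate = TRUE,
                          sampling_rate = NULL) {
  tr <- as_trace(filtered, sampling_rate)
  x <- tr$samples
  fs <- tr$sampling_rate
  if (length(x) == 0L) abort("Trace is empty.")
  n_pre <- round(window_ms[1] * 1e-3 * fs)
  n_post <- round(window_ms[2] * 1e-3 * fs)
  empty <- tibble::tibble(
    time_s = numeric(0), amplitude = numeric(0), snippet = list()
  )
  sdn <- noise_sd(x, match.arg(estimator))
  if (sdn == 0) sdn <- stats::sd(x)  # noise-free traces: MAD of sparse spikes is 0
  thr <- -k_sd * sdn
  if (!is.finite(thr) || is.na(sdn) || sdn == 0) {
    return(structure(empty, sampling_rate = fs, threshold = thr,
                     alignment = n_pre + 1L, class = c("plb_spikes", class(empty))))
  }
  n <- length(x)
  below <- which(x < thr)
  below <- below[below > 1L & below < n]
  cand <- below[x[below] <= x[below - 1L] & x[below] < x[below + 1L]]

  # lockout: scan in time order, keep the deeper of two close minima
  if (length(cand) > 1L) {
    lock_n <- round(lockout * fs)
    keep <- integer(0)
    cur <- cand[1]
    for (i in cand[-1]) {
      if (i - cur <= lock_n) {
        if (x[i] < x[cur]) cur <- i
      } else {
        keep <- c(keep, cur); cur <- i
      }
    }
    cand <- c(keep, cur)
  }
  pad <- 8L  # margin for sub-sample interpolation
  cand <- cand[cand - n_pre - pad >= 1L & cand + n_post + pad <= n]
  snippets <- lapply(cand, function(i) {
    if (interpolate) {
      # parabolic sub-sample trough position, then spline resampling so the
      # minimum sits exactly on the alignment sample (reduces jitter that
      # would otherwise dominate the principal components)
      den <- x[i - 1L] - 2 * x[i] + x[i + 1L]
      d <- if (den > 0) 0.5 * (x[i - 1L] - x[i + 1L]) / den else 0
      d <- max(min(d, 0.5), -0.5)
      lo <- i - n_pre - pad
      hi <- i + n_post + pad
      stats::spline(lo:hi, x[lo:hi], xout = i + d + seq(-n_pre, n_post),
                    method = "natural")$y
    } else {
      x[(i - n_pre):(i + n_post)]
    }
  })
  out <- tibble::tibble(
    time_s = (cand - 1L) / fs,
    amplitude = x[cand],
    snippet = snippets
  )
  structure(out, sampling_rate = fs, threshold = thr,
            alignment = n_pre + 1L, class = c("plb_spikes", class(empty)))
}

#' Sort spike events into unit clusters
#'
#' Projects the detected snippets onto their first `n_components` principal
#' components (3 by default) and clusters the projections with k-means.
#' Cluster labels are relabelled in order of first occurrence so the
#' assignment is invariant to event order up to that convention.
#'
#' @param spikes A `plb_spikes` tibble from [detect_spikes()].
#' @param n_clusters Number of units to extract (supplied, not estimated).
#' @param n_components Principal components used for clustering.
#' @param seed Integer seed making k-means deterministic.
#' @param nstart Random restarts for k-means.
#' @return The input tibble with a `unit_id` column appended.
#' @export
sort_units <- function(spikes, n_clusters, n_components = 3, seed = 1, nstart = 10) {
  if (n_clusters < 1) abort("`n_clusters` must be >= 1.")
  if (nrow(spikes) < n_clusters) abort("Fewer events than requested clusters.")
  mat <- do.call(rbind, spikes$snippet)
  if (n_clusters == 1L) {
    spikes$unit_id <- rep(1L, nrow(spikes))
    return(spikes)
  }
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  set.seed(seed)
  km <- kmeans(scores, centers = n_clusters, nstart = nstart, iter.max = 100)
  cl <- km$cluster
  spikes$unit_id <- as.integer(factor(cl, levels = unique(cl)))
  spikes
}

#' Fraction of refractory-period violations
#'
#' Proportion of spikes whose interval to the previous spike is shorter than
#' the refractory period (2 ms). A cluster qualifies as a single unit when
#' fewer than 0.3 percent of its spikes violate the refractory period.
#'
#' @param spike_times Sorted ascending spike times, seconds.
#' @param refractory Refractory period, seconds (default 0.002).
#' @return Proportion in `[0, 1]` (0 for fewer than 2 spikes).
#' @examples
#' refractory_violations(c(0, 0.001, 0.010, 0.020))
#' @export
refractory_violations <- function(spike_times, refractory = 0.002) {
  if (is.unsorted(spike_times)) abort("`spike_times` must be sorted ascending.")
  if (length(spike_times) < 2L) return(0)
  sum(diff(spike_times) < refractory) / length(spike_times)
}

#' Per-unit summaries of sorted spikes
#'
#' Collapses a sorted spike table to one row per unit: spike count, mean
#' waveform, refractory-violation fraction and the single-unit flag
#' (violations below `single_unit_max`, 0.3 percent by default).
#'
#' @param sorted A `plb_spikes` tibble with a `unit_id` column (see
#'   [sort_units()]).
#' @param refractory Refractory period, seconds.
#' @param single_unit_max Violation fraction below which a cluster counts as
#'   a single unit.
#' @return Tibble with `unit_id`, `n_spikes`, `mean_waveform` (list-column),
#'   `refractory_violation_fraction`, `is_single_unit`.
#' @export
summarize_units <- function(sorted, refractory = 0.002, single_unit_max = 0.003) {
  stopifnot("unit_id" %in% names(sorted))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sorted), .data$unit_id),
    n_spikes = dplyr::n(),
    mean_waveform = list(colMeans(do.call(rbind, .data$snippet))),
    refractory_violation_fraction = refractory_violations(sort(.data$time_s), refractory),
    .groups = "drop"
  )
  out$is_single_unit <- out$refractory_violation_fraction < single_unit_max
  out
}
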