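#' @importFrom rlang abort
#' @importFrom stats ppois
NULL

psth_attrs <- function(psth) {
  list(
    n_trials = attr(psth, "n_trials"),
    bin_width = attr(psth, "bin_width"),
    baseline_mean = attr(psth, "baseline_mean"),
    baseline_sd = attr(psth, "baseline_sd"),
    baseline_window = attr(psth, "baseline_window")
  )
}

set_psth <- function(df, n_trials, bin_width, baseline_mean = NULL,
                     baseline_sd = NULL, baseline_window = NULL) {
  structure(
    df,
    n_trials = n_trials, bin_width = bin_width,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    baseline_window = baseline_window,
    class = c("plb_psth", class(tibble::tibble()))
  )
}

#' Peri-stimulus time histogram
#'
#' Bins spike times relative to each reference event into half-open 1-ms
#' bins `[edge, edge + width)` pooled over events, and normalises to a rate
#' in spikes/s (count / (number of events x bin width)). An optional mask of
#' excluded time intervals (e.g. periods of locomotor activity) removes
#' events falling inside the mask before construction.
#'
#' @param spike_times Numeric spike times, seconds (or a `plb_spikes`
#'   tibble).
#' @param event_times Reference event times (>= 1), e.g. first-click times.
#' @param window Histogram span relative to the event, seconds; the default
#'   `c(-1.5, 0.5)` covers the -1.4 to -0.4 s baseline interval.
#' @param bin_width Bin width, seconds (default 0.001).
#' @param mask Optional two-column matrix/data frame of excluded `[start,
#'   end)` intervals in session time.
#' @return A `plb_psth` tibble with `bin_left`, `count`, `rate` and
#'   attributes `n_trials`, `bin_width`.
#' @export
build_psth <- function(spike_times, event_times, window = c(-1.5, 0.5),
                       bin_width = 0.001, mask = NULL) {
  if (inherits(spike_times, "plb_spikes") || is.data.frame(spike_times)) {
    spike_times <- spike_times$time_s
  }
  if (length(event_times) < 1L) abort("Need at least one reference event.")
  if (window[1] >= window[2]) abort("`window` must be increasing.")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    excl <- vapply(event_times, function(e) {
      any(e >= mask[, 1] & e < mask[, 2])
    }, logical(1))
    event_times <- event_times[!excl]
    if (length(event_times) == 0L) abort("All events fall inside the mask.")
  }
  edges <- seq(window[1], window[2], by = bin_width)
  n_bins <- length(edges) - 1L
  counts <- integer(n_bins)
  for (e in event_times) {
    rel <- spike_times - e
    rel <- rel[rel >= window[1] & rel < edges[n_bins + 1L]]
    if (length(rel)) {
      idx <- floor((rel - window[1]) / bin_width) + 1L
      idx <- idx[idx >= 1L & idx <= n_bins]
      counts <- counts + tabulate(idx, nbins = n_bins)
    }
  }
  n_trials <- length(event_times)
  out <- tibble::tibble(
    bin_left = edges[-(n_bins + 1L)],
    count = counts,
    rate = counts / (n_trials * bin_width)
  )
  set_psth(out, n_trials = n_trials, bin_width = bin_width)
}

#' Baseline-subtract a PSTH
#'
#' Subtracts the mean pre-stimulus firing rate, computed over the baseline
#' window (-1.4 to -0.4 s before the first click by default), from every
#' bin, and records the baseline mean and SD for later significance testing.
#' After subtraction the baseline bins average zero to machine precision.
#'
#' @param psth A `plb_psth` from [build_psth()].
#' @param baseline_window Two-element window in seconds relative to the
#'   event; must lie inside the PSTH span.
#' @return The PSTH with a `rate_bs` column and baseline attributes set.
#' @export
baseline_subtract <- function(psth, baseline_window = c(-1.4, -0.4)) {
  at <- psth_attrs(psth)
  lo <- baseline_window[1]; hi <- baseline_window[2]
  span_lo <- psth$bin_left[1]
  span_hi <- psth$bin_left[nrow(psth)] + at$bin_width
  if (lo < span_lo || hi > span_hi) abort("Baseline window not covered by the PSTH span.")
  sel <- psth$bin_left >= lo & psth$bin_left < hi
  if (!any(sel)) abort("Baseline window contains no bins.")
  bmean <- mean(psth$rate[sel])
  bsd <- stats::sd(psth$rate[sel])
  psth$rate_bs <- psth$rate - bmean
  set_psth(psth, n_trials = at$n_trials, bin_width = at$bin_width,
           baseline_mean = bmean, baseline_sd = bsd,
           baseline_window = baseline_window)
}

#' Average baseline-subtracted PSTHs across units
#'
#' Unweighted per-bin mean of the baseline-subtracted rates of several
#' units, the population response summary of the gating paradigm. All PSTHs
#' must share the same bin grid.
#'
#' @param psths List of baseline-subtracted `plb_psth` objects.
#' @return A `plb_psth` with the averaged `rate_bs` (and `rate`); `count`
#'   holds the summed counts, `n_trials` the per-unit trial count of the
#'   first PSTH.
#' @export
average_psth <- function(psths) {
  if (length(psths) < 1L) abort("Need at least one PSTH.")
  ref <- psths[[1]]
  for (p in psths) {
    if (nrow(p) != nrow(ref) || max(abs(p$bin_left - ref$bin_left)) > 1e-12) {
      abort("All PSTHs must share an identical bin grid.")
    }
    if (is.null(p$rate_bs)) abort("PSTHs must be baseline-subtracted first.")
  }
  at <- psth_attrs(ref)
  out <- tibble::tibble(
    bin_left = ref$bin_left,
    count = Reduce(`+`, lapply(psths, function(p) p$count)),
    rate = rowMeans(do.call(cbind, lapply(psths, function(p) p$rate))),
    rate_bs = rowMeans(do.call(cbind, lapply(psths, function(p) p$rate_bs)))
  )
  set_psth(out, n_trials = at$n_trials, bin_width = at$bin_width,
           baseline_mean = mean(vapply(psths, function(p) attr(p, "baseline_mean"), 1)),
           baseline_sd = NULL, baseline_window = at$baseline_window)
}

#' Evoked-response amplitude
#'
#' Mean baseline-subtracted firing rate in a 30-ms window starting 10 ms
#' after the stimulus, the standard response-amplitude measure of the gating
#' paradigm.
#'
#' @param psth A baseline-subtracted `plb_psth`.
#' @param click_time Stimulus time on the PSTH's relative axis (0 for the
#'   reference event itself, 0.5 for the second click of a pair).
#' @param window Measurement window relative to the click, seconds.
#' @return Amplitude in spikes/s.
#' @export
response_amplitude <- function(psth, click_time = 0, window = c(0.010, 0.040)) {
  if (is.null(psth$rate_bs)) abort("PSTH must be baseline-subtracted first.")
  at <- psth_attrs(psth)
  lo <- click_time + window[1]; hi <- click_time + window[2]
  span_hi <- psth$bin_left[nrow(psth)] + at$bin_width
  if (lo < psth$bin_left[1] || hi > span_hi) abort("Amplitude window not covered by the PSTH span.")
  sel <- psth$bin_left >= lo & psth$bin_left < hi
  mean(psth$rate_bs[sel])
}

#' Evoked-response onset latency
#'
#' Scans the 1-ms bins after the stimulus and returns the left edge (relative
#' to the click) of the first bin whose pooled spike count is significantly
#' above the baseline rate, using a one-sided exact Poisson test with mean
#' equal to the baseline mean count per bin. Returns `NA` when no bin in the
#' search window reaches significance. No multiplicity correction is applied:
#' the estimator is defined as the *first* significant bin.
#'
#' @param psth A baseline-subtracted `plb_psth` built from a single unit's
#'   raw counts.
#' @param click_time Stimulus time on the PSTH's relative axis.
#' @param alpha One-sided significance level (default 0.01).
#' @param search_window Span after the click to scan, seconds (default 0.1).
#' @return Latency in seconds after the click, or `NA_real_`.
#' @export
onset_latency <- function(psth, click_time = 0, alpha = 0.01, search_window = 0.1) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  at <- psth_attrs(psth)
  if (is.null(at$baseline_mean)) abort("PSTH must be baseline-subtracted first.")
  mu <- at$baseline_mean * at$bin_width * at$n_trials  # baseline count per bin
  sel <- which(psth$bin_left > click_time - 1e-12 &
                 psth$bin_left <= click_time + search_window - at$bin_width + 1e-12)
  if (!length(sel)) abort("Search window not covered by the PSTH span.")
  for (i in sel) {
    k <- psth$count[i]
    if (k > 0 && ppois(k - 1, mu, lower.tail = FALSE) <= alpha) {
      return(psth$bin_left[i] - click_time)
    }
  }
  NA_real_
}

#' Paired-click gating ratio
#'
#' Ratio of the second-click to first-click response amplitudes (S2/S1), an
#' optional summary of sensory gating strength; values below 1 indicate
#' suppression of the second response.
#'
#' @param psth A baseline-subtracted `plb_psth` referenced to the first
#'   click.
#' @param inter_stimulus_interval First-to-second click interval, seconds.
#' @param window Amplitude window passed to [response_amplitude()].
#' @return The S2/S1 amplitude ratio (`NA` when S1 is not positive).
#' @export
gating_ratio <- function(psth, inter_stimulus_interval = 0.5,
                         window = c(0.010, 0.040)) {
  s1 <- response_amplitude(psth, 0, window)
  s2 <- response_amplitude(psth, inter_stimulus_interval, window)
  if (s1 <= 0) return(NA_real_)
  s2 / s1
}

#' Evoked-response summary for a set of units
#'
#' Convenience wrapper running [build_psth()], [baseline_subtract()],
#' [response_amplitude()] and [onset_latency()] per unit.
#'
#' @param spikes Data frame with `unit_id` and `time_s` columns.
#' @param event_times Reference events (first-click times).
#' @param window,bin_width,baseline_window,alpha,search_window Passed to the
#'   underlying functions.
#' @return Tibble with one row per unit: `unit_id`, `baseline_rate`,
#'   `amplitude`, `latency_s`.
#' @export
evoked_response_table <- function(spikes, event_times,
                                  window = c(-1.5, 0.5), bin_width = 0.001,
                                  baseline_window = c(-1.4, -0.4),
                                  alpha = 0.01, search_window = 0.1) {
  stopifnot(all(c("unit_id", "time_s") %in% names(spikes)))
  purrr::map_dfr(split(spikes$time_s, spikes$unit_id), function(st) {
    p <- baseline_subtract(
      build_psth(st, event_times, window = window, bin_width = bin_width),
      baseline_window
    )
    tibble::tibble(
      baseline_rate = attr(p, "baseline_mean"),
      amplitude = response_amplitude(p),
      latency_s = onset_latency(p, alpha = alpha, search_window = search_window)
    )
  }, .id = "unit_id")
}
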