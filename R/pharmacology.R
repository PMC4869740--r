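#' @importFrom rlang abort warn
NULL

#' Spontaneous discharge rate
#'
#' Spike count divided by recording duration; the standard 5-minute
#' recording per neuron makes this a reliable spontaneous-rate estimate.
#'
#' @param spike_times Spike times in seconds (only their count is used).
#' @param duration Recording duration, seconds (default 300).
#' @return Rate in spikes/s.
#' @examples
#' spontaneous_rate(seq(0, 299, by = 1))
#' @export
spontaneous_rate <- function(spike_times, duration = 300) {
  if (duration <= 0) abort("`duration` must be positive.")
  length(spike_times) / duration
}

#' Per-cell summaries of a genotype x treatment rate table
#'
#' Collapses per-neuron discharge rates to one row per design cell: mean,
#' SEM (sd / sqrt(n)) and n, the summary-statistics form consumed by
#' [two_way_anova_summary()].
#'
#' @param records Data frame with columns `genotype`, `treatment`, `rate`.
#' @return Tibble with `genotype`, `treatment`, `mean`, `sem`, `n`.
#' @export
summarize_cells <- function(records) {
  stopifnot(all(c("genotype", "treatment", "rate") %in% names(records)))
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$genotype, .data$treatment),
    mean = base::mean(.data$rate),
    sem = stats::sd(.data$rate) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
  if (any(out$n < 2)) abort("Every genotype x treatment cell needs at least 2 neurons.")
  if (any(out$sem == 0)) warn("A cell has zero variance; its SEM is 0.")
  out
}

#' Screen units for putative pyramidal identity
#'
#' Applies the electrophysiological inclusion criteria for putative
#' pyramidal neurons: broad action potentials (trough FWHM above
#' `min_fwhm_ms`, reusing the waveform-classification features) and low
#' spontaneous discharge (below `max_rate`).
#'
#' @param units Data frame with `fwhm_ms` and `rate` columns (e.g.
#'   [classify_units()] output joined with rates).
#' @param min_fwhm_ms Minimum trough FWHM, ms (default 0.37).
#' @param max_rate Maximum spontaneous rate, spikes/s (default 10).
#' @return The subset of `units` passing both criteria.
#' @export
filter_putative_pyramidal <- function(units, min_fwhm_ms = 0.37, max_rate = 10) {
  stopifnot(all(c("fwhm_ms", "rate") %in% names(units)))
  dplyr::filter(units, .data$fwhm_ms > min_fwhm_ms, .data$rate < max_rate)
}

#' Genotype x treatment comparison of discharge rates
#'
#' Runs the unweighted-means two-way ANOVA (treatment and genotype as main
#' factors) and Newman-Keuls post hoc comparisons of the four cells. Accepts
#' either raw per-neuron records (columns `genotype`, `treatment`, `rate`)
#' or pre-computed cell summaries (columns `genotype`, `treatment`, `mean`,
#' `sem`, `n`); the two pathways agree exactly on data summarised from the
#' same records.
#'
#' @param x Raw records or cell summaries (see Details).
#' @param alpha Significance level for the post hoc stepwise decisions.
#' @return A `plb_discharge_comparison`: list with `anova` (a `plb_anova`),
#'   `posthoc` (a `plb_posthoc`) and `cells` (the summaries used).
#' @examples
#' compare_discharge_rates(gabazine_reference_summaries())
#' @export
compare_discharge_rates <- function(x, alpha = 0.05) {
  has_summary <- all(c("mean", "sem", "n") %in% names(x))
  has_raw <- "rate" %in% names(x)
  if (!has_summary && !has_raw) {
    abort("`x` must hold either raw `rate` records or `mean`/`sem`/`n` summaries.")
  }
  cells <- if (has_summary) tibble::as_tibble(x) else summarize_cells(x)
  if (nrow(cells) != length(unique(cells$genotype)) * length(unique(cells$treatment))) {
    abort("Design is incomplete: at least one genotype x treatment cell is missing.")
  }
  av <- two_way_anova_summary(cells, genotype, treatment, mean, sem, n)
  groups <- tibble::tibble(
    group = paste(cells$genotype, cells$treatment, sep = "."),
    mean = cells$mean,
    n = cells$n
  )
  ph <- newman_keuls(groups, ms_within = av$ms_within,
                     df_within = av$df_den, alpha = alpha)
  structure(
    list(anova = av, posthoc = ph, cells = cells),
    class = "plb_discharge_comparison"
  )
}

#' @export
print.plb_discharge_comparison <- function(x, ...) {
  print(x$anova)
  cat("\nNewman-Keuls post hoc:\n")
  print(as.data.frame(x$posthoc), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method tidy plb_discharge_comparison
#' @export
tidy.plb_discharge_comparison <- function(x, ...) x$anova$effects

#' @method glance plb_discharge_comparison
#' @export
glance.plb_discharge_comparison <- function(x, ...) glance(x$anova)
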