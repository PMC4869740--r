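#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_step geom_point
#'   geom_vline geom_hline geom_errorbar geom_line labs theme_minimal
#'   position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a peri-stimulus time histogram
#'
#' Step plot of the (baseline-subtracted, when available) firing rate per
#' 1-ms bin, with the stimulus marked at time zero.
#'
#' @param object A `plb_psth`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plb_psth
#' @export
autoplot.plb_psth <- function(object, ...) {
  y <- if (!is.null(object$rate_bs)) object$rate_bs else object$rate
  df <- data.frame(t = object$bin_left, rate = y)
  ggplot(df, aes(x = .data$t, y = .data$rate)) +
    geom_step() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(
      x = "Time from stimulus (s)",
      y = if (!is.null(object$rate_bs)) "Rate, baseline-subtracted (spikes/s)" else "Rate (spikes/s)"
    ) +
    theme_minimal()
}

#' Waveform-feature scatter with classification regions
#'
#' Plots trough FWHM against valley-to-peak time for a table of units, with
#' the classification thresholds drawn (FWHM 0.35/0.37 ms, valley-to-peak
#' 0.15/0.2 ms) and points coloured by assigned class.
#'
#' @param units Data frame with `fwhm_ms`, `v2p_ms` and `cell_class` columns
#'   (see [classify_units()]).
#' @return A ggplot object.
#' @export
plot_waveform_classes <- function(units) {
  ggplot(units, aes(x = .data$fwhm_ms, y = .data$v2p_ms,
                    colour = .data$cell_class)) +
    geom_point() +
    geom_vline(xintercept = c(0.35, 0.37), linetype = "dotted") +
    geom_hline(yintercept = c(0.15, 0.20), linetype = "dotted") +
    labs(x = "Trough FWHM (ms)", y = "Valley-to-peak (ms)", colour = "Class") +
    theme_minimal()
}

#' Plot a genotype x treatment discharge-rate comparison
#'
#' Cell means with SEM error bars, grouped by genotype and coloured by
#' treatment.
#'
#' @param object A `plb_discharge_comparison` from
#'   [compare_discharge_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plb_discharge_comparison
#' @export
autoplot.plb_discharge_comparison <- function(object, ...) {
  cells <- object$cells
  ggplot(cells, aes(x = .data$genotype, y = .data$mean, fill = .data$treatment)) +
    geom_col(position = position_dodge(0.8), width = 0.7) +
    geom_errorbar(
      aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = position_dodge(0.8), width = 0.2
    ) +
    labs(x = "Genotype", y = "Discharge rate (spikes/s)", fill = "Treatment") +
    theme_minimal()
}

#' Accuracy against stimulus duration by genotype
#'
#' Group mean percent accuracy (with SEM) at each stimulus duration, the
#' standard display of an attentional challenge.
#'
#' @param cohort Tibble from [simulate_5csrtt_cohort()] (or any table with
#'   `genotype`, `stimulus_duration`, `pct_accuracy`).
#' @return A ggplot object.
#' @export
plot_accuracy_curves <- function(cohort) {
  summ <- dplyr::summarise(
    dplyr::group_by(cohort, .data$genotype, .data$stimulus_duration),
    mean = base::mean(.data$pct_accuracy),
    sem = stats::sd(.data$pct_accuracy) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot(summ, aes(x = .data$stimulus_duration, y = .data$mean,
                   colour = .data$genotype, group = .data$genotype)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
                  width = 0.03) +
    labs(x = "Stimulus duration (s)", y = "Accuracy (%)", colour = "Genotype") +
    theme_minimal()
}
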