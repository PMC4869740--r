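#' @importFrom rlang abort
NULL

# Linear-interpolated crossing of `level` between samples i and i+1.
cross_at <- function(x, i, level) {
  i + (level - x[i]) / (x[i + 1] - x[i])
}

#' Waveform trough features of an average spike waveform
#'
#' Measures the two features used for putative cell typing: the full width of
#' the spike trough (valley) at half its depth, and the time from the trough
#' minimum to the subsequent peak maximum. The half-depth reference level is
#' the pre-trough baseline, estimated as the mean of the first
#' `baseline_ms` of the snippet (minima-aligned snippets begin near
#' baseline). Crossings are located by linear interpolation between samples.
#'
#' @param waveform Numeric vector, one average waveform (trough-aligned).
#' @param sampling_rate Samples per second.
#' @param baseline_ms Initial span used as the baseline reference (default
#'   0.2 ms).
#' @return A one-row tibble with `fwhm_ms` and `v2p_ms` (both in
#'   milliseconds).
#' @examples
#' tpl <- simulate_waveform_template("pyramidal", fwhm_ms = 0.5, v2p_ms = 0.3)
#' waveform_features(tpl$template, tpl$sampling_rate)
#' @export
waveform_features <- function(waveform, sampling_rate, baseline_ms = 0.2) {
  x <- as.numeric(waveform)
  n <- length(x)
  if (n < 5L) abort("Waveform too short to measure features.")
  nb <- max(1L, floor(baseline_ms * 1e-3 * sampling_rate))
  baseline <- mean(x[seq_len(min(nb, n))])
  vi <- which.min(x)
  depth <- baseline - x[vi]
  if (depth <= 0 || sum(x == x[vi]) > 1L) {
    abort("Waveform features undefined: no strict trough below baseline.")
  }
  if (vi < 2L || vi > n - 2L) {
    abort("Waveform features undefined: trough lies at the snippet edge.")
  }
  half <- baseline - depth / 2

  # last crossing of the half level before the trough, first after it
  left <- NA_real_
  for (i in seq(vi - 1L, 1L)) {
    if (x[i] >= half && x[i + 1L] < half) { left <- cross_at(x, i, half); break }
  }
  right <- NA_real_
  if (vi < n) {
    for (i in seq(vi, n - 1L)) {
      if (x[i] < half && x[i + 1L] >= half) { right <- cross_at(x, i, half); break }
    }
  }
  if (is.na(left) || is.na(right)) {
    abort("Waveform features undefined: trough does not recross its half depth.")
  }
  if (vi >= n - 1L) abort("Waveform features undefined: no samples after the trough.")
  post <- x[(vi + 1L):n]
  pi <- vi + which.max(post)
  if (x[pi] <= x[vi]) abort("Waveform features undefined: no peak after the trough.")

  tibble::tibble(
    fwhm_ms = (right - left) / sampling_rate * 1e3,
    v2p_ms = (pi - vi) / sampling_rate * 1e3
  )
}

#' Classify a unit from its waveform features
#'
#' Applies the published trough-width rules: units with trough FWHM below
#' 0.35 ms and valley-to-peak time below 0.2 ms are putative fast-spiking
#' interneurons; units with FWHM above 0.37 ms and valley-to-peak above
#' 0.15 ms are putative pyramidal cells; everything else is intermediate and
#' conventionally excluded from further analysis. The two FWHM intervals are
#' disjoint, so where the valley-to-peak clauses overlap (0.15-0.2 ms) the
#' FWHM clause decides membership unambiguously.
#'
#' @param fwhm_ms,v2p_ms Numeric vectors of trough FWHM and valley-to-peak
#'   time in milliseconds.
#' @return Character vector: `"interneuron"`, `"pyramidal"` or
#'   `"intermediate"`.
#' @examples
#' classify_waveform(c(0.30, 0.50, 0.36), c(0.15, 0.30, 0.18))
#' @export
classify_waveform <- function(fwhm_ms, v2p_ms) {
  if (any(fwhm_ms <= 0 | v2p_ms <= 0, na.rm = TRUE)) {
    abort("Features must be positive.")
  }
  dplyr::case_when(
    fwhm_ms < 0.35 & v2p_ms < 0.2 ~ "interneuron",
    fwhm_ms > 0.37 & v2p_ms > 0.15 ~ "pyramidal",
    TRUE ~ "intermediate"
  )
}

#' Feature extraction and classification for a table of units
#'
#' Data-frame wrapper over [waveform_features()] and [classify_waveform()]:
#' takes a unit table with a list-column of mean waveforms and appends
#' `fwhm_ms`, `v2p_ms` and `cell_class`. Units whose features are undefined
#' get `NA` features and an `"intermediate"` label.
#'
#' @param units Data frame with a `mean_waveform` list-column.
#' @param sampling_rate Samples per second.
#' @return The input tibble with feature and class columns appended.
#' @export
classify_units <- function(units, sampling_rate) {
  stopifnot("mean_waveform" %in% names(units))
  feats <- purrr::map(units$mean_waveform, function(w) {
    tryCatch(waveform_features(w, sampling_rate),
             error = function(e) tibble::tibble(fwhm_ms = NA_real_, v2p_ms = NA_real_))
  })
  feats <- dplyr::bind_rows(feats)
  units$fwhm_ms <- feats$fwhm_ms
  units$v2p_ms <- feats$v2p_ms
  units$cell_class <- ifelse(
    is.na(feats$fwhm_ms), "intermediate",
    classify_waveform(pmax(feats$fwhm_ms, 1e-9), pmax(feats$v2p_ms, 1e-9))
  )
  tibble::as_tibble(units)
}
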