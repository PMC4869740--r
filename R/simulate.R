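#' @importFrom rlang abort warn
#' @importFrom stats rnorm rpois runif rgamma rbinom rlnorm mad plogis qlogis
NULL

#' Synthesize a spike waveform template with prescribed trough features
#'
#' Builds an extracellular-like waveform (negative trough followed by a
#' positive after-peak) whose measured trough FWHM and valley-to-peak time
#' match the requested targets to within one sample period, so generated
#' units carry exact ground truth for classifier testing. The shape is
#' piecewise -- raised-cosine descent, power-law rise placing the after-peak
#' exactly at the valley-to-peak target, Gaussian return to baseline -- with
#' the flank width and rise exponent solved from the feature targets in
#' closed form; the realised features are verified with
#' [waveform_features()] before returning. The trough is normalised to
#' depth 1.
#'
#' @param cell_class `"interneuron"`, `"pyramidal"` or `"intermediate"`;
#'   chooses default feature targets typical of the class.
#' @param sampling_rate Samples per second (default 40000).
#' @param fwhm_ms,v2p_ms Target trough FWHM and valley-to-peak time in
#'   milliseconds; defaults depend on `cell_class`.
#' @param window_ms Snippet extent before/after the trough, milliseconds.
#' @return A list with `template` (numeric, trough = -1 at the alignment
#'   sample), `sampling_rate`, `cell_class`, and the realised `fwhm_ms`,
#'   `v2p_ms`.
#' @examples
#' tpl <- simulate_waveform_template("interneuron")
#' waveform_features(tpl$template, tpl$sampling_rate)
#' @export
simulate_waveform_template <- function(cell_class = c("interneuron", "pyramidal", "intermediate"),
                                       sampling_rate = 40000,
                                       fwhm_ms = NULL, v2p_ms = NULL,
                                       window_ms = c(0.8, 1.6)) {
  cell_class <- match.arg(cell_class)
  defaults <- list(
    interneuron = c(0.25, 0.15),
    pyramidal = c(0.50, 0.30),
    intermediate = c(0.36, 0.18)
  )[[cell_class]]
  if (is.null(fwhm_ms)) fwhm_ms <- defaults[1]
  if (is.null(v2p_ms)) v2p_ms <- defaults[2]
  sample_ms <- 1e3 / sampling_rate
  if (fwhm_ms <= 2 * sample_ms || v2p_ms <= 2 * sample_ms) {
    abort("Feature targets are below the resolution of the sampling rate.")
  }
  n_pre <- round(window_ms[1] * 1e-3 * sampling_rate)
  n_post <- round(window_ms[2] * 1e-3 * sampling_rate)
  t <- (seq(-n_pre, n_post)) * sample_ms  # ms relative to the trough

  # Piecewise shape with analytically placed features:
  #   t in [-L, 0]   raised-cosine descent; left half-crossing exactly -L/2,
  #                  zero (flat baseline) before -L
  #   t in [0, v2p]  power-law rise from -1 to the after-peak at exactly v2p,
  #                  exponent solved so the right half-crossing sits at t_r
  #   t > v2p        Gaussian decay of the after-peak back to baseline
  # FWHM = L/2 + t_r; L is capped so the first 0.2 ms of the snippet stay at
  # baseline, and t_r must fall inside the rise segment.
  h <- 0.4  # after-peak height relative to trough depth
  L_max <- window_ms[1] - 0.2
  t_r_min <- max(0.05 * v2p_ms, 0.5 * sample_ms)
  L <- min(L_max, 2 * (fwhm_ms - t_r_min))
  t_r <- fwhm_ms - L / 2
  if (L <= 2 * sample_ms || t_r > 0.95 * v2p_ms) {
    abort("Feature targets unresolvable at this sampling rate.")
  }
  gamma <- log(0.5 / (1 + h)) / log(t_r / v2p_ms)
  tau <- max(0.5 * v2p_ms, 0.15)
  tpl <- numeric(length(t))
  pre <- t >= -L & t < 0
  tpl[pre] <- -(1 - cos(pi * (t[pre] + L) / L)) / 2
  mid <- t >= 0 & t <= v2p_ms
  tpl[mid] <- -1 + (1 + h) * (t[mid] / v2p_ms)^gamma
  post <- t > v2p_ms
  tpl[post] <- h * exp(-((t[post] - v2p_ms) / tau)^2)

  ft <- waveform_features(tpl, sampling_rate)
  if (abs(ft$fwhm_ms - fwhm_ms) > sample_ms || abs(ft$v2p_ms - v2p_ms) > sample_ms) {
    abort("Feature targets unresolvable at this sampling rate.")
  }
  list(
    template = tpl, sampling_rate = sampling_rate, cell_class = cell_class,
    fwhm_ms = ft$fwhm_ms, v2p_ms = ft$v2p_ms, alignment = n_pre + 1L
  )
}

#' Paired-click stimulus schedule
#'
#' Generates the paired white-noise click schedule used in the auditory
#' gating paradigm: pairs of 10-ms clicks separated by a 500-ms
#' inter-stimulus interval, with a 10-s interval between pairs, across a
#' recording of `duration` seconds.
#'
#' @param duration Recording length in seconds (default 600, a 10-min
#'   session).
#' @param inter_pair_interval Gap between pairs, seconds.
#' @param inter_stimulus_interval First-to-second click interval, seconds.
#' @param stimulus_duration Click length, seconds.
#' @param first_click_start Time of the first click, seconds; leaves room for
#'   the pre-stimulus baseline window.
#' @return A tibble with `pair`, `first_click`, `second_click` and the
#'   schedule parameters as attributes.
#' @export
click_schedule <- function(duration = 600,
                           inter_pair_interval = 10,
                           inter_stimulus_interval = 0.5,
                           stimulus_duration = 0.01,
                           first_click_start = 2) {
  if (duration <= 0) abort("`duration` must be positive.")
  period <- inter_pair_interval + inter_stimulus_interval
  if (period <= inter_stimulus_interval) abort("Pairs would overlap.")
  first <- seq(first_click_start,
               duration - inter_stimulus_interval - stimulus_duration,
               by = period)
  out <- tibble::tibble(
    pair = seq_along(first),
    first_click = first,
    second_click = first + inter_stimulus_interval
  )
  attr(out, "inter_pair_interval") <- inter_pair_interval
  attr(out, "inter_stimulus_interval") <- inter_stimulus_interval
  attr(out, "stimulus_duration") <- stimulus_duration
  out
}

#' Simulate a spike train with click-evoked transients
#'
#' Baseline activity is a homogeneous Poisson process; each click adds an
#' additive transient rate kernel (rectangular by default, height
#' `evoked_amplitude` spikes/s, width `kernel_width`, starting
#' `evoked_latency` after the click). Negative amplitudes (suppression) are
#' realised by thinning the baseline inside the kernel window and must not
#' drive the instantaneous rate negative.
#'
#' @param baseline_rate Baseline rate, spikes/s.
#' @param duration Train length, seconds.
#' @param click_times Stimulus times, seconds (may be empty).
#' @param evoked_amplitude Added rate during the kernel, spikes/s.
#' @param evoked_latency Kernel onset after each click, seconds.
#' @param kernel_width Kernel duration, seconds (default 0.030, the span of
#'   the response-amplitude window).
#' @param seed Optional integer seed for reproducibility.
#' @return Sorted numeric vector of spike times in `[0, duration]`.
#' @export
simulate_spike_train <- function(baseline_rate, duration,
                                 click_times = numeric(0),
                                 evoked_amplitude = 0,
                                 evoked_latency = 0.015,
                                 kernel_width = 0.030,
                                 seed = NULL) {
  if (baseline_rate < 0 || duration <= 0) abort("Rate must be >= 0 and duration > 0.")
  if (baseline_rate + evoked_amplitude < 0) {
    abort("Negative instantaneous rate: |evoked_amplitude| exceeds baseline_rate.")
  }
  if (!is.null(seed)) set.seed(seed)
  n0 <- rpois(1, baseline_rate * duration)
  spikes <- runif(n0, 0, duration)
  if (length(click_times) && evoked_amplitude != 0) {
    starts <- click_times + evoked_latency
    if (evoked_amplitude > 0) {
      extra <- lapply(starts, function(s) {
        ne <- rpois(1, evoked_amplitude * kernel_width)
        runif(ne, s, s + kernel_width)
      })
      spikes <- c(spikes, unlist(extra))
    } else {
      keep_p <- (baseline_rate + evoked_amplitude) / baseline_rate
      in_win <- rep(FALSE, length(spikes))
      for (s in starts) in_win <- in_win | (spikes >= s & spikes < s + kernel_width)
      drop <- in_win & runif(length(spikes)) > keep_p
      spikes <- spikes[!drop]
    }
  }
  sort(spikes[spikes >= 0 & spikes <= duration])
}

#' Simulate a paired-click extracellular recording with ground truth
#'
#' Builds a continuous voltage trace as white Gaussian noise plus waveform
#' templates inserted at the spike times of each simulated unit (overlapping
#' spikes superpose linearly). Each unit fires as a Poisson process with a
#' click-evoked transient (see [simulate_spike_train()]); the clicks follow
#' the paired-click schedule. Ground-truth spike times, templates and unit
#' parameters are retained so detection, sorting and classification can be
#' scored exactly.
#'
#' @param units Data frame with one row per unit and columns `cell_class`,
#'   `baseline_rate` (spikes/s), `evoked_amplitude` (spikes/s),
#'   `evoked_latency` (s), `amplitude` (trough depth in trace units) and
#'   optionally `fwhm_ms`, `v2p_ms` feature targets.
#' @param duration Recording length, seconds (default 600).
#' @param sampling_rate Samples per second; must exceed twice the 9 kHz
#'   band-pass edge (default 40000).
#' @param noise_sd Noise standard deviation, trace units.
#' @param schedule Optional click schedule from [click_schedule()]; built
#'   with defaults when `NULL`. Use `schedule = FALSE` for no stimuli.
#' @param seed Optional integer seed.
#' @return A `plb_recording`: list with `trace`, `sampling_rate`, `duration`,
#'   `schedule`, `units` (tibble with `template` list-column) and `spikes`
#'   (tibble `unit_id`, `time_s` of ground-truth spike times).
#' @export
simulate_recording <- function(units, duration = 600, sampling_rate = 40000,
                               noise_sd = 1, schedule = NULL, seed = NULL) {
  if (!is.data.frame(units) || nrow(units) == 0L) abort("`units` must be a non-empty data frame.")
  if (sampling_rate <= 2 * 9000) abort("`sampling_rate` must exceed twice the 9 kHz band edge.")
  if (duration <= 0) abort("`duration` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  no_clicks <- isFALSE(schedule)
  if (is.null(schedule)) schedule <- click_schedule(duration)
  clicks <- if (no_clicks) numeric(0) else sort(c(schedule$first_click, schedule$second_click))

  n <- round(duration * sampling_rate)
  trace <- rnorm(n, 0, noise_sd)
  units <- tibble::as_tibble(units)
  if (!"unit_id" %in% names(units)) units$unit_id <- seq_len(nrow(units))
  if (!"amplitude" %in% names(units)) units$amplitude <- 8 * max(noise_sd, 1e-12)

  templates <- vector("list", nrow(units))
  spike_list <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    tpl <- simulate_waveform_template(
      u$cell_class, sampling_rate,
      fwhm_ms = if ("fwhm_ms" %in% names(units)) u$fwhm_ms else NULL,
      v2p_ms = if ("v2p_ms" %in% names(units)) u$v2p_ms else NULL
    )
    templates[[i]] <- tpl$template * u$amplitude
    st <- simulate_spike_train(
      u$baseline_rate, duration, clicks,
      evoked_amplitude = u$evoked_amplitude,
      evoked_latency = u$evoked_latency
    )
    spike_list[[i]] <- st
    align <- tpl$alignment
    len <- length(tpl$template)
    for (tt in st) {
      i0 <- round(tt * sampling_rate) + 1L - (align - 1L)
      i1 <- i0 + len - 1L
      src <- seq_len(len)
      if (i0 < 1L) { src <- src[-(seq_len(1L - i0))]; i0 <- 1L }
      if (i1 > n) { src <- src[seq_len(length(src) - (i1 - n))]; i1 <- n }
      if (length(src)) trace[i0:i1] <- trace[i0:i1] + templates[[i]][src]
    }
  }
  units$template <- templates
  spikes <- tibble::tibble(
    unit_id = rep(units$unit_id, lengths(spike_list)),
    time_s = unlist(spike_list)
  )
  structure(
    list(
      trace = trace, sampling_rate = sampling_rate, duration = duration,
      noise_sd = noise_sd, schedule = if (no_clicks) NULL else schedule,
      units = units, spikes = spikes
    ),
    class = "plb_recording"
  )
}

#' @export
print.plb_recording <- function(x, ...) {
  cat(sprintf(
    "<plb_recording> %.1f s at %d Hz, %d units, %d ground-truth spikes, %s click pairs\n",
    x$duration, x$sampling_rate, nrow(x$units), nrow(x$spikes),
    if (is.null(x$schedule)) "no" else nrow(x$schedule)
  ))
  invisible(x)
}

#' Reference cell summaries for the gabazine discharge-rate comparison
#'
#' The published per-cell group statistics (mean, SEM, n of spontaneous
#' pyramidal discharge rates in spikes/s) for the 2 x 2 genotype x treatment
#' design: wild-type and microdeletion mice recorded under saline or local
#' gabazine. These four summaries are the inputs of the summary-statistics
#' two-way ANOVA worked example and of the matched population generator.
#'
#' @return Tibble with columns `genotype` (`WT`/`DF`), `treatment`
#'   (`saline`/`gabazine`), `mean`, `sem`, `n`.
#' @export
gabazine_reference_summaries <- function() {
  tibble::tibble(
    genotype = c("WT", "WT", "DF", "DF"),
    treatment = c("saline", "gabazine", "saline", "gabazine"),
    mean = c(0.97, 3.58, 0.57, 1.12),
    sem = c(0.26, 0.59, 0.16, 0.10),
    n = c(29L, 38L, 24L, 28L)
  )
}

#' Simulate a discharge-rate population matching target cell summaries
#'
#' Draws per-neuron spontaneous firing rates for each genotype x treatment
#' cell from a gamma law with the target cell mean and standard deviation
#' (SD = SEM * sqrt(n) when `sd` is absent). The gamma law keeps rates
#' non-negative and reproduces the heavy right skew of cortical discharge
#' rates; `dispersion` scales the target SDs (0 gives every neuron the cell
#' mean exactly).
#'
#' @param cells Data frame with columns `genotype`, `treatment`, `mean`, `n`
#'   and either `sd` or `sem` (see [gabazine_reference_summaries()]).
#' @param n_per_cell Optional override of each cell's `n`.
#' @param dispersion Multiplier on the target SDs (default 1).
#' @param seed Optional integer seed.
#' @return Tibble with `neuron_id`, `genotype`, `treatment`, `rate`.
#' @export
simulate_discharge_population <- function(cells, n_per_cell = NULL,
                                          dispersion = 1, seed = NULL) {
  stopifnot(all(c("genotype", "treatment", "mean", "n") %in% names(cells)))
  if (any(cells$mean < 0)) abort("Target means must be non-negative.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  sds <- if ("sd" %in% names(cells)) cells$sd else cells$sem * sqrt(cells$n)
  sds <- sds * dispersion
  ns <- if (is.null(n_per_cell)) cells$n else rep(n_per_cell, nrow(cells))
  if (any(ns < 2)) abort("Every cell needs n >= 2.")
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::pmap(
    list(cells$genotype, cells$treatment, cells$mean, sds, ns),
    function(g, tr, m, s, n) {
      rate <- if (s == 0 || m == 0) {
        rep(m, n)
      } else {
        rgamma(n, shape = (m / s)^2, rate = m / s^2)
      }
      tibble::tibble(genotype = g, treatment = tr, rate = rate)
    }
  )
  out <- dplyr::bind_rows(rows)
  out$neuron_id <- seq_len(nrow(out))
  dplyr::relocate(out, "neuron_id")
}

#' Stimulus-duration accuracy curves for the 5-CSRTT
#'
#' Saturating accuracy-versus-stimulus-duration curves used as simulation
#' defaults: both genotypes perform alike at long durations, while the
#' microdeletion genotype loses `gap` accuracy (as a proportion) at
#' durations of `gap_below` seconds or shorter -- the selective attentional
#' deficit the task is designed to expose.
#'
#' @param genotype `"WT"` or `"DF"`.
#' @param gap Accuracy deficit of the `DF` genotype at short durations
#'   (proportion, default 0.08).
#' @param gap_below Stimulus duration (s) at or below which the gap applies.
#' @return A function mapping stimulus duration (s) to P(correct | responded).
#' @export
csrtt_accuracy_curve <- function(genotype = c("WT", "DF"), gap = 0.08, gap_below = 0.8) {
  genotype <- match.arg(genotype)
  function(sd_s) {
    p <- 0.92 - 0.14 * exp(-sd_s / 0.35)
    if (genotype == "DF") p <- p - gap * (sd_s <= gap_below)
    pmin(pmax(p, 0), 1)
  }
}

#' Simulate one 5-CSRTT session log
#'
#' Generates a trial-by-trial session log. Each trial is flagged premature
#' with probability `premature_rate`; the scored outcome is an omission with
#' probability `omission_rate`, otherwise correct with probability given by
#' the genotype's accuracy curve at the session's stimulus duration.
#' Response and reward-retrieval latencies are log-normal (positive by
#' construction).
#'
#' @param genotype `"WT"` or `"DF"`.
#' @param stimulus_duration Stimulus duration, seconds.
#' @param n_trials Trials in the session (40 in training, up to 140 in
#'   extended testing).
#' @param accuracy_curve Optional function(stimulus duration) -> P(correct);
#'   defaults to [csrtt_accuracy_curve()] for the genotype.
#' @param omission_rate,premature_rate Trial probabilities in `[0, 1]`.
#' @param delay Pre-stimulus delay, seconds.
#' @param seed Optional integer seed.
#' @return A tibble in the session-log schema: `trial_index`, `outcome`,
#'   `premature`, `perseverative_correct_responses`, `correction_trial`,
#'   `response_latency_s`, `reward_latency_s`, `stimulus_duration_s`,
#'   `delay_s`.
#' @export
simulate_5csrtt_session <- function(genotype = c("WT", "DF"),
                                    stimulus_duration = 2,
                                    n_trials = 40,
                                    accuracy_curve = NULL,
                                    omission_rate = 0.15,
                                    premature_rate = 0.05,
                                    delay = 5,
                                    seed = NULL) {
  genotype <- match.arg(genotype)
  probs <- c(omission_rate, premature_rate)
  if (any(probs < 0 | probs > 1)) abort("Rates must be probabilities in [0, 1].")
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  if (is.null(accuracy_curve)) accuracy_curve <- csrtt_accuracy_curve(genotype)
  p_correct <- accuracy_curve(stimulus_duration)
  if (p_correct < 0 || p_correct > 1) abort("`accuracy_curve` must return a probability.")
  if (!is.null(seed)) set.seed(seed)

  premature <- runif(n_trials) < premature_rate
  omitted <- runif(n_trials) < omission_rate
  correct <- runif(n_trials) < p_correct
  outcome <- ifelse(omitted, "omission", ifelse(correct, "correct", "incorrect"))
  responded <- outcome != "omission"
  tibble::tibble(
    trial_index = seq_len(n_trials),
    outcome = outcome,
    premature = premature,
    perseverative_correct_responses = ifelse(outcome == "correct", rpois(n_trials, 0.1), 0L),
    correction_trial = FALSE,
    response_latency_s = ifelse(responded, rlnorm(n_trials, log(1.0), 0.3), NA_real_),
    reward_latency_s = ifelse(outcome == "correct", rlnorm(n_trials, log(1.5), 0.3), NA_real_),
    stimulus_duration_s = stimulus_duration,
    delay_s = delay
  )
}

#' Simulate a two-genotype 5-CSRTT cohort across stimulus durations
#'
#' Per-animal percent accuracy at each probed stimulus duration, for a
#' genotype x stimulus-duration mixed design. Animals carry a log-odds random
#' intercept (`subject_sd` on the logit scale) and per-duration accuracy is
#' the binomial proportion over that animal's scored trials, so the table
#' feeds [mixed_anova()] directly. Defaults mirror extended 5-CSRTT testing:
#' 16 animals per genotype, durations 2-0.6 s, 140-trial sessions probed for
#' two days (280 trials per duration before omissions), and an 8-point
#' accuracy gap for the mutant genotype at durations of 0.8 s or less.
#'
#' @param n_per_group Animals per genotype.
#' @param stimulus_durations Probed durations, seconds.
#' @param trials_per_duration Trials presented per duration per animal.
#' @param accuracy_gap Mutant accuracy deficit (proportion) at short
#'   durations; 0 gives a null cohort.
#' @param gap_below Duration threshold (s) for the deficit.
#' @param subject_sd SD of the per-animal logit intercept.
#' @param omission_rate Probability a trial is omitted (unscored).
#' @param seed Optional integer seed.
#' @return Tibble with `animal_id`, `genotype`, `stimulus_duration`,
#'   `pct_accuracy`.
#' @export
simulate_5csrtt_cohort <- function(n_per_group = 16,
                                   stimulus_durations = c(2, 1, 0.8, 0.6),
                                   trials_per_duration = 280,
                                   accuracy_gap = 0.08,
                                   gap_below = 0.8,
                                   subject_sd = 0.25,
                                   omission_rate = 0.15,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  animals <- tibble::tibble(
    animal_id = sprintf("m%02d", seq_len(2 * n_per_group)),
    genotype = rep(c("WT", "DF"), each = n_per_group),
    offset = rnorm(2 * n_per_group, 0, subject_sd)
  )
  grid <- tidyr::expand_grid(animals, stimulus_duration = stimulus_durations)
  curves <- list(
    WT = csrtt_accuracy_curve("WT", gap = accuracy_gap, gap_below = gap_below),
    DF = csrtt_accuracy_curve("DF", gap = accuracy_gap, gap_below = gap_below)
  )
  p <- purrr::map2_dbl(grid$genotype, grid$stimulus_duration,
                       function(g, s) curves[[g]](s))
  p <- plogis(qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)) + grid$offset)
  n_scored <- pmax(1L, rbinom(nrow(grid), trials_per_duration, 1 - omission_rate))
  grid$pct_accuracy <- 100 * rbinom(nrow(grid), n_scored, p) / n_scored
  grid[c("animal_id", "genotype", "stimulus_duration", "pct_accuracy")]
}
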