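# Independent oracles and small builders shared across tests.

# Half-crossing feature measurement independent of the package's
# implementation: baseline from the first 0.2 ms, crossings located with
# stats::approx on each flank, peak by direct argmax.
oracle_features <- function(w, fs) {
  nb <- floor(0.2e-3 * fs)
  baseline <- mean(w[seq_len(nb)])
  vi <- which.min(w)
  depth <- baseline - w[vi]
  half <- baseline - depth / 2
  left_idx <- seq_len(vi)
  right_idx <- vi:length(w)
  left <- stats::approx(w[left_idx], left_idx, xout = half, ties = "ordered")$y
  rs <- w[right_idx]
  ri <- which(rs[-1] >= half & rs[-length(rs)] < half)[1]
  right <- right_idx[ri] + (half - rs[ri]) / (rs[ri + 1] - rs[ri])
  # left flank: use the last upward crossing before the trough
  li <- which(w[-1] < half & w[-length(w)] >= half)
  li <- li[li < vi]
  li <- li[length(li)]
  left <- li + (half - w[li]) / (w[li + 1] - w[li])
  pk <- vi + which.max(w[(vi + 1):length(w)])
  list(
    fwhm_ms = (right - left) / fs * 1e3,
    v2p_ms = (pk - vi) / fs * 1e3
  )
}

# Majority-vote map from sorted clusters to ground-truth units.
match_clusters <- function(sorted, truth_spikes, tol = 3e-4) {
  truth <- vapply(sorted$time_s, function(t) {
    i <- which.min(abs(truth_spikes$time_s - t))
    if (abs(truth_spikes$time_s[i] - t) < tol) truth_spikes$unit_id[i] else 0L
  }, integer(1))
  vapply(split(truth, sorted$unit_id), function(v) {
    as.integer(names(which.max(table(v))))
  }, integer(1))
}

# Two-unit study recording used by the end-to-end pipeline tests.
pipeline_units <- function() {
  tibble::tibble(
    cell_class = c("interneuron", "pyramidal"),
    baseline_rate = c(10, 3),
    evoked_amplitude = c(100, 50),
    evoked_latency = c(0.012, 0.018),
    amplitude = c(10, 6),
    fwhm_ms = c(0.25, 0.50),
    v2p_ms = c(0.11, 0.40)
  )
}

# Minimal session log builder for behavioural metric tests.
make_log <- function(outcomes, premature = FALSE, correction = FALSE,
                     persev = 0L) {
  n <- length(outcomes)
  tibble::tibble(
    trial_index = seq_len(n),
    outcome = outcomes,
    premature = rep_len(premature, n),
    perseverative_correct_responses = rep_len(persev, n),
    correction_trial = rep_len(correction, n),
    response_latency_s = ifelse(outcomes == "omission", NA_real_, 1.0),
    reward_latency_s = ifelse(outcomes == "correct", 1.5, NA_real_),
    stimulus_duration_s = 2,
    delay_s = 5
  )
}
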