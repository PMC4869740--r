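#' @importFrom rlang abort warn
NULL

pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

scored_trials <- function(log) {
  if ("correction_trial" %in% names(log)) {
    log[!as.logical(log$correction_trial), , drop = FALSE]
  } else {
    log
  }
}

#' Session-level dependent variables for a 5-CSRTT session
#'
#' Computes the standard dependent variables of the 5-choice serial reaction
#' time task from a trial log: percent accuracy (correct / (correct +
#' incorrect)), percent omission (omitted / total), percent premature
#' (premature trials / total), percent perseverative correct (perseverative
#' responses at the correct location / correct responses) and mean response
#' and reward-retrieval latencies. Correction trials, when flagged, are
#' excluded from all denominators and reported separately. Percentages are on
#' a 0-100 scale; undefined metrics (e.g. accuracy with no scored responses)
#' propagate as `NA`, never as 0.
#'
#' @param log Data frame of trials with at least an `outcome` column taking
#'   values `"correct"`, `"incorrect"` or `"omission"`. Optional columns:
#'   `premature` (logical), `perseverative_correct_responses` (counts),
#'   `correction_trial` (logical), `response_latency_s`, `reward_latency_s`.
#' @return A one-row tibble of session metrics.
#' @examples
#' log <- simulate_5csrtt_session("WT", stimulus_duration = 0.8, n_trials = 40, seed = 1)
#' session_metrics(log)
#' @export
session_metrics <- function(log) {
  if (!is.data.frame(log) || nrow(log) == 0L) abort("`log` must have at least one trial.")
  if (!"outcome" %in% names(log)) abort("`log` needs an `outcome` column.")
  bad <- setdiff(unique(log$outcome), c("correct", "incorrect", "omission"))
  if (length(bad)) abort(paste0("Unknown outcome value(s): ", paste(bad, collapse = ", ")))
  s <- scored_trials(log)
  total <- nrow(s)
  n_cor <- sum(s$outcome == "correct")
  n_inc <- sum(s$outcome == "incorrect")
  n_om <- sum(s$outcome == "omission")
  n_prem <- if ("premature" %in% names(s)) sum(as.logical(s$premature)) else 0L
  n_persev <- if ("perseverative_correct_responses" %in% names(s)) {
    sum(s$perseverative_correct_responses, na.rm = TRUE)
  } else 0L
  lat_mean <- function(col) {
    if (!col %in% names(s)) return(NA_real_)
    v <- s[[col]][!is.na(s[[col]])]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  tibble::tibble(
    completed_trials = total,
    n_correct = n_cor,
    n_incorrect = n_inc,
    n_omission = n_om,
    n_premature = n_prem,
    n_correction = nrow(log) - total,
    pct_accuracy = pct(n_cor, n_cor + n_inc),
    pct_omission = pct(n_om, total),
    pct_premature = pct(n_prem, total),
    pct_perseverative_correct = pct(n_persev, n_cor),
    mean_response_latency = lat_mean("response_latency_s"),
    mean_reward_latency = lat_mean("reward_latency_s")
  )
}

#' Per-bin dependent variables across a session
#'
#' Splits the trial log into consecutive bins (10 trials by default, the
#' convention used for vigilance analyses) and computes [session_metrics()]
#' within each. A final partial bin is retained and flagged.
#'
#' @param log Trial log as for [session_metrics()].
#' @param bin_size Trials per bin (>= 1).
#' @return A tibble with one row per bin, prefixed by `bin` and `partial`.
#' @export
trial_bin_metrics <- function(log, bin_size = 10) {
  if (bin_size < 1) abort("`bin_size` must be >= 1.")
  if (nrow(log) == 0L) abort("`log` must have at least one trial.")
  idx <- ceiling(seq_len(nrow(log)) / bin_size)
  out <- purrr::map_dfr(split(log, idx), session_metrics, .id = "bin")
  out$bin <- as.integer(out$bin)
  out$partial <- tabulate(idx)[out$bin] < bin_size
  dplyr::relocate(out, "bin", "partial")
}

#' Acquisition criterion over consecutive sessions
#'
#' TRUE when the two most recent sessions both reach at least 80 percent
#' accuracy with at most 20 percent omissions, the criterion used to gate
#' probe testing.
#'
#' @param history Data frame of per-session metrics in chronological order,
#'   with columns `pct_accuracy` and `pct_omission`.
#' @param min_accuracy,max_omission Criterion bounds (percent).
#' @return Logical flag.
#' @export
criterion_met <- function(history, min_accuracy = 80, max_omission = 20) {
  if (nrow(history) < 2L) return(FALSE)
  last2 <- utils::tail(history, 2L)
  all(
    !is.na(last2$pct_accuracy), !is.na(last2$pct_omission),
    last2$pct_accuracy >= min_accuracy, last2$pct_omission <= max_omission
  )
}

#' Aggregate a two-session probe test
#'
#' Probe tests run for two consecutive sessions and are reported as the mean
#' of the two days' metrics.
#'
#' @param sessions Data frame of exactly two rows of session metrics.
#' @return A one-row tibble with the unweighted mean of every numeric metric.
#' @export
probe_aggregate <- function(sessions) {
  if (nrow(sessions) != 2L) abort("A probe test aggregates exactly 2 sessions.")
  num <- vapply(sessions, is.numeric, logical(1))
  out <- sessions[1, , drop = FALSE]
  out[num] <- lapply(sessions[num], mean)
  tibble::as_tibble(out)
}

#' Reversal-learning error decomposition
#'
#' Splits incorrect responses over sessions into perseverative errors (those
#' made before the first session with more than 50 percent correct
#' responding) and learning errors (those made from that session onwards),
#' and counts trials, errors and correction trials to criterion.
#'
#' @param sessions Data frame with one row per session in order, columns
#'   `n_correct`, `n_incorrect` and optionally `n_correction` (e.g. stacked
#'   [session_metrics()] rows).
#' @param criterion_accuracy Percent-correct level defining acquisition of the
#'   reversed contingency (default 80).
#' @return One-row tibble with `perseverative_errors`, `learning_errors`,
#'   `trials_to_criterion`, `errors_to_criterion`,
#'   `corrections_to_criterion` and `criterion_reached`.
#' @export
reversal_metrics <- function(sessions, criterion_accuracy = 80) {
  stopifnot(all(c("n_correct", "n_incorrect") %in% names(sessions)))
  n_corr <- sessions$n_correct
  n_inc <- sessions$n_incorrect
  n_cor_tr <- if ("n_correction" %in% names(sessions)) sessions$n_correction else rep(0L, nrow(sessions))
  pct_correct <- 100 * n_corr / (n_corr + n_inc)
  split_at <- which(pct_correct > 50)[1]  # first session above chance
  persev <- if (is.na(split_at)) sum(n_inc) else sum(n_inc[seq_len(split_at - 1L)])
  learning <- sum(n_inc) - persev
  crit_at <- which(pct_correct >= criterion_accuracy)[1]
  reached <- !is.na(crit_at)
  upto <- if (reached) seq_len(crit_at) else seq_len(nrow(sessions))
  tibble::tibble(
    perseverative_errors = persev,
    learning_errors = learning,
    trials_to_criterion = sum(n_corr[upto] + n_inc[upto]),
    errors_to_criterion = sum(n_inc[upto]),
    corrections_to_criterion = sum(n_cor_tr[upto]),
    criterion_reached = reached
  )
}

#' Progressive-ratio breakpoint and response measures
#'
#' The breakpoint is the number of screen responses emitted in the last
#' successfully completed trial of the session; with a linear ramp schedule
#' that is `ramp_step` times the number of completed trials.
#'
#' @param log Data frame with one row per started trial, columns `completed`
#'   (logical) and optionally `touches_required` (responses demanded by that
#'   trial) and `blank_touches`.
#' @param ramp_step Linear ramp increment (4, 8, 12 or 16 touches); used to
#'   derive `touches_required` when absent.
#' @param session_duration_s Session length, used to normalise blank touches.
#' @return One-row tibble with `breakpoint`, `trials_completed`,
#'   `total_touches` and `blank_touch_rate` (per second, `NA` when blank
#'   touches are not recorded).
#' @export
pr_breakpoint <- function(log, ramp_step = 4, session_duration_s = NULL) {
  if (!ramp_step %in% c(4, 8, 12, 16)) abort("`ramp_step` must be 4, 8, 12 or 16.")
  stopifnot("completed" %in% names(log))
  req <- if ("touches_required" %in% names(log)) log$touches_required else ramp_step * seq_len(nrow(log))
  done <- which(as.logical(log$completed))
  bp <- if (length(done)) req[max(done)] else 0
  total <- sum(req[done])
  blank_rate <- if ("blank_touches" %in% names(log) && !is.null(session_duration_s)) {
    sum(log$blank_touches, na.rm = TRUE) / session_duration_s
  } else NA_real_
  tibble::tibble(
    breakpoint = bp,
    trials_completed = length(done),
    total_touches = total,
    blank_touch_rate = blank_rate
  )
}

#' Novel-object discrimination ratio
#'
#' Time spent exploring the novel object divided by total exploration time;
#' 0.5 is chance, `NA` when the animal explored neither object.
#'
#' @param novel_time,familiar_time Exploration times in seconds (vectorised).
#' @return Proportion in `[0, 1]`.
#' @examples
#' discrimination_ratio(30, 10)
#' @export
discrimination_ratio <- function(novel_time, familiar_time) {
  if (any(c(novel_time, familiar_time) < 0, na.rm = TRUE)) {
    abort("Exploration times must be non-negative.")
  }
  total <- novel_time + familiar_time
  ifelse(total > 0, novel_time / total, NA_real_)
}

#' Percent responses in extinction sessions
#'
#' Total responses divided by responses plus omissions, on a 0-100 scale.
#'
#' @param log Data frame with an `outcome` column taking values `"response"`
#'   or `"omission"`.
#' @return Percentage.
#' @export
extinction_percent_responses <- function(log) {
  if (nrow(log) == 0L) abort("`log` must have at least one trial.")
  bad <- setdiff(unique(log$outcome), c("response", "omission"))
  if (length(bad)) abort(paste0("Unknown outcome value(s): ", paste(bad, collapse = ", ")))
  pct(sum(log$outcome == "response"), nrow(log))
}

#' Accuracy and correction-trial percentage for TUNL / PAL sessions
#'
#' Percent accuracy is correct / (correct + incorrect); percent correction
#' trials is correction trials over the same denominator (correction trials
#' themselves are not scored).
#'
#' @param log Trial log with `outcome` in `"correct"`/`"incorrect"` and an
#'   optional logical `correction_trial` column.
#' @return One-row tibble with `pct_accuracy` and `pct_correction`.
#' @export
tunl_pal_accuracy <- function(log) {
  if (nrow(log) == 0L) abort("`log` must have at least one trial.")
  s <- scored_trials(log)
  n_cor <- sum(s$outcome == "correct")
  n_inc <- sum(s$outcome == "incorrect")
  tibble::tibble(
    pct_accuracy = pct(n_cor, n_cor + n_inc),
    pct_correction = pct(nrow(log) - nrow(s), n_cor + n_inc)
  )
}

#' Collapse per-session data into session bins
#'
#' Adds a `session_bin` column grouping consecutive sessions (e.g. 70
#' paired-associate-learning sessions into 14 five-session bins).
#'
#' @param data Data frame with a numeric session index column.
#' @param session Unquoted session index column.
#' @param bin_size Sessions per bin.
#' @return The input with a `session_bin` integer column.
#' @export
session_bin <- function(data, session, bin_size = 5) {
  session <- rlang::ensym(session)
  if (bin_size < 1) abort("`bin_size` must be >= 1.")
  data$session_bin <- as.integer(ceiling(data[[rlang::as_name(session)]] / bin_size))
  data
}
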