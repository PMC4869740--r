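test_that("session metrics implement the dependent-variable formulas", {
  log <- make_log(rep(c("correct", "incorrect", "omission"), c(30, 5, 5)))
  m <- session_metrics(log)
  expect_equal(m$pct_accuracy, 100 * 30 / 35)
  expect_equal(m$pct_omission, 12.5)
  expect_equal(m$completed_trials, 40)

  # all omitted: accuracy undefined (NA, not 0), omission 100
  m0 <- session_metrics(make_log(rep("omission", 10)))
  expect_true(is.na(m0$pct_accuracy))
  expect_equal(m0$pct_omission, 100)
  expect_true(is.na(m0$mean_response_latency))

  # premature and perseverative percentages
  log2 <- make_log(rep(c("correct", "incorrect"), c(8, 2)),
                   premature = c(rep(TRUE, 3), rep(FALSE, 7)),
                   persev = c(rep(1L, 4), rep(0L, 6)))
  m2 <- session_metrics(log2)
  expect_equal(m2$pct_premature, 30)
  expect_equal(m2$pct_perseverative_correct, 100 * 4 / 8)

  expect_error(session_metrics(make_log(character(0))), "at least one trial")
  expect_error(session_metrics(make_log(c("correct", "typo"))), "Unknown outcome")
})

test_that("correction trials are excluded from metric denominators", {
  log <- make_log(rep(c("correct", "incorrect"), c(6, 2)),
                  correction = c(rep(FALSE, 6), TRUE, FALSE))
  m <- session_metrics(log)
  expect_equal(m$completed_trials, 7)
  expect_equal(m$n_correction, 1)
  expect_equal(m$pct_accuracy, 100 * 6 / 7)
})

test_that("binomial sampling recovers the programmed accuracy at large n", {
  log <- simulate_5csrtt_session("WT", stimulus_duration = 0.8, n_trials = 1e4,
                                 accuracy_curve = function(s) 0.9,
                                 omission_rate = 0.15, seed = 7)
  m <- session_metrics(log)
  se <- 100 * sqrt(0.9 * 0.1 / (m$n_correct + m$n_incorrect))
  expect_lt(abs(m$pct_accuracy - 90), 3 * se)
  expect_lt(abs(m$pct_omission - 15), 3 * 100 * sqrt(0.15 * 0.85 / 1e4))
})

test_that("trial bins conserve session counts and flag the partial bin", {
  log <- simulate_5csrtt_session("DF", 0.6, n_trials = 45, seed = 3)
  bins <- trial_bin_metrics(log, bin_size = 10)
  expect_equal(nrow(bins), 5)
  expect_equal(bins$partial, c(rep(FALSE, 4), TRUE))
  expect_equal(sum(bins$n_correct), sum(log$outcome == "correct"))
  expect_equal(sum(bins$n_omission), sum(log$outcome == "omission"))
  expect_equal(sum(bins$completed_trials), 45)

  bins140 <- trial_bin_metrics(simulate_5csrtt_session("WT", 2, 140, seed = 4))
  expect_equal(nrow(bins140), 14)
  expect_false(any(bins140$partial))
})

test_that("count-based session metrics ignore trial order", {
  log <- simulate_5csrtt_session("WT", 1, n_trials = 60, seed = 9)
  shuffled <- log[sample(nrow(log)), ]
  a <- session_metrics(log); b <- session_metrics(shuffled)
  cols <- c("pct_accuracy", "pct_omission", "pct_premature",
            "pct_perseverative_correct", "completed_trials")
  expect_equal(a[cols], b[cols])
})

test_that("acquisition criterion needs two consecutive qualifying sessions", {
  hist <- tibble::tibble(pct_accuracy = c(85, 82), pct_omission = c(15, 19))
  expect_true(criterion_met(hist))
  expect_false(criterion_met(tibble::tibble(pct_accuracy = c(85, 79),
                                            pct_omission = c(15, 10))))
  expect_false(criterion_met(tibble::tibble(pct_accuracy = 90, pct_omission = 5)))
  # omission bound is the binding constraint here
  expect_false(criterion_met(tibble::tibble(pct_accuracy = c(90, 90),
                                            pct_omission = c(25, 10))))
})

test_that("probe tests aggregate exactly two sessions by unweighted mean", {
  s <- tibble::tibble(pct_accuracy = c(80, 90), pct_omission = c(10, 20))
  agg <- probe_aggregate(s)
  expect_equal(agg$pct_accuracy, 85)
  expect_equal(agg$pct_omission, 15)
  expect_equal(probe_aggregate(s[c(1, 1), ])$pct_accuracy, 80)
  expect_error(probe_aggregate(s[1, ]), "exactly 2")
})

test_that("reversal errors split at the first session above 50 percent correct", {
  sessions <- tibble::tibble(
    n_correct = c(3, 4, 6), n_incorrect = c(7, 6, 4),
    n_correction = c(5, 4, 2)
  )
  r <- reversal_metrics(sessions)
  expect_equal(r$perseverative_errors, 13)
  expect_equal(r$learning_errors, 4)

  # first session already above chance: no perseverative errors
  r2 <- reversal_metrics(tibble::tibble(n_correct = 10, n_incorrect = 0))
  expect_equal(r2$perseverative_errors, 0)
  expect_true(r2$criterion_reached)

  # criterion never reached: counts cover everything, flagged
  low <- tibble::tibble(n_correct = c(2, 3), n_incorrect = c(8, 7))
  r3 <- reversal_metrics(low, criterion_accuracy = 80)
  expect_false(r3$criterion_reached)
  expect_equal(r3$trials_to_criterion, 20)
  expect_equal(r3$errors_to_criterion, 15)
})

test_that("progressive-ratio breakpoint is the last completed requirement", {
  log <- tibble::tibble(completed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  r <- pr_breakpoint(log, ramp_step = 4)
  expect_equal(r$breakpoint, 20)
  expect_equal(r$trials_completed, 5)
  expect_equal(r$total_touches, 4 + 8 + 12 + 16 + 20)

  r0 <- pr_breakpoint(tibble::tibble(completed = logical(0)), ramp_step = 8)
  expect_equal(r0$breakpoint, 0)

  log_b <- tibble::tibble(completed = c(TRUE, FALSE), blank_touches = c(30, 30))
  rb <- pr_breakpoint(log_b, ramp_step = 4, session_duration_s = 600)
  expect_equal(rb$blank_touch_rate, 0.1)
  expect_error(pr_breakpoint(log, ramp_step = 5), "ramp_step")
})

test_that("discrimination ratio and extinction percentages follow their formulas", {
  expect_equal(discrimination_ratio(30, 10), 0.75)
  expect_equal(discrimination_ratio(10, 10), 0.5)
  expect_equal(discrimination_ratio(10, 0), 1)
  expect_true(is.na(discrimination_ratio(0, 0)))
  expect_error(discrimination_ratio(-1, 5), "non-negative")

  ext <- tibble::tibble(outcome = rep(c("response", "omission"), each = 20))
  expect_equal(extinction_percent_responses(ext), 50)
  expect_equal(extinction_percent_responses(tibble::tibble(outcome = rep("response", 5))), 100)
  expect_equal(extinction_percent_responses(tibble::tibble(outcome = rep("omission", 5))), 0)
})

test_that("TUNL/PAL accuracy and correction percentages use scored trials", {
  log <- make_log(rep(c("correct", "incorrect"), c(8, 2)))
  r <- tunl_pal_accuracy(log)
  expect_equal(r$pct_accuracy, 80)
  expect_equal(r$pct_correction, 0)

  withcorr <- make_log(rep(c("correct", "incorrect"), c(8, 2)),
                       correction = rep(c(FALSE, TRUE), c(10, 5)))
  # 5 extra correction rows appended
  withcorr <- dplyr::bind_rows(log, make_log(rep("correct", 5), correction = TRUE))
  r2 <- tunl_pal_accuracy(withcorr)
  expect_equal(r2$pct_correction, 50)

  sessions <- tibble::tibble(session = 1:70, acc = runif(70))
  binned <- session_bin(sessions, session, bin_size = 5)
  expect_equal(max(binned$session_bin), 14)
  expect_equal(unname(table(binned$session_bin)[1]), 5L)
})
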