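test_that("PSTH bins are half-open and counts are conserved", {
  p <- build_psth(0.005, event_times = 0, window = c(-0.01, 0.05))
  expect_equal(sum(p$count), 1)
  expect_equal(p$count[abs(p$bin_left - 0.005) < 1e-9], 1)

  # spike exactly on a bin edge lands in the right-hand bin
  p2 <- build_psth(0.006, event_times = 0, window = c(-0.01, 0.05))
  expect_equal(p2$count[abs(p2$bin_left - 0.006) < 1e-9], 1)

  # count conservation across events and bins
  set.seed(3)
  spikes <- sort(runif(500, 0, 100))
  events <- seq(5, 95, by = 10)
  p3 <- build_psth(spikes, events, window = c(-1.5, 0.5))
  n_in <- sum(vapply(events, function(e) {
    sum(spikes - e >= -1.5 & spikes - e < 0.5)
  }, 1))
  expect_equal(sum(p3$count), n_in)
  expect_equal(p3$rate, p3$count / (length(events) * 0.001))

  expect_error(build_psth(spikes, numeric(0)), "at least one")
})

test_that("homogeneous activity yields flat rates near the true value", {
  set.seed(14)
  events <- seq(5, 2000, by = 10)  # 200 events
  spikes <- simulate_spike_train(10, 2005, seed = 15)
  p <- build_psth(spikes, events, window = c(-1.5, 0.5))
  se <- sqrt(10 / (length(events) * 0.001))
  expect_lt(abs(mean(p$rate) - 10), 3 * se / sqrt(nrow(p)))
  expect_lt(max(abs(p$rate - 10)), 6 * se)  # no bin wildly off
})

test_that("baseline subtraction zeroes the baseline window exactly", {
  set.seed(16)
  spikes <- simulate_spike_train(8, 700, seed = 17)
  events <- seq(5, 695, by = 10)
  p <- baseline_subtract(build_psth(spikes, events))
  sel <- p$bin_left >= -1.4 & p$bin_left < -0.4
  expect_equal(mean(p$rate_bs[sel]), 0, tolerance = 1e-12)
  expect_equal(attr(p, "baseline_mean") + mean(p$rate_bs[sel]),
               mean(p$rate[sel]))

  # a PSTH that does not span the baseline window errors
  short <- build_psth(spikes, events, window = c(-0.2, 0.5))
  expect_error(baseline_subtract(short), "not covered")
})

test_that("averaging requires identical grids and is the unweighted mean", {
  set.seed(18)
  events <- seq(5, 295, by = 10)
  mk <- function(seed) baseline_subtract(
    build_psth(simulate_spike_train(5, 300, seed = seed), events)
  )
  p1 <- mk(1); p2 <- mk(2)
  avg <- average_psth(list(p1, p2))
  expect_equal(avg$rate_bs, (p1$rate_bs + p2$rate_bs) / 2)
  expect_equal(average_psth(list(p1, p1))$rate_bs, p1$rate_bs)

  # opposite responses cancel
  neg <- p1; neg$rate_bs <- -p1$rate_bs; neg$rate <- -p1$rate
  expect_equal(max(abs(average_psth(list(p1, neg))$rate_bs)), 0)

  other <- baseline_subtract(
    build_psth(simulate_spike_train(5, 300, seed = 3), events,
               window = c(-1.6, 0.5))
  )
  expect_error(average_psth(list(p1, other)), "identical bin grid")
})

test_that("response amplitude recovers a rectangular kernel height", {
  # kernel exactly covering the 10-40 ms window, averaged over units
  events <- click_schedule(600)$first_click
  amps <- vapply(1:30, function(i) {
    st <- simulate_spike_train(10, 600, events, evoked_amplitude = 50,
                               evoked_latency = 0.010, kernel_width = 0.030,
                               seed = 100 + i)
    response_amplitude(baseline_subtract(build_psth(st, events)))
  }, 1)
  total_mean <- (50 + 10) * 0.03 * length(events)
  se_one <- sqrt(total_mean) / (length(events) * 0.03)
  expect_lt(abs(mean(amps) - 50), 3 * se_one / sqrt(30))

  # a kernel entirely before 10 ms contributes nothing to the window
  st2 <- simulate_spike_train(10, 600, events, evoked_amplitude = 50,
                              evoked_latency = 0.0, kernel_width = 0.009,
                              seed = 200)
  amp2 <- response_amplitude(baseline_subtract(build_psth(st2, events)))
  expect_lt(abs(amp2), 3 * sqrt(10 * 0.03 * length(events)) / (length(events) * 0.03))

  # all-zero PSTH -> amplitude 0
  p0 <- baseline_subtract(build_psth(numeric(0), events))
  expect_equal(response_amplitude(p0), 0)
})

test_that("amplitude is linear in deterministic per-bin spike counts", {
  events <- 100
  base_spikes <- 100 + seq(-1.4, -0.401, by = 0.001) + 5e-4  # 1 per baseline bin
  for (k in c(1, 2, 4)) {
    win_spikes <- rep(100 + seq(0.0105, 0.0395, by = 0.001), k)
    p <- baseline_subtract(build_psth(c(base_spikes, win_spikes), events))
    expect_equal(response_amplitude(p), k * 1000 - 1000, tolerance = 1e-9)
  }
})

test_that("onset latency is the first significantly elevated bin", {
  # zero baseline: the first bin holding spikes across trials defines latency
  events <- c(10, 20, 30)
  spikes <- events + 0.0125
  p <- baseline_subtract(build_psth(spikes, events))
  expect_equal(onset_latency(p), 0.012)

  # strong responses recover a 15 ms latency within 2 ms for >= 90% of units
  events_l <- click_schedule(600)$first_click
  lat <- vapply(1:40, function(i) {
    st <- simulate_spike_train(10, 600, events_l, evoked_amplitude = 100,
                               evoked_latency = 0.015, seed = 300 + i)
    onset_latency(baseline_subtract(build_psth(st, events_l)))
  }, 1)
  expect_gte(mean(!is.na(lat) & lat >= 0.015 - 1e-9 & lat <= 0.017 + 1e-9), 0.9)

  expect_error(onset_latency(p, alpha = 1.2), "alpha")
})

test_that("null PSTHs rarely report a latency at stringent alpha", {
  # no evoked response: defined-latency fraction bounded by alpha x bins
  events <- seq(5, 595, by = 10.5)
  alpha <- 0.001; bins <- 50
  hits <- vapply(1:300, function(i) {
    st <- simulate_spike_train(10, 600, seed = 400 + i)
    !is.na(onset_latency(baseline_subtract(build_psth(st, events)),
                         alpha = alpha, search_window = bins / 1000))
  }, logical(1))
  expect_lte(mean(hits), alpha * bins + 3 * sqrt(alpha * bins / 300))
})

test_that("event masking removes excluded periods before construction", {
  events <- c(10, 20, 30, 40)
  spikes <- rep(events, each = 2) + c(0.015, 0.2)
  mask <- cbind(c(18, 38), c(22, 42))  # excludes events at 20 and 40
  p <- build_psth(spikes, events, mask = mask)
  expect_equal(attr(p, "n_trials"), 2)
  expect_equal(sum(p$count), 4)
  expect_error(build_psth(spikes, c(20), mask = mask), "inside the mask")
})

test_that("gating ratio compares second-click to first-click amplitudes", {
  sch <- click_schedule(600)
  clicks <- sort(c(sch$first_click, sch$second_click))
  st <- simulate_spike_train(5, 600, clicks, evoked_amplitude = 60,
                             evoked_latency = 0.010, kernel_width = 0.030,
                             seed = 500)
  p <- baseline_subtract(build_psth(st, sch$first_click, window = c(-1.5, 0.6)))
  r <- gating_ratio(p)
  expect_gt(r, 0.6); expect_lt(r, 1.4)  # equal kernels at both clicks
})
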