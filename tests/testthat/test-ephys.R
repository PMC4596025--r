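test_that("baseline noise estimate recovers the true SD on clean noise", {
  est <- vapply(1:10, function(s) {
    estimate_noise(noise_trace(s, duration = 60))
  }, numeric(1))
  expect_true(all(abs(est - 1) < 0.05))
})

test_that("noise estimate is robust to events and matches a masked oracle", {
  # events on ~5% of samples
  bursts <- data.frame(at = seq(20, 560, by = 60), duration = 3000,
                       amplitude = 6)
  tr <- noise_trace(31, bursts = bursts)
  est <- estimate_noise(tr)
  # oracle: robust SD of the event-free samples only
  mask <- rep(TRUE, nrow(tr))
  for (i in seq_len(nrow(bursts))) {
    mask[tr$time_s >= bursts$at[i] - 0.1 &
           tr$time_s <= bursts$at[i] + bursts$duration[i] / 1000 + 0.1] <- FALSE
  }
  oracle <- mad(tr$amplitude_uv[mask])
  expect_equal(est, oracle, tolerance = 0.05)
})

test_that("degenerate traces are refused", {
  flat <- new_lfp_trace(seq(0, 10, by = 0.001), rep(0, 10001))
  expect_equal(estimate_noise(flat), 0)
  expect_error(detect_events(flat), "degenerate")
  short <- new_lfp_trace(seq(0, 0.5, by = 0.001), rnorm(501))
  expect_error(estimate_noise(short), "1000 samples")
})

test_that("detection applies both gates strictly", {
  # 600 ms at 5 sigma: passes both gates
  t1 <- noise_trace(41, bursts = data.frame(at = 300, duration = 600,
                                            amplitude = 5))
  ev <- detect_events(t1)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$duration_ms, 500)
  expect_gte(ev$n_spikes, 2)
  expect_gt(ev$peak_noise_multiple, 3)
  expect_equal(ev$start_s, 300, tolerance = 0.05)
  expect_equal(ev$end_s, 300.6, tolerance = 0.05)
  # 400 ms at 5 sigma: duration gate rejects
  t2 <- noise_trace(41, bursts = data.frame(at = 300, duration = 400,
                                            amplitude = 5))
  expect_equal(nrow(detect_events(t2)), 0)
  # 600 ms at 2 sigma: amplitude gate rejects (2 sigma never crosses 3 sigma
  # threshold; chance noise coincidences are debounced)
  t3 <- noise_trace(41, bursts = data.frame(at = 300, duration = 600,
                                            amplitude = 2))
  expect_equal(nrow(detect_events(t3)), 0)
})

test_that("duration gate bisects to the 500 ms boundary", {
  flip <- function(d) {
    tr <- noise_trace(7, bursts = data.frame(at = 100, duration = d,
                                             amplitude = 5))
    nrow(detect_events(tr)) >= 1
  }
  lo <- 300; hi <- 800
  while (hi - lo > 1) {
    mid <- (lo + hi) / 2
    if (flip(mid)) hi <- mid else lo <- mid
  }
  expect_equal(hi, 500, tolerance = 0.01)
})

test_that("amplitude gate bisects to 3x the estimated noise", {
  # inject into a noise-free window so the gate is probed directly
  # (additive noise under the spikes otherwise shifts the flip point)
  flip <- function(a) {
    tr <- noise_trace(8, quiet_window = c(98, 103),
                      bursts = data.frame(at = 100, duration = 1000,
                                          amplitude = a))
    nrow(detect_events(tr)) >= 1
  }
  lo <- 2; hi <- 5
  while (hi - lo > 0.002) {
    mid <- (lo + hi) / 2
    if (flip(mid)) hi <- mid else lo <- mid
  }
  sigma_hat <- estimate_noise(noise_trace(8, quiet_window = c(98, 103)))
  expect_equal(hi / sigma_hat, 3, tolerance = 0.02)
})

test_that("events are merged iff separated by less than the merge gap", {
  two <- function(gap_ms) {
    noise_trace(15, bursts = data.frame(at = c(100, 100.6 + gap_ms / 1000),
                                        duration = c(600, 600),
                                        amplitude = c(6, 6)))
  }
  # wider than the gap: two events
  ev2 <- detect_events(two(250))
  expect_equal(nrow(ev2), 2)
  # narrower: always merged into one long event
  ev1 <- detect_events(two(120))
  expect_equal(nrow(ev1), 1)
  expect_gt(ev1$duration_ms, 1200)
})

test_that("detection is gain- and offset-equivariant", {
  tr <- noise_trace(21, bursts = data.frame(at = c(100, 300, 450),
                                            duration = c(700, 1500, 900),
                                            amplitude = c(5, 8, 6)))
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 3)
  for (c in c(0.05, 2, 40)) {
    scaled <- new_lfp_trace(tr$time_s, tr$amplitude_uv * c)
    evc <- detect_events(scaled)
    expect_equal(evc$start_s, ev$start_s)
    expect_equal(evc$end_s, ev$end_s)
    expect_equal(evc$n_spikes, ev$n_spikes)
    expect_equal(evc$peak_noise_multiple, ev$peak_noise_multiple,
                 tolerance = 1e-9)
    expect_equal(evc$peak_uv, ev$peak_uv * c, tolerance = 1e-9)
  }
})

test_that("epoch event counts normalize to the reference epoch", {
  ev <- data.frame(start_s = seq_len(12))
  expect_equal(epoch_event_count(ev[0, , drop = FALSE], 600), 0)
  expect_equal(epoch_event_count(ev, recorded = 600, epoch = 600), 12)
  expect_equal(epoch_event_count(ev, recorded = 300, epoch = 600), 24)
})

test_that("detected counts track the generator rate", {
  counts <- vapply(1:40, function(s) {
    sim <- simulate_lfp(lfp_params(event_rate = 3), 600, 1000,
                        seed = 400 + s)
    epoch_event_count(detect_events(sim$trace), recorded = 600)
  }, numeric(1))
  expect_equal(mean(counts), 30, tolerance = 0.1)
})

test_that("suppression calls follow the reduction rule", {
  s <- suppression_call(0, 20)
  expect_true(s$suppressed)
  expect_equal(s$reduction_fraction, 1)
  s <- suppression_call(20, 20)
  expect_false(s$suppressed)
  expect_equal(s$reduction_fraction, 0)
  # boundary: 90% reduction passes at the default rule
  expect_true(suppression_call(2, 20)$suppressed)
  expect_false(suppression_call(2.1, 20)$suppressed)
  expect_error(suppression_call(5, 0), "positive")
})
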