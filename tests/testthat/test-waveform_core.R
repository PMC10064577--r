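test_that("integrate_flow matches closed-form integrals", {
  # constant 0.5 L/s for 1 s at 100 Hz
  v <- integrate_flow(rep(0.5, 101), dt = 0.01)
  expect_equal(v[1], 0)
  expect_equal(v[101], 0.5, tolerance = 1e-12)
  # all-zero flow
  expect_equal(integrate_flow(rep(0, 50), dt = 0.01), rep(0, 50))
  # half-sine amplitude 1 L/s over 1 s -> 2/pi
  t <- seq(0, 1, by = 0.01)
  v <- integrate_flow(sin(pi * t), dt = 0.01)
  expect_equal(v[length(v)], 2 / pi, tolerance = 1e-3)
})

test_that("integrate_flow agrees with an independent trapezoid and rejects bad grids", {
  set.seed(42)
  f <- cumsum(rnorm(200)) / 10
  t <- seq(0, 1.99, by = 0.01)
  expect_equal(integrate_flow(f, dt = 0.01), pracma::cumtrapz(t, f)[, 1],
               tolerance = 1e-12)
  expect_error(integrate_flow(f, dt = 0.01, time = c(0, 0.01, 0.05)),
               "uniform")
  expect_error(integrate_flow(f, dt = -1), "positive")
})

test_that("integration then differentiation round-trips smooth flow", {
  t <- seq(0, 10, by = 0.01)
  f <- 0.8 * sin(2 * pi * 0.3 * t) + 0.2 * cos(2 * pi * 0.11 * t)
  v <- integrate_flow(f, dt = 0.01)
  f_back <- c(f[1], diff(v) / 0.01)
  # central-difference style error bound on smooth signals
  expect_lt(max(abs(f_back[-1] - (f[-1] + f[-length(f)]) / 2)), 1e-2)
})

test_that("detect_effort_episodes finds half-sine efforts and drops chatter", {
  expect_equal(nrow(detect_effort_episodes(rep(0, 1000), sampling_hz = 100)), 0)
  s <- half_sine_series(8, onset = 0.7, duration = 0.8)
  ep <- detect_effort_episodes(s$pmus, threshold = 0.5, sampling_hz = 100)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$peak_time, 1.1, tolerance = 0.02)  # onset + T/2
  expect_equal(ep$peak_amplitude, 8, tolerance = 0.01)
  expect_gte(ep$onset_time, 0.7)
  expect_lte(ep$end_time, 1.5)
  # two efforts separated by 2 s come out in time order
  two <- half_sine_series(8, 0.5, 0.8, total_s = 5)$pmus +
    half_sine_series(5, 3.0, 0.8, total_s = 5)$pmus
  ep2 <- detect_effort_episodes(two, 0.5, 100)
  expect_equal(nrow(ep2), 2)
  expect_true(all(diff(ep2$onset_time) > 0))
  # sub-100-ms blips are discarded
  blip <- rep(0, 500); blip[200:205] <- 3
  expect_equal(nrow(detect_effort_episodes(blip, 0.5, 100)), 0)
})

test_that("detect_effort_episodes equals the brute-force run scan", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 600
    pm <- pmax(0, stats::filter(rnorm(n, 0, 3), rep(1 / 25, 25), sides = 2))
    pm[is.na(pm)] <- 0
    got <- detect_effort_episodes(pm, threshold = 0.5, sampling_hz = 100)
    want <- oracle_effort_episodes(pm, 0.5, 100)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$onset_time, want$onset_time)
      expect_equal(got$peak_time, want$peak_time)
      expect_equal(got$end_time, want$end_time)
      expect_equal(got$peak_amplitude, want$peak_amplitude)
    }
  }
})

test_that("breath-event detection round-trips the simulator's phase log", {
  sim <- passive_vcv(duration_s = 50, rate = 12)
  ev <- detect_breath_events(sim$signals)
  expect_equal(nrow(ev), nrow(sim$events))
  expect_equal(ev$trigger_time, sim$events$trigger_time)
  expect_equal(ev$cycleoff_time, sim$events$cycleoff_time)
  expect_equal(ev$trigger_kind, sim$events$trigger_kind)
})

test_that("flow re-derivation recovers trigger times within one sample", {
  sim <- psv_with_efforts(duration_s = 20)
  ev <- detect_breath_events(sim$signals, use_phase = FALSE)
  expect_equal(nrow(ev), nrow(sim$events))
  expect_true(all(abs(ev$trigger_time - sim$events$trigger_time) <= 0.01 + 1e-9))
})

test_that("apneic records yield an empty event list with a warning", {
  sig <- breath_signals(seq(0, 10, by = 0.01), paw = rep(5, 1001),
                        flow = rep(0, 1001), sampling_hz = 100)
  expect_warning(ev <- detect_breath_events(sig, use_phase = FALSE), "no ventilator cycle")
  expect_equal(nrow(ev), 0)
})

test_that("breath_signals invariants are enforced", {
  t <- seq(0, 1, by = 0.01)
  expect_error(breath_signals(rev(t), rep(5, 101), rep(0, 101)),
               "strictly increasing")
  expect_error(breath_signals(c(0, 0.01, 0.03), rep(5, 3), rep(0, 3)),
               "uniform")
  # volume channel must be the integral of flow on noiseless records
  expect_error(breath_signals(t, rep(5, 101), rep(0.5, 101),
                              volume = rep(0, 101)),
               "integral")
  # malformed breath_id (increment without phase transition)
  bid <- rep(0L, 101); bid[50:101] <- 1L
  expect_error(breath_signals(t, rep(5, 101), rep(0, 101), breath_id = bid),
               "breath_id")
})
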