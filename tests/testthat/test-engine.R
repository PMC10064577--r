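test_that("pmus_waveform evaluates the documented shapes", {
  hs <- effort_profile("half_sine", amplitude = 8, rise_s = 0.4, release_s = 0.4)
  expect_equal(pmus_waveform(hs, 0.4), 8)                   # sine peak at T/2
  expect_equal(pmus_waveform(hs, 2.0), 0)                   # beyond support
  rhr <- effort_profile("ramp_hold_release", 10, rise_s = 0.3, hold_s = 0.2,
                        release_s = 0.3)
  expect_equal(pmus_waveform(rhr, 0.15), 5)                 # linear midpoint
  expect_equal(pmus_waveform(rhr, 0.4), 10)                 # plateau
  expect_equal(pmus_waveform(rhr, 0.65), 10 * (1 - 0.15 / 0.3))
  expect_equal(pmus_waveform(rhr, 0.9), 0)
})

test_that("passive VCV matches the closed-form equation of motion", {
  sim <- passive_vcv(duration_s = 10)
  sig <- sim$signals
  insp1 <- which(sig$phase == "inspiration" & sig$breath_id == 1)
  # Paw(end-insp) = PEEP + R*flow + VT/C = 5 + 10*0.5 + 500/50 = 20 cmH2O
  expect_equal(max(sig$paw[insp1]), 20, tolerance = 0.2)
})

test_that("equation-of-motion residual is below 0.1 cmH2O at all noiseless samples", {
  for (mech in mechanics_presets()) {
    for (sim in list(
      passive_vcv(duration_s = 15, mech = mech),
      psv_with_efforts(duration_s = 15, mech = mech)
    )) {
      sig <- sim$signals
      E <- 1000 / mech$compliance
      res <- sig$paw - (mech$resistance * sig$flow + sig$volume * E +
                          mech$peep_total - sig$pmus_true)
      expect_lt(max(abs(res)), 0.1)
    }
  }
})

test_that("passive expiration decays with time constant R*C", {
  for (mech in mechanics_presets()[c("normal", "restrictive")]) {
    sim <- passive_vcv(duration_s = 15, rate = 8, mech = mech)
    sig <- sim$signals
    e <- which(sig$phase == "expiration" & sig$breath_id == 1 &
                 sig$flow < -0.02)
    fit <- stats::lm(log(-sig$flow[e]) ~ sig$time[e])
    tau_hat <- -1 / coef(fit)[2]
    tau <- mech$resistance * mech$compliance / 1000
    expect_equal(unname(tau_hat), tau, tolerance = 0.05)
  }
})

test_that("machine rate delivers the set number of breaths", {
  m <- normal_mech()
  s <- ventilator_settings("PCV", "flow", 2, support_pressure = 12,
                           insp_time_s = 1, set_rate_bpm = 15)
  sim <- simulate_pv(m, s, duration_s = 60, noise_sd = 0)
  expect_equal(nrow(sim$events), 15)
  expect_true(all(sim$events$trigger_kind == "machine"))
})

test_that("a single effort patient-triggers one PSV breath promptly", {
  m <- normal_mech()
  s <- ventilator_settings("PSV", "flow", 2, support_pressure = 12)
  sim <- simulate_pv(m, s, effort_train(5, effort_profile("half_sine", 8, 0.4, 0, 0.4)),
                     duration_s = 15, noise_sd = 0)
  expect_equal(nrow(sim$events), 1)
  expect_equal(sim$events$trigger_kind, "patient")
  expect_gte(sim$events$trigger_time, 5)
  expect_lt(sim$events$trigger_time, 5.1)   # within 100 ms of effort onset
})

test_that("volume returns to baseline between non-stacked breaths", {
  sim <- psv_with_efforts(duration_s = 30)
  sig <- sim$signals
  vt <- max(sig$volume)
  # last expiratory sample before each trigger after the first breath
  for (tt in sim$events$trigger_time[-1]) {
    k <- max(which(sig$time < tt - 0.01))
    expect_lt(abs(sig$volume[k]), 0.05 * vt)
  }
})

test_that("simulation is bit-identical for identical seed and inputs", {
  a <- psv_with_efforts(seed = 7, noise_sd = 0.3)
  b <- psv_with_efforts(seed = 7, noise_sd = 0.3)
  expect_identical(a$signals, b$signals)
  expect_identical(a$events, b$events)
  c <- psv_with_efforts(seed = 8, noise_sd = 0.3)
  expect_false(identical(a$signals$paw, c$signals$paw))
})

test_that("auto-trigger artifacts fire only when and where they should", {
  m <- normal_mech()
  s <- ventilator_settings("PSV", "flow", 2, support_pressure = 12,
                           set_rate_bpm = 0, refractory_s = 0.3)
  base <- simulate_pv(m, s, duration_s = 20, noise_sd = 0)
  expect_equal(nrow(base$events), 0)
  # 0.1 L/s blip vs 2 L/min (0.033 L/s) threshold during expiration
  art <- inject_autotrigger_artifact(times = 5, artifact_flow_lps = 0.1)
  sim <- simulate_pv(m, s, duration_s = 20, noise_sd = 0, artifact = art)
  expect_equal(nrow(sim$events), 1)
  expect_equal(sim$events$trigger_kind, "artifact")
  expect_equal(nrow(sim$efforts_gold), 0)   # no overlapping gold effort
  # below-threshold blip leaves the breath count unchanged
  art2 <- inject_autotrigger_artifact(times = 5, artifact_flow_lps = 0.02)
  sim2 <- simulate_pv(m, s, duration_s = 20, noise_sd = 0, artifact = art2)
  expect_equal(nrow(sim2$events), 0)
  # blip during inspiration is ignored (trigger armed only in expiration)
  s3 <- ventilator_settings("PCV", "flow", 2, support_pressure = 12,
                            insp_time_s = 1, set_rate_bpm = 6)
  art3 <- inject_autotrigger_artifact(times = 10.6, artifact_flow_lps = 0.1)
  sim3a <- simulate_pv(m, s3, duration_s = 20, noise_sd = 0)
  sim3b <- simulate_pv(m, s3, duration_s = 20, noise_sd = 0, artifact = art3)
  expect_equal(nrow(sim3b$events), nrow(sim3a$events))
})

test_that("degenerate mechanics are rejected before integration", {
  expect_error(respiratory_mechanics(-5, 50), "resistance")
  expect_error(respiratory_mechanics(10, 0), "compliance")
})

test_that("entrained efforts follow machine insufflations at the set delay", {
  m <- normal_mech()
  s <- ventilator_settings("PCV", "pressure", 3, support_pressure = 15,
                           insp_time_s = 1, set_rate_bpm = 12, refractory_s = 1)
  ef <- effort_train(profile = effort_profile("half_sine", 6, 0.4, 0, 0.4),
                     entrain_to_machine = TRUE, entrain_delay_s = 0.3)
  sim <- simulate_pv(m, s, ef, duration_s = 30, noise_sd = 0)
  expect_equal(nrow(sim$efforts_gold), nrow(sim$events))
  delays <- sim$efforts_gold$onset_time - sim$events$trigger_time
  expect_true(all(abs(delays - 0.3) < 1e-9))
})
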