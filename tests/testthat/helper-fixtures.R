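# Shared fixtures: small simulated records built in code.

normal_mech <- function() respiratory_mechanics(10, 50, peep_total = 5)

passive_vcv <- function(duration_s = 30, seed = 1L, noise_sd = 0,
                        rate = 12, mech = normal_mech()) {
  simulate_pv(
    mech,
    ventilator_settings("VCV", "flow", 2, tidal_volume_l = 0.5,
                        insp_flow_lps = 0.5, set_rate_bpm = rate),
    duration_s = duration_s, seed = seed, noise_sd = noise_sd
  )
}

psv_with_efforts <- function(duration_s = 30, seed = 1L, noise_sd = 0,
                             amplitude = 8, mech = normal_mech()) {
  simulate_pv(
    mech,
    ventilator_settings("PSV", "flow", 2, support_pressure = 12,
                        cycling_flow_fraction = 0.25),
    effort_train(seq(1, duration_s - 2, by = 3),
                 effort_profile("half_sine", amplitude, 0.4, 0, 0.4)),
    duration_s = duration_s, seed = seed, noise_sd = noise_sd
  )
}

balanced_participants <- function() {
  # four strata with even sizes summing to 98
  data.frame(
    id = 1:98,
    profession = c(rep("physician", 48), rep("respiratory_therapist", 50)),
    experience = c(rep(c("<=5y", ">5y"), each = 24),
                   rep(c("<=5y", ">5y"), c(24, 26)))
  )
}

half_sine_series <- function(peak, onset, duration, hz = 100, total_s = 3) {
  t <- seq(0, total_s, by = 1 / hz)
  p <- ifelse(t >= onset & t <= onset + duration,
              peak * sin(pi * (t - onset) / duration), 0)
  list(t = t, pmus = p)
}
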