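# Deterministic battery of 49 labeled scenarios: seven asynchrony types plus
# synchronous cycles, spread over three respiratory-mechanics presets
# (normal, obstructive, restrictive) and at least two effort amplitudes per
# category.
#
# Each recipe is designed so that the intended asynchrony actually arises from
# the closed-loop physics (amplitudes, inspiratory times, cycling criteria and
# expiratory refractory periods chosen so the trigger/cycling logic produces
# the category's defining event pattern), and the injected primary label is
# recoverable by the rule-based labeler from gold Pmus plus the event log.

#' Respiratory mechanics presets
#'
#' Conventional teaching-range triad used by the default battery: normal
#' (R = 10 cmH2O·s/L, C = 50 mL/cmH2O), obstructive (R = 20, C = 60) and
#' restrictive (R = 10, C = 25), all at total PEEP 5 cmH2O.
#'
#' @return named list of `respiratory_mechanics` objects.
#' @export
mechanics_presets <- function() {
  list(
    normal = respiratory_mechanics(10, 50, peep_total = 5),
    obstructive = respiratory_mechanics(20, 60, peep_total = 5),
    restrictive = respiratory_mechanics(10, 25, peep_total = 5)
  )
}

new_scenario <- function(scenario_id, category, mechanics_name, mechanics,
                         settings, efforts, artifact = NULL,
                         injected_labels, duration_s = 30, noise_sd = 0.1) {
  stopifnot(length(injected_labels) >= 1L,
            all(injected_labels %in% ASYNC_LABELS), duration_s == 30)
  structure(list(scenario_id = as.integer(scenario_id), category = category,
                 mechanics_name = mechanics_name, mechanics = mechanics,
                 settings = settings, efforts = efforts, artifact = artifact,
                 injected_labels = injected_labels,
                 duration_s = duration_s, noise_sd = noise_sd),
            class = "pv_scenario")
}

#' @export
print.pv_scenario <- function(x, ...) {
  cat(sprintf("<pv_scenario %d> %s | %s mechanics | %s mode\n", x$scenario_id,
              x$category, x$mechanics_name, x$settings$mode))
  invisible(x)
}

#' Build the default 49-scenario battery
#'
#' Deterministic composition: 6 scenarios for each of the seven asynchrony
#' categories (three mechanics presets x two effort amplitudes, or two
#' artifact magnitudes for auto-triggering) plus 7 synchronous scenarios,
#' each a 30-s recording. A documented minority of scenarios carry a
#' secondary label (double-triggering scenarios also cycle off before the
#' effort peak; reverse-triggering-with-double-cycling scenarios contain the
#' plain entrainment pattern).
#'
#' @return list of 49 `pv_scenario` objects, scenario_id 1..49.
#' @export
build_default_battery <- function() {
  mp <- mechanics_presets()
  scen <- list()
  sid <- 0L
  add <- function(...) {
    sid <<- sid + 1L
    scen[[sid]] <<- new_scenario(sid, ...)
  }

  # --- synchronous (7): assisted PCV, effort comfortably inside inspiration
  for (m in names(mp)) {
    for (amp in c(6, 10)) {
      add("synchronous", m, mp[[m]],
          ventilator_settings("PCV", "flow", 2, support_pressure = 12,
                              insp_time_s = 0.7, set_rate_bpm = 0,
                              refractory_s = 0.5),
          effort_train(seq(1, 28, by = 3),
                       effort_profile("half_sine", amp, 0.5, 0, 0.5)),
          injected_labels = "synchronous")
    }
  }
  add("synchronous", "normal", mp$normal,
      ventilator_settings("VCV", "flow", 2, tidal_volume_l = 0.45,
                          insp_flow_lps = 0.6, set_rate_bpm = 0,
                          refractory_s = 0.5),
      effort_train(seq(1, 28, by = 3),
                   effort_profile("half_sine", 8, 0.5, 0, 0.5)),
      injected_labels = "synchronous")

  # --- ineffective effort (6): weak efforts between mandatory PCV breaths,
  #     insensitive pressure trigger
  for (m in names(mp)) {
    for (amp in c(1.2, 2.0)) {
      add("ineffective_effort", m, mp[[m]],
          ventilator_settings("PCV", "pressure", 3, support_pressure = 15,
                              insp_time_s = 1.0, set_rate_bpm = 10,
                              refractory_s = 0.3),
          effort_train(seq(3.5, 27.5, by = 6),
                       effort_profile("half_sine", amp, 0.4, 0, 0.4)),
          injected_labels = "ineffective_effort")
    }
  }

  # --- auto-triggering (6): passive patient, expiratory flow blips cross the
  #     flow trigger
  for (m in names(mp)) {
    for (blip in c(0.08, 0.12)) {
      add("auto_triggering", m, mp[[m]],
          ventilator_settings("PSV", "flow", 2, support_pressure = 12,
                              cycling_flow_fraction = 0.25, set_rate_bpm = 0,
                              max_insp_time_s = 1.5, refractory_s = 0.3),
          effort_train(),
          artifact = inject_autotrigger_artifact(seq(2, 26, by = 4), blip),
          injected_labels = "auto_triggering")
    }
  }

  # --- double triggering (6): long strong effort, short low-pressure assisted
  #     PCV inspiration; the remaining effort retriggers
  for (m in names(mp)) {
    for (amp in c(12, 16)) {
      add("double_triggering", m, mp[[m]],
          ventilator_settings("PCV", "flow", 2, support_pressure = 6,
                              insp_time_s = 0.5, set_rate_bpm = 0,
                              refractory_s = 0.2),
          effort_train(seq(1, 29, by = 4),
                       effort_profile("half_sine", amp, 0.8, 0, 0.8)),
          injected_labels = c("double_triggering", "premature_cycling"))
    }
  }

  # --- reverse triggering (6): mandatory PCV with entrained efforts at fixed
  #     delay, too weak/late to retrigger
  for (m in names(mp)) {
    for (amp in c(4, 7)) {
      add("reverse_triggering", m, mp[[m]],
          ventilator_settings("PCV", "pressure", 3, support_pressure = 15,
                              insp_time_s = 1.0, set_rate_bpm = 12,
                              refractory_s = 1.0),
          effort_train(profile = effort_profile("half_sine", amp, 0.4, 0, 0.4),
                       entrain_to_machine = TRUE, entrain_delay_s = 0.3),
          injected_labels = "reverse_triggering")
    }
  }

  # --- reverse triggering with double cycling (6): strong entrained effort
  #     outlasting the mandatory inspiration and retriggering
  for (m in names(mp)) {
    for (amp in c(12, 16)) {
      add("reverse_triggering_double_cycling", m, mp[[m]],
          ventilator_settings("PCV", "flow", 2, support_pressure = 9,
                              insp_time_s = 0.7, set_rate_bpm = 12,
                              refractory_s = 0.2),
          effort_train(profile = effort_profile("half_sine", amp, 0.6, 0, 0.6),
                       entrain_to_machine = TRUE, entrain_delay_s = 0.5),
          injected_labels = c("reverse_triggering_double_cycling",
                              "reverse_triggering"))
    }
  }

  # --- premature cycling (6): inspiratory time far shorter than the effort,
  #     long refractory prevents breath stacking
  for (m in names(mp)) {
    for (amp in c(8, 12)) {
      add("premature_cycling", m, mp[[m]],
          ventilator_settings("PCV", "flow", 2, support_pressure = 15,
                              insp_time_s = 0.4, set_rate_bpm = 0,
                              refractory_s = 1.5),
          effort_train(seq(1, 29, by = 4),
                       effort_profile("half_sine", amp, 0.7, 0, 0.7)),
          injected_labels = "premature_cycling")
    }
  }

  # --- delayed cycling (6): assisted inspiratory time far outlasting the
  #     effort, so cycle-off falls after effort end on every mechanics preset
  for (m in names(mp)) {
    for (amp in c(6, 10)) {
      add("delayed_cycling", m, mp[[m]],
          ventilator_settings("PCV", "flow", 2, support_pressure = 12,
                              insp_time_s = 2.0, set_rate_bpm = 0,
                              refractory_s = 0.5),
          effort_train(seq(1, 29, by = 4),
                       effort_profile("half_sine", amp, 0.4, 0, 0.4)),
          injected_labels = "delayed_cycling")
    }
  }

  stopifnot(length(scen) == 49L)
  scen
}

#' Render a scenario to waveforms and its answer-key entry
#'
#' Runs the closed-loop simulator for the scenario's 30-s recording and
#' returns the sampled record, the ventilator event log, the gold effort
#' episodes, and the answer-key entry (scenario id, injected primary label,
#' full label set). Rendering is deterministic given the seed.
#'
#' @param scenario a `pv_scenario`.
#' @param seed integer seed for the measurement noise (combined with the
#'   scenario id so each scenario gets its own stream).
#' @param noise_sd override of the scenario's measurement-noise sd
#'   (`NULL` = use the scenario's value; 0 gives a noiseless render).
#' @return list with `signals`, `events`, `efforts_gold`, `key`.
#' @export
render_scenario <- function(scenario, seed = 1L, noise_sd = NULL) {
  stopifnot(inherits(scenario, "pv_scenario"))
  if (is.null(noise_sd)) noise_sd <- scenario$noise_sd
  sim <- simulate_pv(scenario$mechanics, scenario$settings, scenario$efforts,
                     duration_s = scenario$duration_s,
                     seed = (as.integer(seed) * 101L + scenario$scenario_id) %% .Machine$integer.max,
                     noise_sd = noise_sd, artifact = scenario$artifact)
  sim$key <- list(scenario_id = scenario$scenario_id,
                  primary_label = scenario$injected_labels[1L],
                  all_labels = scenario$injected_labels)
  sim
}

#' Battery answer key
#'
#' @param battery list of `pv_scenario` objects (default battery if omitted).
#' @return data.frame with columns `scenario_id`, `primary_label`,
#'   `all_labels` (semicolon-joined), one row per scenario.
#' @export
answer_key <- function(battery = build_default_battery()) {
  data.frame(
    scenario_id = vapply(battery, function(s) s$scenario_id, integer(1)),
    primary_label = vapply(battery, function(s) s$injected_labels[1L], character(1)),
    all_labels = vapply(battery, function(s)
      paste(s$injected_labels, collapse = ";"), character(1))
  )
}

#' Battery manifest
#'
#' Version-pinned summary of the deterministic battery composition, suitable
#' for serialization to YAML.
#'
#' @param battery list of `pv_scenario` objects.
#' @return data.frame, one row per scenario, with the recipe's headline
#'   parameters.
#' @export
battery_manifest <- function(battery = build_default_battery()) {
  data.frame(
    scenario_id = vapply(battery, function(s) s$scenario_id, integer(1)),
    primary_label = vapply(battery, function(s) s$injected_labels[1L], character(1)),
    all_labels = vapply(battery, function(s)
      paste(s$injected_labels, collapse = ";"), character(1)),
    mechanics = vapply(battery, function(s) s$mechanics_name, character(1)),
    resistance = vapply(battery, function(s) s$mechanics$resistance, numeric(1)),
    compliance = vapply(battery, function(s) s$mechanics$compliance, numeric(1)),
    mode = vapply(battery, function(s) s$settings$mode, character(1)),
    trigger = vapply(battery, function(s) s$settings$trigger_kind, character(1)),
    effort_amplitude = vapply(battery, function(s)
      s$efforts$profile$amplitude, numeric(1)),
    entrained = vapply(battery, function(s)
      s$efforts$entrain_to_machine, logical(1)),
    artifact_lps = vapply(battery, function(s)
      if (is.null(s$artifact)) 0 else s$artifact$artifact_flow_lps, numeric(1)),
    duration_s = vapply(battery, function(s) s$duration_s, numeric(1))
  )
}

#' Label one rendered scenario
#'
#' Convenience wrapper: runs the rule-based labeler on a rendered scenario and
#' aggregates to the scenario-level primary label.
#'
#' @param rendered output of [render_scenario()] (or of [simulate_pv()]).
#' @param source `"gold"` to use the simulator's gold effort episodes,
#'   `"detect"` to re-detect episodes from the record's Pmus channel,
#'   `"estimate"` to detect them from a supplied estimated Pmus series.
#' @param pmus_estimate estimated Pmus series (required for
#'   `source = "estimate"`).
#' @param ... tolerances passed to [label_breaths()].
#' @return list with `primary`, `all_labels`, and the full [label_breaths()]
#'   output under `detail`.
#' @export
label_scenario <- function(rendered, source = c("gold", "detect", "estimate"),
                           pmus_estimate = NULL, ...) {
  source <- match.arg(source)
  efforts <- switch(source,
    gold = rendered$efforts_gold,
    detect = detect_effort_episodes(rendered$signals),
    estimate = {
      if (is.null(pmus_estimate)) stop("supply pmus_estimate")
      detect_effort_episodes(pmus_estimate,
                             sampling_hz = attr(rendered$signals, "sampling_hz"),
                             t0 = rendered$signals$time[1L])
    })
  lb <- label_breaths(rendered$events, efforts = efforts, ...)
  if (nrow(lb$breaths) == 0L && nrow(lb$unpaired_efforts) == 0L) {
    return(list(primary = "synchronous", all_labels = "synchronous", detail = lb))
  }
  sl <- scenario_label(lb)
  list(primary = sl$primary, all_labels = sl$all_labels, detail = lb)
}
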