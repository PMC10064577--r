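# Closed-loop single-compartment patient-ventilator simulation.
#
# Equation of motion (single compartment, linear):
#   Paw(t) = R * flow(t) + V(t)/C + PEEP_total - Pmus(t)
# with R in cmH2O.s/L, C in mL/cmH2O (so the elastic term is V[L]*1000/C),
# PEEP_total the baseline alveolar pressure and Pmus >= 0 subtracted (muscle
# effort lowers alveolar pressure).
#
# The loop advances at the sampling rate with explicit-Euler sub-stepping
# (x10) for stiffness; trigger and cycling decisions are taken once per
# output sample.

#' Respiratory-system mechanics
#'
#' @param resistance airway resistance (cmH2O·s/L), `> 0`.
#' @param compliance respiratory-system compliance (mL/cmH2O), `> 0`.
#' @param peep_total baseline alveolar pressure (cmH2O).
#' @return object of class `respiratory_mechanics`.
#' @export
respiratory_mechanics <- function(resistance, compliance, peep_total = 5) {
  stopifnot(resistance > 0, compliance > 0)
  structure(list(resistance = resistance, compliance = compliance,
                 peep_total = peep_total),
            class = "respiratory_mechanics")
}

#' Patient effort profile
#'
#' Shape of one inspiratory effort. `half_sine` is
#' `amplitude * sin(pi * t / T)` on `[0, T]` with
#' `T = rise_s + hold_s + release_s`; `ramp_hold_release` rises linearly over
#' `rise_s`, holds for `hold_s` and releases linearly over `release_s`.
#'
#' @param shape `"half_sine"` or `"ramp_hold_release"`.
#' @param amplitude peak Pmus (cmH2O), `>= 0`.
#' @param rise_s,hold_s,release_s segment durations (s), `>= 0`.
#' @return object of class `effort_profile`.
#' @export
effort_profile <- function(shape = c("half_sine", "ramp_hold_release"),
                           amplitude = 8, rise_s = 0.4, hold_s = 0,
                           release_s = 0.4) {
  shape <- match.arg(shape)
  stopifnot(amplitude >= 0, rise_s >= 0, hold_s >= 0, release_s >= 0)
  total <- rise_s + hold_s + release_s
  if (amplitude > 0 && total <= 0) stop("effort with positive amplitude needs positive duration")
  structure(list(shape = shape, amplitude = amplitude, rise_s = rise_s,
                 hold_s = hold_s, release_s = release_s, total_s = total),
            class = "effort_profile")
}

#' Evaluate an effort profile
#'
#' @param profile an `effort_profile`.
#' @param t_since_onset time since effort onset (s), vectorized, `>= 0`.
#' @return Pmus value(s) in cmH2O; 0 outside the profile's support.
#' @export
pmus_waveform <- function(profile, t_since_onset) {
  stopifnot(inherits(profile, "effort_profile"), all(t_since_onset >= -1e-12))
  t <- t_since_onset
  Ttot <- profile$total_s
  a <- profile$amplitude
  if (a == 0 || Ttot == 0) return(rep(0, length(t)))
  out <- numeric(length(t))
  inside <- t >= 0 & t <= Ttot
  if (profile$shape == "half_sine") {
    out[inside] <- a * sin(pi * t[inside] / Ttot)
  } else {
    r <- profile$rise_s; h <- profile$hold_s; rel <- profile$release_s
    ti <- t[inside]
    v <- numeric(length(ti))
    up <- ti < r
    v[up] <- a * ti[up] / r
    mid <- ti >= r & ti < r + h
    v[mid] <- a
    dn <- ti >= r + h
    if (rel > 0) v[dn] <- a * pmax(0, 1 - (ti[dn] - r - h) / rel)
    out[inside] <- v
  }
  out
}

#' Patient effort train
#'
#' Either a list of absolute onset times, or an entrained train in which each
#' effort fires at a fixed delay after every machine (or artifact) insufflation
#' onset — the substrate of reverse triggering.
#'
#' @param onsets strictly increasing onset times (s); ignored when
#'   `entrain_to_machine` is set.
#' @param profile an `effort_profile` shared by all efforts.
#' @param entrain_to_machine logical; fire efforts at machine-insufflation
#'   onset plus `entrain_delay_s` instead of at `onsets`.
#' @param entrain_delay_s entrainment delay (s).
#' @return object of class `effort_train`.
#' @export
effort_train <- function(onsets = numeric(0), profile = effort_profile(),
                         entrain_to_machine = FALSE, entrain_delay_s = 0.3) {
  if (length(onsets) > 1L && any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
  structure(list(onsets = as.numeric(onsets), profile = profile,
                 entrain_to_machine = isTRUE(entrain_to_machine),
                 entrain_delay_s = entrain_delay_s),
            class = "effort_train")
}

#' Ventilator settings
#'
#' @param mode `"PSV"`, `"PCV"` or `"VCV"`.
#' @param trigger_kind `"flow"` (threshold in L/min on inspiratory flow) or
#'   `"pressure"` (threshold in cmH2O below set PEEP; the demand valve
#'   occludes inspiratory flow during expiration so effort reads as a
#'   pressure dip).
#' @param trigger_threshold trigger sensitivity, `> 0` (L/min or cmH2O).
#' @param support_pressure pressure above PEEP (cmH2O) for PSV/PCV.
#' @param tidal_volume_l,insp_flow_lps VCV set tidal volume (L) and constant
#'   inspiratory flow (L/s).
#' @param rise_time_s first-order pressurization time constant (s).
#' @param cycling_flow_fraction PSV expiratory cycling criterion, fraction of
#'   peak inspiratory flow, in (0,1).
#' @param insp_time_s set inspiratory time (s) for PCV/VCV (VCV default:
#'   `tidal_volume_l / insp_flow_lps`).
#' @param set_rate_bpm mandatory/backup rate (breaths/min), `>= 0` (0 = none).
#' @param peep_set set PEEP (cmH2O).
#' @param max_insp_time_s PSV inspiratory-time safety cap (s).
#' @param refractory_s minimum expiratory time before the patient trigger
#'   re-arms (s).
#' @return object of class `ventilator_settings`.
#' @export
ventilator_settings <- function(mode = c("PSV", "PCV", "VCV"),
                                trigger_kind = c("flow", "pressure"),
                                trigger_threshold = 2,
                                support_pressure = 12,
                                tidal_volume_l = 0.5, insp_flow_lps = 0.5,
                                rise_time_s = 0.1,
                                cycling_flow_fraction = 0.25,
                                insp_time_s = NULL, set_rate_bpm = 0,
                                peep_set = 5, max_insp_time_s = 2.5,
                                refractory_s = 0.2) {
  mode <- match.arg(mode)
  trigger_kind <- match.arg(trigger_kind)
  stopifnot(trigger_threshold > 0, cycling_flow_fraction > 0,
            cycling_flow_fraction < 1, set_rate_bpm >= 0, rise_time_s >= 0,
            max_insp_time_s > 0, refractory_s >= 0)
  if (is.null(insp_time_s)) {
    insp_time_s <- if (mode == "VCV") tidal_volume_l / insp_flow_lps else 1.0
  }
  stopifnot(insp_time_s > 0)
  structure(list(mode = mode, trigger_kind = trigger_kind,
                 trigger_threshold = trigger_threshold,
                 support_pressure = support_pressure,
                 tidal_volume_l = tidal_volume_l, insp_flow_lps = insp_flow_lps,
                 rise_time_s = rise_time_s,
                 cycling_flow_fraction = cycling_flow_fraction,
                 insp_time_s = insp_time_s, set_rate_bpm = set_rate_bpm,
                 peep_set = peep_set, max_insp_time_s = max_insp_time_s,
                 refractory_s = refractory_s),
            class = "ventilator_settings")
}

#' Auto-trigger artifact specification
#'
#' Brief exogenous flow blips (half-sine, 150 ms) superimposed on the sensed
#' flow during expiration — e.g. circuit condensation or cardiac oscillation —
#' capable of crossing the flow trigger with `pmus_true == 0`. They are sensed
#' and recorded flow, not system flow, so they do not enter the equation of
#' motion.
#'
#' @param times blip onset times (s).
#' @param artifact_flow_lps blip peak amplitude (L/s).
#' @param duration_s blip duration (s), default 0.15.
#' @return object of class `autotrigger_artifact`.
#' @export
inject_autotrigger_artifact <- function(times, artifact_flow_lps,
                                        duration_s = 0.15) {
  stopifnot(all(diff(times) > 0) || length(times) <= 1L,
            artifact_flow_lps > 0, duration_s > 0)
  structure(list(times = as.numeric(times),
                 artifact_flow_lps = artifact_flow_lps,
                 duration_s = duration_s),
            class = "autotrigger_artifact")
}

artifact_flow_at <- function(artifact, t) {
  if (is.null(artifact)) return(0)
  for (t0 in artifact$times) {
    dt <- t - t0
    if (dt >= 0 && dt <= artifact$duration_s) {
      return(artifact$artifact_flow_lps * sin(pi * dt / artifact$duration_s))
    }
  }
  0
}

#' Simulate a patient-ventilator recording
#'
#' Advances the closed loop of a single-compartment active respiratory system
#' and a ventilator with trigger, pressurization and cycling logic, and
#' returns the sampled record plus the ventilator event log and the gold
#' effort episodes (taken from the programmed effort train, not re-detected).
#' Gaussian measurement noise is added to the exported paw and flow channels
#' only; the gold `pmus_true` channel stays noiseless because it is the
#' answer key.
#'
#' @param mechanics a `respiratory_mechanics` object.
#' @param settings a `ventilator_settings` object.
#' @param efforts an `effort_train` (may be empty for a passive patient).
#' @param duration_s record length (s), default 30.
#' @param seed integer RNG seed for the measurement noise.
#' @param noise_sd measurement-noise sd on the exported airway-pressure
#'   channel (cmH2O); the flow channel receives one tenth of this value in
#'   L/s, matching the relative scales of typical pressure and flow sensors.
#' @param sampling_hz output sampling rate (Hz), default 100.
#' @param artifact optional `autotrigger_artifact`.
#' @return list with elements `signals` (a `breath_signals`), `events`
#'   (a `breath_events`) and `efforts_gold` (an `effort_episodes`).
#' @details The loop uses an implicit trapezoidal (Crank-Nicolson) step per
#'   sample, which is unconditionally stable for the stiff single-compartment
#'   dynamics and makes the recorded flow, volume and airway pressure
#'   mutually consistent: the volume channel is exactly the trapezoidal
#'   integral of the recorded system flow, and the equation of motion holds
#'   at every sample to numerical precision.
#' @export
simulate_pv <- function(mechanics, settings, efforts = effort_train(),
                        duration_s = 30, seed = 1L, noise_sd = 0,
                        sampling_hz = 100, artifact = NULL) {
  stopifnot(inherits(mechanics, "respiratory_mechanics"),
            inherits(settings, "ventilator_settings"),
            inherits(efforts, "effort_train"), duration_s > 0)
  R <- mechanics$resistance
  E <- 1000 / mechanics$compliance            # cmH2O/L
  tau <- R / E
  if (!is.finite(tau) || tau <= 0) stop("nonpositive time constant: unstable parameters")
  peep_alv <- mechanics$peep_total
  peep_set <- settings$peep_set
  dt <- 1 / sampling_hz
  n <- as.integer(round(duration_s * sampling_hz)) + 1L
  tgrid <- (seq_len(n) - 1L) * dt

  thr_flow <- settings$trigger_threshold / 60   # L/min -> L/s
  thr_pres <- settings$trigger_threshold
  prof <- efforts$profile
  onsets <- if (efforts$entrain_to_machine) numeric(0) else efforts$onsets
  onsets <- onsets[onsets < duration_s]

  pmus_at <- function(t) {
    keep <- onsets[t - onsets >= 0 & t - onsets <= prof$total_s]
    if (!length(keep)) return(0)
    sum(pmus_waveform(prof, t - keep))
  }

  # state
  V <- 0                       # L above end-expiratory baseline (prev sample)
  f_prev <- 0                  # system flow at previous sample (L/s)
  first <- TRUE
  phase <- "expiration"
  breath_id <- 0L
  t_cycleoff <- -Inf           # time of last cycle-off
  t_insp0 <- NA_real_
  peak_flow <- 0
  period <- if (settings$set_rate_bpm > 0) 60 / settings$set_rate_bpm else Inf
  next_mandatory <- if (is.finite(period)) 0.5 else Inf

  paw_out <- numeric(n); flow_out <- numeric(n); pmus_out <- numeric(n)
  phase_out <- character(n); bid_out <- integer(n); af_out <- numeric(n)
  ev_trig <- numeric(0); ev_coff <- numeric(0); ev_kind <- character(0)

  # implicit trapezoidal step under a pressure boundary: solve
  #   f_k = (Pdrive - E*V_k)/R,  V_k = V_prev + dt/2*(f_prev + f_k)
  step_pressure <- function(pdrive) {
    if (first) {
      f <- (pdrive - E * V) / R
      list(f = f, V = V)
    } else {
      f <- (pdrive - E * (V + dt / 2 * f_prev)) / (R + E * dt / 2)
      list(f = f, V = V + dt / 2 * (f_prev + f))
    }
  }
  # step with imposed flow (VCV square wave, or occluded demand valve)
  step_flow <- function(f) {
    if (first) list(f = f, V = V)
    else list(f = f, V = V + dt / 2 * (f_prev + f))
  }
  step_expiration <- function(pmus) {
    st <- step_pressure(peep_set - peep_alv + pmus)
    if (settings$trigger_kind == "pressure" && st$f > 0) {
      # demand valve closed to inspiratory flow: effort reads as pressure dip
      st <- step_flow(0)
      st$paw <- peep_alv + st$V * E - pmus
    } else {
      st$paw <- peep_set
    }
    st
  }
  step_inspiration <- function(pmus, ti) {
    if (settings$mode == "VCV") {
      st <- step_flow(settings$insp_flow_lps)
      st$paw <- R * st$f + st$V * E + peep_alv - pmus
    } else {
      target <- settings$support_pressure
      paw <- peep_set + if (settings$rise_time_s > 0) {
        target * (1 - exp(-ti / settings$rise_time_s))
      } else target
      st <- step_pressure(paw - peep_alv + pmus)
      st$paw <- paw
    }
    st
  }

  start_breath <- function(t, kind) {
    phase <<- "inspiration"
    breath_id <<- breath_id + 1L
    t_insp0 <<- t
    peak_flow <<- 0
    ev_trig <<- c(ev_trig, t)
    ev_kind <<- c(ev_kind, kind)
    if (efforts$entrain_to_machine && kind %in% c("machine", "artifact")) {
      onsets <<- sort(c(onsets, t + efforts$entrain_delay_s))
    }
  }
  end_breath <- function(t) {
    phase <<- "expiration"
    t_cycleoff <<- t
    ev_coff <<- c(ev_coff, t)
  }

  for (k in seq_len(n)) {
    t <- tgrid[k]
    pmus <- pmus_at(t)
    st <- NULL

    # ---- trigger decisions (taken on the tentative expiration sample) ----
    if (phase == "expiration") {
      st <- step_expiration(pmus)
      armed <- (t - t_cycleoff) >= settings$refractory_s
      if (settings$trigger_kind == "pressure") {
        patient_fire <- armed && (peep_set - st$paw) >= thr_pres
      } else {
        sensed <- st$f + artifact_flow_at(artifact, t)
        patient_fire <- armed && sensed >= thr_flow
      }
      if (is.finite(next_mandatory) && t >= next_mandatory) {
        start_breath(t, "machine")
        next_mandatory <- next_mandatory + period
      } else if (patient_fire) {
        af <- artifact_flow_at(artifact, t)
        kind <- if (settings$trigger_kind == "flow" && af > 0 &&
                    st$f < thr_flow) "artifact" else "patient"
        start_breath(t, kind)
      }
    }

    if (phase == "inspiration") {
      ti <- t - t_insp0
      st <- step_inspiration(pmus, ti)
      if (st$f > peak_flow) peak_flow <- st$f
      cyc <- if (settings$mode == "PSV") {
        (ti >= 0.1 && st$f <= settings$cycling_flow_fraction * peak_flow) ||
          ti >= settings$max_insp_time_s
      } else {
        ti >= settings$insp_time_s
      }
      if (cyc && ti > 0) {
        end_breath(t)
        st <- step_expiration(pmus)
      }
    }

    # record sample and commit state
    af_rec <- if (phase == "expiration") artifact_flow_at(artifact, t) else 0
    af_out[k] <- af_rec
    paw_out[k] <- st$paw
    flow_out[k] <- st$f + af_rec
    pmus_out[k] <- pmus
    phase_out[k] <- phase
    bid_out[k] <- breath_id
    V <- st$V
    f_prev <- st$f
    first <- FALSE
  }

  if (length(ev_coff) < length(ev_trig)) ev_coff <- c(ev_coff, tgrid[n])
  events <- breath_events(ev_trig, ev_coff, ev_kind,
                          breath_id = seq_along(ev_trig))

  # gold effort episodes from the realized (possibly entrained) onset list
  onsets <- onsets[onsets < duration_s]
  if (length(onsets) && prof$amplitude > 0) {
    peak_off <- if (prof$shape == "half_sine") prof$total_s / 2 else
      prof$rise_s + prof$hold_s / 2
    gold <- effort_episodes(onset_time = onsets,
                            peak_time = onsets + peak_off,
                            peak_amplitude = prof$amplitude,
                            end_time = onsets + prof$total_s)
  } else {
    gold <- effort_episodes(numeric(0), numeric(0), numeric(0), numeric(0))
  }

  # effort-id channel
  eid <- rep(NA_integer_, n)
  if (nrow(gold)) {
    for (i in seq_len(nrow(gold))) {
      eid[tgrid >= gold$onset_time[i] & tgrid <= gold$end_time[i]] <- i
    }
  }

  volume <- integrate_flow(flow_out, dt = dt)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    paw_out <- paw_out + stats::rnorm(n, 0, noise_sd)
    flow_out <- flow_out + stats::rnorm(n, 0, noise_sd / 10)
  }
  sig <- breath_signals(tgrid, paw_out, flow_out, volume = volume,
                        pmus_true = pmus_out, phase = phase_out,
                        breath_id = bid_out, effort_id = eid,
                        sampling_hz = sampling_hz, noise_sd = noise_sd)
  attr(sig, "trigger_kind") <- events$trigger_kind
  attr(sig, "seed") <- as.integer(seed)
  # sensed (non-system) artifact flow, for consistency checks: the recorded
  # flow/volume channels include it, the equation of motion does not
  if (any(af_out != 0)) attr(sig, "artifact_flow") <- af_out
  list(signals = sig, events = events, efforts_gold = gold)
}
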