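# Rule-based per-breath and per-scenario asynchrony classification from a
# Pmus channel (gold or estimated) plus the ventilator event log.
#
# Categories: synchronous, ineffective_effort, auto_triggering,
# double_triggering, reverse_triggering, reverse_triggering_double_cycling,
# premature_cycling, delayed_cycling.

ASYNC_LABELS <- c("synchronous", "ineffective_effort", "auto_triggering",
                  "double_triggering", "reverse_triggering",
                  "reverse_triggering_double_cycling", "premature_cycling",
                  "delayed_cycling")

# precedence used for rule resolution and scenario-level tie-breaking
LABEL_PRECEDENCE <- c("ineffective_effort", "double_triggering",
                      "auto_triggering", "reverse_triggering",
                      "reverse_triggering_double_cycling", "premature_cycling",
                      "delayed_cycling", "synchronous")

#' Asynchrony label vocabulary
#'
#' @return character vector of the eight per-breath categories (seven
#'   asynchronies plus `synchronous`).
#' @export
asynchrony_labels <- function() ASYNC_LABELS

#' Associate effort episodes with breath events
#'
#' Greedy nearest-in-time pairing. A breath is associated with an effort when
#' its trigger time falls in `[onset - 0.1 s, end_time + window_s]`, or when
#' the effort's onset falls inside the breath's inspiration
#' `[trigger_time, cycleoff_time]` (the entrained-effort case of reverse
#' triggering, where the effort begins after the machine trigger). Each effort
#' may own several breaths (stacking); each breath owns at most one effort.
#'
#' @param efforts an `effort_episodes` table (time-ordered).
#' @param events a `breath_events` table (time-ordered).
#' @param window_s association window after effort end (s), default 0.3.
#' @param pre_onset_s slack before effort onset (s), default 0.1.
#' @return data.frame with one row per breath: `breath_id`, `effort_id`
#'   (`NA` if unpaired), `trigger_delay_s` (trigger − onset).
#' @export
associate_efforts <- function(efforts, events, window_s = 0.3,
                              pre_onset_s = 0.1) {
  out <- data.frame(breath_id = events$breath_id,
                    effort_id = rep(NA_integer_, nrow(events)),
                    trigger_delay_s = rep(NA_real_, nrow(events)))
  if (!nrow(efforts) || !nrow(events)) return(out)
  for (i in seq_len(nrow(events))) {
    tt <- events$trigger_time[i]
    co <- events$cycleoff_time[i]
    ok <- (tt >= efforts$onset_time - pre_onset_s &
             tt <= efforts$end_time + window_s) |
      (efforts$onset_time >= tt & efforts$onset_time <= co)
    if (any(ok)) {
      cand <- which(ok)
      j <- cand[which.min(abs(tt - efforts$onset_time[cand]))]
      out$effort_id[i] <- efforts$effort_id[j]
      out$trigger_delay_s[i] <- tt - efforts$onset_time[j]
    }
  }
  out
}

#' Label breaths and unpaired efforts with asynchrony categories
#'
#' Executable form of the standard asynchrony definitions, applied per effort
#' and per breath with first-match-wins rule order:
#'
#' 1. `ineffective_effort` — effort without ventilator triggering (unpaired).
#' 2. `double_triggering` — two (or more) ventilator cycles triggered by a
#'    single effort: the effort owns >= 2 breaths whose inter-trigger gap is
#'    shorter than effort duration + window and the first stacked breath is
#'    patient-triggered.
#' 3. `auto_triggering` — patient- or artifact-triggered breath with no
#'    paired effort.
#' 4. `reverse_triggering` — machine-triggered breath whose paired effort
#'    begins after the trigger, with onset delay stable (sd < `entrain_sd_s`)
#'    across >= 3 consecutive machine breaths; with a stacked second breath
#'    the variant is `reverse_triggering_double_cycling` (both stacked
#'    breaths receive it).
#' 5. `premature_cycling` — cycle-off before the paired effort's peak.
#' 6. `delayed_cycling` — cycle-off later than effort end + `grace_s`.
#' 7. `synchronous` otherwise.
#'
#' @param signals optional `breath_signals`; when `efforts` is `NULL` the
#'   effort episodes are detected from its Pmus channel.
#' @param events a `breath_events` table.
#' @param efforts an `effort_episodes` table (gold episodes or episodes
#'   detected from an estimated Pmus).
#' @param window_s association window (s), default 0.3.
#' @param entrain_sd_s entrainment-delay stability tolerance (s), default 0.1.
#' @param grace_s delayed-cycling grace period (s), default 0.1.
#' @param pmus_threshold detection threshold when efforts are detected from
#'   `signals` (cmH2O).
#' @return list with `breaths` (data.frame: breath_id, label,
#'   associated_effort_id, trigger_delay_s, cycleoff_minus_peak_s,
#'   cycleoff_minus_end_s) and `unpaired_efforts` (data.frame: effort_id,
#'   label — always `ineffective_effort`).
#' @export
label_breaths <- function(events, efforts = NULL, signals = NULL,
                          window_s = 0.3, entrain_sd_s = 0.1, grace_s = 0.1,
                          pmus_threshold = 0.5) {
  if (is.null(efforts)) {
    if (is.null(signals)) stop("supply either `efforts` or `signals`")
    efforts <- detect_effort_episodes(signals, threshold = pmus_threshold)
  }
  nb <- nrow(events)
  pair <- associate_efforts(efforts, events, window_s = window_s)
  lab <- rep(NA_character_, nb)

  eff_row <- function(id) match(id, efforts$effort_id)
  breaths_of <- function(id) which(!is.na(pair$effort_id) & pair$effort_id == id)

  # rule 1: unpaired efforts -> ineffective_effort
  unpaired <- setdiff(efforts$effort_id, pair$effort_id[!is.na(pair$effort_id)])
  unpaired_df <- data.frame(effort_id = unpaired,
                            label = rep("ineffective_effort", length(unpaired)))

  # stacking bookkeeping per effort
  stacked_effort <- logical(nrow(efforts))
  if (nrow(efforts)) {
    for (r in seq_len(nrow(efforts))) {
      b <- breaths_of(efforts$effort_id[r])
      if (length(b) >= 2L) {
        dur <- efforts$end_time[r] - efforts$onset_time[r]
        gaps <- diff(events$trigger_time[b])
        stacked_effort[r] <- any(gaps < dur + window_s)
      }
    }
  }

  # rule 2: double triggering (first stacked breath patient-triggered)
  for (r in which(stacked_effort)) {
    b <- breaths_of(efforts$effort_id[r])
    if (events$trigger_kind[b[1L]] == "patient") {
      lab[b] <- "double_triggering"
    }
  }

  # rule 3: auto-triggering
  auto <- is.na(lab) & is.na(pair$effort_id) &
    events$trigger_kind %in% c("patient", "artifact")
  lab[auto] <- "auto_triggering"

  # rule 4: reverse triggering (entrainment across >= 3 machine breaths)
  mach <- which(events$trigger_kind == "machine")
  delays <- rep(NA_real_, nb)
  follows <- rep(FALSE, nb)
  for (i in mach) {
    id <- pair$effort_id[i]
    if (!is.na(id)) {
      r <- eff_row(id)
      if (efforts$onset_time[r] >= events$trigger_time[i]) {
        follows[i] <- TRUE
        delays[i] <- efforts$onset_time[r] - events$trigger_time[i]
      }
    }
  }
  entrained <- rep(FALSE, nb)
  if (length(mach) >= 3L) {
    for (w in seq_len(length(mach) - 2L)) {
      idx <- mach[w:(w + 2L)]
      if (all(follows[idx]) && stats::sd(delays[idx]) < entrain_sd_s) {
        entrained[idx] <- TRUE
      }
    }
  }
  for (i in which(entrained & is.na(lab))) {
    r <- eff_row(pair$effort_id[i])
    if (stacked_effort[r]) {
      b <- breaths_of(pair$effort_id[i])
      lab[b[is.na(lab[b])]] <- "reverse_triggering_double_cycling"
    } else {
      lab[i] <- "reverse_triggering"
    }
  }

  # rules 5-6: cycling-phase timing (needs an associated effort)
  cmp <- rep(NA_real_, nb); cme <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    id <- pair$effort_id[i]
    if (is.na(id)) next
    r <- eff_row(id)
    cmp[i] <- events$cycleoff_time[i] - efforts$peak_time[r]
    cme[i] <- events$cycleoff_time[i] - efforts$end_time[r]
    if (!is.na(lab[i])) next
    if (cmp[i] < 0) {
      lab[i] <- "premature_cycling"
    } else if (cme[i] > grace_s) {
      lab[i] <- "delayed_cycling"
    }
  }

  lab[is.na(lab)] <- "synchronous"
  list(
    breaths = data.frame(
      breath_id = events$breath_id, label = lab,
      associated_effort_id = pair$effort_id,
      trigger_delay_s = pair$trigger_delay_s,
      cycleoff_minus_peak_s = cmp, cycleoff_minus_end_s = cme
    ),
    unpaired_efforts = unpaired_df
  )
}

#' Scenario-level primary label
#'
#' Aggregates per-breath labels (plus ineffective-effort labels of unpaired
#' efforts) into one primary scenario label: the most frequent
#' non-synchronous label, ties broken by rule-order precedence;
#' `synchronous` only when no non-synchronous label occurs.
#'
#' @param labeled output of [label_breaths()], or a character vector of labels.
#' @return list with `primary` (character scalar) and `all_labels`
#'   (character vector of distinct labels present).
#' @export
scenario_label <- function(labeled) {
  labs <- if (is.character(labeled)) labeled else
    c(labeled$breaths$label, labeled$unpaired_efforts$label)
  if (!length(labs)) stop("scenario_label needs at least one labeled unit")
  stopifnot(all(labs %in% ASYNC_LABELS))
  nonsync <- labs[labs != "synchronous"]
  if (!length(nonsync)) {
    return(list(primary = "synchronous", all_labels = "synchronous"))
  }
  tab <- table(nonsync)
  top <- names(tab)[tab == max(tab)]
  primary <- LABEL_PRECEDENCE[LABEL_PRECEDENCE %in% top][1L]
  list(primary = primary, all_labels = unique(c(primary, sort(unique(labs)))))
}
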