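# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# per-sample scan for threshold runs (effort-episode oracle)
oracle_effort_episodes <- function(pmus, threshold, hz, min_dur = 0.1, t0 = 0) {
  out <- NULL
  in_run <- FALSE
  start <- NA_integer_
  for (k in seq_along(pmus)) {
    if (!in_run && !is.na(pmus[k]) && pmus[k] >= threshold) {
      in_run <- TRUE; start <- k
    }
    ends <- in_run && (k == length(pmus) || is.na(pmus[k + 1]) ||
                         pmus[k + 1] < threshold)
    if (ends) {
      if ((k - start) / hz >= min_dur) {
        pk <- start - 1 + which.max(pmus[start:k])
        out <- rbind(out, data.frame(
          onset_time = t0 + (start - 1) / hz, peak_time = t0 + (pk - 1) / hz,
          peak_amplitude = pmus[pk], end_time = t0 + (k - 1) / hz))
      }
      in_run <- FALSE
    }
  }
  if (is.null(out)) data.frame(onset_time = numeric(0), peak_time = numeric(0),
                               peak_amplitude = numeric(0),
                               end_time = numeric(0)) else out
}

# exhaustive pairing: every assignment of breaths to candidate efforts (or
# none), minimizing total |trigger - onset| over valid assignments
oracle_associate <- function(efforts, events, window = 0.3, pre = 0.1) {
  nb <- nrow(events)
  cand <- lapply(seq_len(nb), function(i) {
    tt <- events$trigger_time[i]; co <- events$cycleoff_time[i]
    ok <- (tt >= efforts$onset_time - pre & tt <= efforts$end_time + window) |
      (efforts$onset_time >= tt & efforts$onset_time <= co)
    c(NA_integer_, which(ok))
  })
  grids <- do.call(expand.grid, cand)
  best <- NULL; best_cost <- Inf
  for (g in seq_len(nrow(grids))) {
    asg <- as.integer(grids[g, ])
    cost <- sum(abs(events$trigger_time - efforts$onset_time[asg]), na.rm = TRUE) +
      1e6 * sum(is.na(asg))   # prefer pairing whenever valid
    if (cost < best_cost) { best_cost <- cost; best <- asg }
  }
  best
}

# direct per-definition labeling on a paired timeline
oracle_labels <- function(efforts, events, window = 0.3, entrain_sd = 0.1,
                          grace = 0.1) {
  asg <- oracle_associate(efforts, events, window)
  nb <- nrow(events)
  lab <- rep(NA_character_, nb)
  # stacking per effort
  stacked <- vapply(seq_len(nrow(efforts)), function(r) {
    b <- which(!is.na(asg) & asg == r)
    length(b) >= 2 && any(diff(events$trigger_time[b]) <
                            (efforts$end_time[r] - efforts$onset_time[r]) + window)
  }, logical(1))
  for (r in which(stacked)) {
    b <- which(!is.na(asg) & asg == r)
    if (events$trigger_kind[b[1]] == "patient") lab[b] <- "double_triggering"
  }
  lab[is.na(lab) & is.na(asg) &
        events$trigger_kind %in% c("patient", "artifact")] <- "auto_triggering"
  # entrainment over machine breaths
  mach <- which(events$trigger_kind == "machine")
  delay <- rep(NA_real_, nb)
  for (i in mach) {
    if (!is.na(asg[i]) && efforts$onset_time[asg[i]] >= events$trigger_time[i]) {
      delay[i] <- efforts$onset_time[asg[i]] - events$trigger_time[i]
    }
  }
  entrained <- rep(FALSE, nb)
  if (length(mach) >= 3) {
    for (w in 1:(length(mach) - 2)) {
      idx <- mach[w:(w + 2)]
      if (!anyNA(delay[idx]) && sd(delay[idx]) < entrain_sd) entrained[idx] <- TRUE
    }
  }
  for (i in which(entrained & is.na(lab))) {
    r <- asg[i]
    b <- which(!is.na(asg) & asg == r)
    if (stacked[r]) lab[b[is.na(lab[b])]] <- "reverse_triggering_double_cycling"
    else lab[i] <- "reverse_triggering"
  }
  for (i in seq_len(nb)) {
    if (!is.na(lab[i]) || is.na(asg[i])) next
    r <- asg[i]
    if (events$cycleoff_time[i] < efforts$peak_time[r]) {
      lab[i] <- "premature_cycling"
    } else if (events$cycleoff_time[i] > efforts$end_time[r] + grace) {
      lab[i] <- "delayed_cycling"
    }
  }
  lab[is.na(lab)] <- "synchronous"
  unpaired <- setdiff(seq_len(nrow(efforts)), asg[!is.na(asg)])
  list(breath_labels = lab,
       ineffective = efforts$effort_id[unpaired])
}

# confusion-matrix tally oracle for rater scoring
oracle_score <- function(responses, key) {
  kl <- key$primary_label[match(responses$scenario_id, key$scenario_id)]
  out <- NULL
  for (pid in unique(responses$participant_id)) {
    sel <- responses$participant_id == pid
    a <- responses$answered_label[sel]; k <- kl[sel]
    asy <- k != "synchronous"
    out <- rbind(out, data.frame(
      participant_id = pid,
      sensitivity = sum(a[asy] == k[asy]) / sum(asy),
      specificity = sum(a[!asy] == "synchronous") / sum(!asy)))
  }
  out
}

# random small timeline generator for the labeler property test
random_timeline <- function(seed) {
  set.seed(seed)
  ne <- sample(0:4, 1)
  efforts <- if (ne > 0) {
    onset <- sort(runif(ne, 0, 20)); onset <- onset + seq_len(ne) * 2.5
    dur <- runif(ne, 0.5, 1.2)
    effort_episodes(onset, onset + dur / 2, runif(ne, 2, 12), onset + dur)
  } else effort_episodes(numeric(0), numeric(0), numeric(0), numeric(0))
  nb <- sample(0:4, 1)
  if (nb > 0) {
    trig <- numeric(nb)
    for (i in seq_len(nb)) {
      if (ne > 0 && runif(1) < 0.7) {
        j <- sample(ne, 1)
        trig[i] <- efforts$onset_time[j] + runif(1, -0.2, 0.6)
      } else trig[i] <- runif(1, 0, 30)
    }
    trig <- sort(trig)
    # enforce separation so cycles do not overlap
    for (i in seq_len(nb)[-1]) trig[i] <- max(trig[i], trig[i - 1] + 1.3)
    dur <- runif(nb, 0.4, 1.2)
    kind <- sample(c("patient", "machine", "artifact"), nb, replace = TRUE)
    events <- breath_events(trig, trig + dur, kind)
  } else {
    events <- breath_events(numeric(0), numeric(0), character(0), integer(0))
  }
  list(efforts = efforts, events = events)
}
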