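# Shared time-series types and signal primitives.
#
# A BreathSignals object is a data.frame with one row per sample and the
# columns below, plus attributes "sampling_hz" and "noise_sd". All pressures
# are in cmH2O, flow in L/s (inspiratory positive), volume in L above the
# end-expiratory baseline. Pmus is stored nonnegative and enters the equation
# of motion with a minus sign (muscle effort lowers alveolar pressure).

#' Construct a BreathSignals record
#'
#' Bundles sampled ventilator waveforms into the package's standard
#' multichannel container: time, airway pressure, flow, volume, true
#' inspiratory muscle pressure (Pmus), per-sample ventilator phase and
#' breath/effort identifiers.
#'
#' @param time numeric vector of sample times (s), uniformly spaced.
#' @param paw airway pressure (cmH2O).
#' @param flow airway flow (L/s, inspiratory positive).
#' @param volume volume above end-expiratory baseline (L). If `NULL` it is
#'   computed by trapezoidal integration of `flow`.
#' @param pmus_true nonnegative muscle pressure (cmH2O), or `NULL` when the
#'   record carries no reference Pmus (control-group view).
#' @param phase character vector, `"inspiration"` or `"expiration"`.
#' @param breath_id integer ventilator-cycle counter; increments exactly at
#'   expiration-to-inspiration transitions, 0 before the first breath.
#' @param effort_id integer effort-episode counter or `NA` outside efforts.
#' @param sampling_hz sampling rate (Hz).
#' @param noise_sd measurement-noise standard deviation recorded with the
#'   object (cmH2O on paw; same numeric value on flow in L/s).
#' @param validate check the type invariants (default `TRUE`).
#' @return A `breath_signals` data.frame.
#' @export
breath_signals <- function(time, paw, flow, volume = NULL, pmus_true = NULL,
                           phase = NULL, breath_id = NULL, effort_id = NULL,
                           sampling_hz = NULL, noise_sd = 0, validate = TRUE) {
  n <- length(time)
  if (n > 1L && any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (is.null(sampling_hz)) {
    if (n < 2L) stop("need at least 2 samples or an explicit sampling_hz")
    sampling_hz <- 1 / (time[2L] - time[1L])
  }
  if (is.null(volume)) volume <- integrate_flow(flow, dt = 1 / sampling_hz)
  if (is.null(phase)) phase <- rep("expiration", n)
  if (is.null(breath_id)) breath_id <- rep(0L, n)
  if (is.null(effort_id)) effort_id <- rep(NA_integer_, n)
  x <- data.frame(
    time = as.numeric(time), paw = as.numeric(paw), flow = as.numeric(flow),
    volume = as.numeric(volume),
    pmus_true = if (is.null(pmus_true)) NA_real_ else as.numeric(pmus_true),
    phase = as.character(phase), breath_id = as.integer(breath_id),
    effort_id = as.integer(effort_id)
  )
  attr(x, "sampling_hz") <- sampling_hz
  attr(x, "noise_sd") <- noise_sd
  class(x) <- c("breath_signals", "data.frame")
  if (validate) validate_breath_signals(x)
  x
}

#' Validate a BreathSignals record against its invariants
#'
#' Checks that time is strictly increasing with a constant step, that the
#' volume channel is the running trapezoidal integral of flow (only enforced
#' on noiseless records, since measurement noise on the exported flow channel
#' breaks sample-level consistency), and that phase transitions and breath-id
#' increments are well formed.
#'
#' @param x a `breath_signals` object.
#' @param volume_tol tolerance (L) for the volume/flow consistency check.
#' @return `x`, invisibly. Errors on violation.
#' @export
validate_breath_signals <- function(x, volume_tol = 1e-3) {
  stopifnot(inherits(x, "breath_signals"))
  dt <- diff(x$time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) stop("time grid not uniform (step varies > 1e-9 s)")
  if (!all(x$phase %in% c("inspiration", "expiration"))) {
    stop("phase must be 'inspiration' or 'expiration'")
  }
  if (isTRUE(attr(x, "noise_sd") == 0)) {
    v <- integrate_flow(x$flow, dt = dt[1L])
    if (max(abs(v - x$volume)) > volume_tol) {
      stop("volume is not the trapezoidal integral of flow (tol ", volume_tol, " L)")
    }
  }
  tr <- which(x$phase[-1L] == "inspiration" & x$phase[-nrow(x)] == "expiration") + 1L
  inc <- which(diff(x$breath_id) != 0L) + 1L
  if (!identical(tr, inc)) {
    stop("breath_id must increment exactly at expiration->inspiration transitions")
  }
  if (any(diff(x$breath_id)[diff(x$breath_id) != 0L] != 1L)) {
    stop("breath_id must increment by 1")
  }
  if (!all(is.na(x$pmus_true)) && any(x$pmus_true < -1e-9, na.rm = TRUE)) {
    stop("pmus_true must be nonnegative (stored-positive convention)")
  }
  invisible(x)
}

#' @export
print.breath_signals <- function(x, ...) {
  cat(sprintf(
    "<breath_signals> %d samples @ %g Hz (%.1f s), %d breaths, pmus %s\n",
    nrow(x), attr(x, "sampling_hz"), x$time[nrow(x)] - x$time[1L],
    max(x$breath_id), if (all(is.na(x$pmus_true))) "absent" else "present"
  ))
  invisible(x)
}

#' Cumulative trapezoidal integration of a flow signal
#'
#' @param flow flow samples (L/s) on a uniform time grid.
#' @param dt sample interval (s), `> 0`.
#' @param time optional time vector; if supplied it must be uniform (used
#'   only to reject non-uniform grids with an explicit message).
#' @return numeric vector of integrated volume (L); first sample 0.
#' @examples
#' integrate_flow(rep(0.5, 101), dt = 0.01)[101] # 0.5 L
#' @export
integrate_flow <- function(flow, dt, time = NULL) {
  if (!is.null(time)) {
    d <- diff(time)
    if (length(d) && (any(d <= 0) || max(d) - min(d) > 1e-9)) {
      stop("integrate_flow requires a uniform, strictly increasing time grid")
    }
    if (length(d)) dt <- d[1L]
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be a positive scalar")
  n <- length(flow)
  if (n == 0L) return(numeric(0))
  c(0, cumsum((flow[-1L] + flow[-n]) / 2) * dt)
}

#' Detect effort episodes in a Pmus series
#'
#' Finds maximal contiguous runs where `pmus >= threshold`. Episode onset is
#' the first sample at/above threshold, end is the last sample of the run
#' (decay below threshold), and the peak is the within-run maximum. Runs
#' shorter than `min_duration_s` are discarded as numerical chatter.
#'
#' @param pmus muscle-pressure samples (cmH2O) or a `breath_signals` object
#'   (its `pmus_true` channel is used).
#' @param threshold detection threshold (cmH2O), `> 0`; default 0.5.
#' @param sampling_hz sampling rate; taken from the object when available.
#' @param min_duration_s minimum episode duration (s); default 0.1.
#' @param t0 time of the first sample (s).
#' @return data.frame of class `effort_episodes` with columns `effort_id`,
#'   `onset_time`, `peak_time`, `peak_amplitude`, `end_time`; zero rows for a
#'   passive record.
#' @export
detect_effort_episodes <- function(pmus, threshold = 0.5, sampling_hz = 100,
                                   min_duration_s = 0.1, t0 = 0) {
  if (inherits(pmus, "breath_signals")) {
    sampling_hz <- attr(pmus, "sampling_hz")
    t0 <- pmus$time[1L]
    pmus <- pmus$pmus_true
  }
  stopifnot(threshold > 0)
  pmus[is.na(pmus)] <- 0
  above <- pmus >= threshold
  out <- effort_episodes(numeric(0), numeric(0), numeric(0), numeric(0))
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths - 1L) / sampling_hz >= min_duration_s
  if (!any(keep)) return(out)
  starts <- starts[keep]; ends <- ends[keep]
  pk <- mapply(function(a, b) a - 1L + which.max(pmus[a:b]), starts, ends)
  effort_episodes(
    onset_time = t0 + (starts - 1L) / sampling_hz,
    peak_time = t0 + (pk - 1L) / sampling_hz,
    peak_amplitude = pmus[pk],
    end_time = t0 + (ends - 1L) / sampling_hz
  )
}

#' Construct an effort-episode table
#'
#' @param onset_time,peak_time,peak_amplitude,end_time episode fields
#'   (seconds and cmH2O); `onset_time < peak_time <= end_time`,
#'   `peak_amplitude > 0`.
#' @param effort_id optional identifiers; defaults to time order.
#' @return data.frame of class `effort_episodes`.
#' @export
effort_episodes <- function(onset_time, peak_time, peak_amplitude, end_time,
                            effort_id = seq_along(onset_time)) {
  x <- data.frame(
    effort_id = as.integer(effort_id), onset_time = as.numeric(onset_time),
    peak_time = as.numeric(peak_time),
    peak_amplitude = as.numeric(peak_amplitude),
    end_time = as.numeric(end_time)
  )
  if (nrow(x)) {
    stopifnot(
      all(x$onset_time < x$peak_time | x$peak_time == x$onset_time),
      all(x$peak_time <= x$end_time), all(x$peak_amplitude > 0)
    )
  }
  class(x) <- c("effort_episodes", "data.frame")
  x
}

#' Construct a breath-event table
#'
#' One row per ventilator cycle: trigger time, cycle-off time and trigger kind
#' (`patient`, `machine` or `artifact`).
#'
#' @param trigger_time,cycleoff_time event times (s), `trigger < cycleoff`.
#' @param trigger_kind one of `"patient"`, `"machine"`, `"artifact"` per event.
#' @param breath_id unique integer ids ordered by trigger time.
#' @return data.frame of class `breath_events`.
#' @export
breath_events <- function(trigger_time, cycleoff_time, trigger_kind,
                          breath_id = seq_along(trigger_time)) {
  x <- data.frame(
    breath_id = as.integer(breath_id), trigger_time = as.numeric(trigger_time),
    cycleoff_time = as.numeric(cycleoff_time),
    trigger_kind = as.character(trigger_kind)
  )
  if (nrow(x)) {
    stopifnot(
      all(x$trigger_time < x$cycleoff_time),
      !anyDuplicated(x$breath_id),
      !is.unsorted(x$trigger_time),
      all(x$trigger_kind %in% c("patient", "machine", "artifact"))
    )
  }
  class(x) <- c("breath_events", "data.frame")
  x
}

#' Detect ventilator breath events in a record
#'
#' For simulator output the per-sample phase and breath-id bookkeeping is read
#' back directly (lossless round trip). For imported records without a phase
#' channel, inspiration onset is re-derived as an upward flow crossing of
#' +0.05 L/s sustained for at least 50 ms, and cycle-off as the subsequent
#' flow downcross below 0; trigger kind is then reported as `"patient"`.
#'
#' @param signals a `breath_signals` object.
#' @param use_phase read the phase/breath_id channels when present (default);
#'   set `FALSE` to force re-derivation from flow.
#' @param flow_threshold_lps onset threshold for re-derivation (L/s).
#' @param sustain_s minimum sustained time above threshold (s).
#' @return a `breath_events` table; empty (with a warning) when no cycle is
#'   detectable.
#' @export
detect_breath_events <- function(signals, use_phase = TRUE,
                                 flow_threshold_lps = 0.05, sustain_s = 0.05) {
  stopifnot(inherits(signals, "breath_signals"))
  hz <- attr(signals, "sampling_hz")
  if (use_phase && any(signals$phase == "inspiration")) {
    insp <- signals$phase == "inspiration"
    on <- which(insp & !c(FALSE, insp[-nrow(signals)]))
    off <- which(!insp & c(FALSE, insp[-nrow(signals)]))
    kinds <- attr(signals, "trigger_kind")
    ev <- list(trig = signals$time[on],
               coff = signals$time[if (length(off) < length(on)) c(off, nrow(signals)) else off])
    if (is.null(kinds)) kinds <- rep("patient", length(on))
    return(breath_events(ev$trig, ev$coff, kinds,
                         breath_id = signals$breath_id[on]))
  }
  flow <- signals$flow
  n <- length(flow)
  need <- max(1L, as.integer(round(sustain_s * hz)))
  trig <- integer(0); coff <- integer(0)
  k <- 2L
  while (k <= n) {
    if (flow[k] >= flow_threshold_lps && flow[k - 1L] < flow_threshold_lps) {
      hi <- min(n, k + need - 1L)
      if (all(flow[k:hi] >= flow_threshold_lps) && hi - k + 1L >= need) {
        j <- hi
        while (j < n && flow[j] >= 0) j <- j + 1L
        trig <- c(trig, k); coff <- c(coff, j)
        k <- j
      }
    }
    k <- k + 1L
  }
  if (!length(trig)) {
    warning("no ventilator cycle detectable in record")
    return(breath_events(numeric(0), numeric(0), character(0), integer(0)))
  }
  breath_events(signals$time[trig], signals$time[coff],
                rep("patient", length(trig)))
}
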