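# Noninvasive Pmus estimation by equation-of-motion inversion.
#
# With respiratory mechanics (R, C, P0) identified, muscle pressure follows
# directly from the single-compartment equation of motion:
#   Pmus_hat(t) = R_hat*flow(t) + volume(t)*1000/C_hat + P0_hat - Paw(t)
# re-zeroed per breath on its expiratory baseline, floored at zero (the
# stored-nonnegative display convention) and lightly smoothed.

#' Fit respiratory mechanics from passive breaths
#'
#' Ordinary least squares of `Paw = R*flow + volume*E + P0` over the samples
#' of the breaths flagged passive (machine-triggered with no effort). On an
#' effort-free record this identifies resistance, compliance and total PEEP.
#'
#' All channels receive an identical short moving-average filter before the
#' regression. Because the equation of motion is linear in the channels, the
#' filtered channels satisfy it exactly too, while noise on the flow
#' regressor (which would otherwise attenuate the resistance estimate,
#' a classical errors-in-variables bias) is strongly reduced.
#'
#' @param signals a `breath_signals` record.
#' @param passive_breath_ids integer breath ids known (or believed) to be
#'   passive; their inspiration and following expiration samples are used.
#' @param smooth_s pre-regression moving-average window (s), default 0.09.
#' @return object of class `mechanics_estimate`: `resistance_hat`
#'   (cmH2O·s/L), `compliance_hat` (mL/cmH2O), `peep_hat` (cmH2O),
#'   `fit_residual_rms` (cmH2O), `n_samples`.
#' @seealso [fit_mechanics_robust()] for records without known passive breaths.
#' @export
fit_mechanics <- function(signals, passive_breath_ids, smooth_s = 0.09) {
  stopifnot(inherits(signals, "breath_signals"))
  if (length(passive_breath_ids) < 1L) {
    stop("no passive breaths supplied; use fit_mechanics_robust() for a ",
         "full-record fit that down-weights effort-suspect samples")
  }
  keep <- signals$breath_id %in% as.integer(passive_breath_ids)
  if (!any(keep)) stop("passive_breath_ids not present in record")
  w <- max(1L, as.integer(round(smooth_s * attr(signals, "sampling_hz"))))
  dat <- data.frame(paw = moving_average(signals$paw, w),
                    flow = moving_average(signals$flow, w),
                    volume = moving_average(signals$volume, w))[keep, ]
  if (stats::sd(dat$flow) < 1e-8) {
    stop("record has no flow excitation: mechanics unidentifiable")
  }
  fit <- stats::lm(paw ~ flow + volume, data = dat)
  co <- stats::coef(fit)
  if (any(is.na(co)) || co[["flow"]] <= 0 || co[["volume"]] <= 0) {
    stop("mechanics fit is degenerate (nonpositive R or elastance)")
  }
  new_mechanics_estimate(co, fit, sum(keep))
}

new_mechanics_estimate <- function(co, fit, n) {
  structure(list(
    resistance_hat = unname(co[["flow"]]),
    compliance_hat = 1000 / unname(co[["volume"]]),
    peep_hat = unname(co[["(Intercept)"]]),
    fit_residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    n_samples = n
  ), class = "mechanics_estimate")
}

#' @export
print.mechanics_estimate <- function(x, ...) {
  cat(sprintf(
    "<mechanics_estimate> R = %.2f cmH2O.s/L, C = %.1f mL/cmH2O, PEEP = %.2f cmH2O (rms %.3f, n=%d)\n",
    x$resistance_hat, x$compliance_hat, x$peep_hat, x$fit_residual_rms,
    x$n_samples))
  invisible(x)
}

#' Robust full-record mechanics fit
#'
#' Mechanics identification for records in which an unknown subset of samples
#' carries patient effort, in two stages:
#'
#' 1. *Resistance, interrupter-style.* At ventilator phase transitions (most
#'    usefully cycle-off) the airway flow jumps between adjacent samples while
#'    volume and muscle pressure are continuous, so the equation of motion
#'    gives `R = d(paw)/d(flow)` across the jump. The median ratio over all
#'    transitions with a flow jump larger than `min_jump_lps` estimates R
#'    independently of effort.
#' 2. *Elastance and PEEP, asymmetric reweighting.* With R fixed,
#'    `paw - R*flow = E*volume + P0 - Pmus`; since effort only lowers the
#'    left side, samples with strongly negative residuals are effort-suspect
#'    and are down-weighted over a few reweighted least-squares passes,
#'    converging onto the passive upper envelope.
#'
#' Falls back to a three-parameter asymmetric reweighted fit of
#' `paw ~ flow + volume` when fewer than three usable transitions exist.
#'
#' @param signals a `breath_signals` record.
#' @param n_iter reweighting iterations (default 10).
#' @param effort_tol residual threshold (cmH2O) below which a sample is
#'   treated as effort-contaminated (default 0.3).
#' @param min_jump_lps minimum flow jump (L/s) for a usable transition.
#' @return a `mechanics_estimate`.
#' @export
fit_mechanics_robust <- function(signals, n_iter = 10L, effort_tol = 0.3,
                                 min_jump_lps = 0.2) {
  stopifnot(inherits(signals, "breath_signals"))
  if (stats::sd(signals$flow) < 1e-8) {
    stop("record has no flow excitation: mechanics unidentifiable")
  }
  n <- nrow(signals)
  ch <- which(signals$phase[-1L] != signals$phase[-n]) + 1L
  df <- signals$flow[ch] - signals$flow[ch - 1L]
  dp <- signals$paw[ch] - signals$paw[ch - 1L]
  ok <- abs(df) > min_jump_lps
  y <- signals$paw
  if (sum(ok) >= 3L) {
    Rhat <- stats::median(dp[ok] / df[ok])
    z <- y - Rhat * signals$flow
    X <- cbind(1, signals$volume)
    w <- rep(1, n)
    for (i in seq_len(n_iter)) {
      fit <- stats::lm.wfit(X, z, w)
      r <- as.vector(z - X %*% fit$coefficients)
      w <- ifelse(r < -effort_tol, 0.02, 1)
    }
    co <- c(unname(fit$coefficients[1L]), Rhat, unname(fit$coefficients[2L]))
  } else {
    X <- cbind(1, signals$flow, signals$volume)
    w <- rep(1, n)
    for (i in seq_len(n_iter)) {
      fit <- stats::lm.wfit(X, y, w)
      r <- as.vector(y - X %*% fit$coefficients)
      w <- ifelse(r < -effort_tol, 0.02, 1)
    }
    co <- unname(fit$coefficients)[c(1L, 2L, 3L)]
  }
  if (any(is.na(co)) || co[2L] <= 0 || co[3L] <= 0) {
    stop("robust mechanics fit is degenerate (nonpositive R or elastance)")
  }
  res <- (y - (co[1L] + co[2L] * signals$flow + co[3L] * signals$volume))[w > 0.5]
  structure(list(
    resistance_hat = co[2L],
    compliance_hat = 1000 / co[3L],
    peep_hat = co[1L],
    fit_residual_rms = sqrt(mean(res^2)),
    n_samples = sum(w > 0.5)
  ), class = "mechanics_estimate")
}

#' Convert true mechanics to a mechanics estimate
#'
#' @param mechanics a `respiratory_mechanics` object.
#' @return a `mechanics_estimate` carrying the true parameter values
#'   (zero residual), for oracle-supplied-mechanics estimation.
#' @export
as_mechanics_estimate <- function(mechanics) {
  stopifnot(inherits(mechanics, "respiratory_mechanics"))
  structure(list(resistance_hat = mechanics$resistance,
                 compliance_hat = mechanics$compliance,
                 peep_hat = mechanics$peep_total,
                 fit_residual_rms = 0, n_samples = NA_integer_),
            class = "mechanics_estimate")
}

moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Model-based Pmus estimation
#'
#' Inverts the single-compartment equation of motion with the supplied
#' mechanics estimate, re-zeroes the series on the median of the record's
#' expiratory baseline (robust to breaths whose expiration is filled by
#' effort, as in breath stacking), floors it at zero and applies a 50-ms
#' centered moving average.
#'
#' @param signals a `breath_signals` record.
#' @param mech a `mechanics_estimate` (or `respiratory_mechanics`, taken as
#'   the truth).
#' @param smooth_s moving-average window (s), default 0.05.
#' @return object of class `pmus_estimate`: list with `series` (cmH2O,
#'   aligned to the input grid), `method = "model_based"`, `mech`, and
#'   `rms_error_vs_gold` (cmH2O, `NA` when the record has no gold Pmus).
#' @export
estimate_pmus_model_based <- function(signals, mech, smooth_s = 0.05) {
  stopifnot(inherits(signals, "breath_signals"))
  if (inherits(mech, "respiratory_mechanics")) mech <- as_mechanics_estimate(mech)
  stopifnot(inherits(mech, "mechanics_estimate"),
            mech$resistance_hat > 0, mech$compliance_hat > 0)
  hz <- attr(signals, "sampling_hz")
  raw <- mech$resistance_hat * signals$flow +
    signals$volume * (1000 / mech$compliance_hat) +
    mech$peep_hat - signals$paw
  # expiratory-baseline re-zeroing over the whole record; a per-breath
  # baseline is badly biased when effort fills a breath's expiration
  expx <- signals$phase == "expiration"
  base <- stats::median(raw[if (any(expx)) expx else TRUE])
  ser <- pmax(raw - base, 0)
  ser <- moving_average(ser, max(1L, as.integer(round(smooth_s * hz))))
  rms <- if (all(is.na(signals$pmus_true))) NA_real_ else
    sqrt(mean((ser - signals$pmus_true)^2))
  structure(list(series = ser, method = "model_based", mech = mech,
                 rms_error_vs_gold = rms),
            class = "pmus_estimate")
}

#' @export
print.pmus_estimate <- function(x, ...) {
  cat(sprintf("<pmus_estimate> method=%s, %d samples, rms vs gold: %s cmH2O\n",
              x$method, length(x$series),
              if (is.na(x$rms_error_vs_gold)) "n/a" else
                sprintf("%.3f", x$rms_error_vs_gold)))
  invisible(x)
}

#' Evaluate a Pmus estimate against the gold series
#'
#' @param estimate estimated Pmus series (numeric, or a `pmus_estimate`).
#' @param gold gold Pmus series of the same length.
#' @param sampling_hz sampling rate (Hz).
#' @param threshold effort-onset detection threshold (cmH2O).
#' @return one-row data.frame: `rms_error` (cmH2O), `peak_amplitude_error`
#'   (mean over matched episodes, cmH2O), `onset_time_error_s` (mean detected
#'   onset minus gold onset over matched episodes), `n_efforts_gold`,
#'   `n_efforts_est`.
#' @export
evaluate_pmus_estimate <- function(estimate, gold, sampling_hz = 100,
                                   threshold = 0.5) {
  if (inherits(estimate, "pmus_estimate")) estimate <- estimate$series
  if (length(estimate) != length(gold)) {
    stop("estimate and gold series lengths differ")
  }
  rms <- sqrt(mean((estimate - gold)^2))
  ep_g <- detect_effort_episodes(gold, threshold, sampling_hz)
  ep_e <- detect_effort_episodes(estimate, threshold, sampling_hz)
  onset_err <- amp_err <- NA_real_
  if (nrow(ep_g) && nrow(ep_e)) {
    d_on <- numeric(0); d_amp <- numeric(0)
    for (i in seq_len(nrow(ep_g))) {
      j <- which.min(abs(ep_e$onset_time - ep_g$onset_time[i]))
      if (abs(ep_e$onset_time[j] - ep_g$onset_time[i]) <= 0.5) {
        d_on <- c(d_on, ep_e$onset_time[j] - ep_g$onset_time[i])
        d_amp <- c(d_amp, ep_e$peak_amplitude[j] - ep_g$peak_amplitude[i])
      }
    }
    if (length(d_on)) { onset_err <- mean(d_on); amp_err <- mean(d_amp) }
  }
  data.frame(rms_error = rms, peak_amplitude_error = amp_err,
             onset_time_error_s = onset_err,
             n_efforts_gold = nrow(ep_g), n_efforts_est = nrow(ep_e))
}

#' Per-scenario estimator evaluation over a battery
#'
#' Renders each scenario, estimates Pmus by the requested method, and
#' tabulates per-scenario error metrics plus the scenario label recovered
#' from the estimated Pmus.
#'
#' @param battery list of `pv_scenario` (default battery if omitted).
#' @param method `"model_based"` (equation-of-motion inversion with a robust
#'   full-record mechanics fit) or `"true_mech"` (inversion with the
#'   scenario's true mechanics).
#' @param seed render seed.
#' @param noise_sd render noise override (default 0 = noiseless).
#' @return data.frame with one row per scenario: metrics from
#'   [evaluate_pmus_estimate()], `label_gold`, `label_est`,
#'   `label_recovered`.
#' @export
evaluate_estimator <- function(battery = build_default_battery(),
                               method = c("model_based", "true_mech"),
                               seed = 1L, noise_sd = 0) {
  method <- match.arg(method)
  rows <- vector("list", length(battery))
  for (i in seq_along(battery)) {
    b <- battery[[i]]
    r <- render_scenario(b, seed = seed, noise_sd = noise_sd)
    mech <- if (method == "true_mech") as_mechanics_estimate(b$mechanics)
            else fit_mechanics_robust(r$signals)
    est <- estimate_pmus_model_based(r$signals, mech)
    met <- evaluate_pmus_estimate(est$series, r$signals$pmus_true,
                                  attr(r$signals, "sampling_hz"))
    lab <- label_scenario(r, "estimate", pmus_estimate = est$series)
    rows[[i]] <- cbind(scenario_id = b$scenario_id, met,
                       label_gold = b$injected_labels[1L],
                       label_est = lab$primary,
                       label_recovered = lab$primary == b$injected_labels[1L])
  }
  do.call(rbind, rows)
}
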