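# Rater-trial statistics: stratified randomization, answer-key scoring into
# sensitivity/specificity, normality-gated two-group comparison, two-sample
# t-test power and sample size, and a seeded rater-response simulator.

#' Stratified 1:1 randomization
#'
#' Permuted-block (block size 2) assignment within each stratum defined by
#' profession and experience, so per-stratum group sizes differ by at most 1.
#'
#' @param participants data.frame with columns `id`, `profession`
#'   (`"physician"` or `"respiratory_therapist"`), `experience`
#'   (`"<=5y"` or `">5y"`).
#' @param seed integer seed for the computer-generated random list.
#' @return the input with an added `group` column (`"control"` / `"pmus"`).
#' @export
allocate_stratified <- function(participants, seed = 1L) {
  stopifnot(all(c("id", "profession", "experience") %in% names(participants)),
            all(participants$profession %in% c("physician", "respiratory_therapist")),
            all(participants$experience %in% c("<=5y", ">5y")))
  set.seed(as.integer(seed))
  participants$group <- NA_character_
  strata <- split(seq_len(nrow(participants)),
                  interaction(participants$profession, participants$experience,
                              drop = TRUE))
  for (idx in strata) {
    idx <- idx[sample.int(length(idx))]        # random order within stratum
    nblocks <- ceiling(length(idx) / 2)
    g <- character(0)
    for (b in seq_len(nblocks)) {
      g <- c(g, sample(c("control", "pmus")))  # permuted block of 2
    }
    participants$group[idx] <- g[seq_along(idx)]
  }
  participants
}

#' Score rater responses against the answer key
#'
#' Per participant: sensitivity is the proportion of asynchronous scenarios
#' whose asynchrony type was identified exactly (the answered label equals the
#' key's primary label); specificity is the proportion of synchronous
#' scenarios called synchronous. The looser any-asynchrony sensitivity (any
#' non-synchronous answer on an asynchronous scenario counts) and per-type
#' sensitivities are also returned.
#'
#' @param responses data.frame with columns `participant_id`, `scenario_id`,
#'   `answered_label` (one of [asynchrony_labels()]); one row per
#'   (participant, scenario).
#' @param key answer key as from [answer_key()] (`scenario_id`,
#'   `primary_label`).
#' @return list with `performance` (data.frame per participant: `sensitivity`,
#'   `sensitivity_any`, `specificity`, `n_async`, `n_sync`, `complete`) and
#'   `per_type` (data.frame per participant x asynchrony type: `n_scenarios`,
#'   `n_correct`, `sensitivity`). Participants with missing responses are
#'   flagged `complete = FALSE` with a warning.
#' @export
score_responses <- function(responses, key) {
  stopifnot(all(c("participant_id", "scenario_id", "answered_label") %in%
                  names(responses)),
            all(c("scenario_id", "primary_label") %in% names(key)),
            all(responses$answered_label %in% ASYNC_LABELS))
  if (anyDuplicated(responses[c("participant_id", "scenario_id")])) {
    stop("duplicate (participant, scenario) responses")
  }
  key_lab <- key$primary_label[match(responses$scenario_id, key$scenario_id)]
  if (anyNA(key_lab)) stop("responses reference scenarios absent from the key")
  responses$key_label <- key_lab
  async_types <- setdiff(ASYNC_LABELS, "synchronous")
  n_scen <- nrow(key)

  perf <- list(); per_type <- list()
  for (pid in unique(responses$participant_id)) {
    rp <- responses[responses$participant_id == pid, ]
    complete <- nrow(rp) == n_scen &&
      all(sort(rp$scenario_id) == sort(key$scenario_id))
    if (!complete) {
      warning("participant ", pid, " has an incomplete response set; flagged")
    }
    asy <- rp$key_label != "synchronous"
    sens <- if (any(asy)) mean(rp$answered_label[asy] == rp$key_label[asy]) else NA_real_
    sens_any <- if (any(asy)) mean(rp$answered_label[asy] != "synchronous") else NA_real_
    spec <- if (any(!asy)) mean(rp$answered_label[!asy] == "synchronous") else NA_real_
    perf[[length(perf) + 1L]] <- data.frame(
      participant_id = pid, sensitivity = sens, sensitivity_any = sens_any,
      specificity = spec, n_async = sum(asy), n_sync = sum(!asy),
      complete = complete)
    for (ty in async_types) {
      sel <- rp$key_label == ty
      per_type[[length(per_type) + 1L]] <- data.frame(
        participant_id = pid, type = ty, n_scenarios = sum(sel),
        n_correct = sum(rp$answered_label[sel] == ty),
        sensitivity = if (any(sel)) mean(rp$answered_label[sel] == ty) else NA_real_)
    }
  }
  list(performance = do.call(rbind, perf), per_type = do.call(rbind, per_type))
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on each group at alpha 0.05; when both are consistent with
#' normality the groups are compared with a two-sample t test (Welch by
#' default) and described as mean (sd), otherwise with the Mann-Whitney test
#' and described as median (IQR).
#'
#' @param x,y numeric vectors (e.g. per-participant sensitivities of the two
#'   groups), at least 3 each.
#' @param pooled_var use the pooled-variance (classical Student) t test
#'   instead of Welch.
#' @param alpha significance level for reporting (default 0.05).
#' @return object of class `group_comparison`: `test_used` (`"student_t"` or
#'   `"mann_whitney"`), `p_value`, `significant`, `estimate_x`, `estimate_y`
#'   (mean or median), `spread_x`, `spread_y` (sd or IQR), `normal_x`,
#'   `normal_y`.
#' @export
compare_groups <- function(x, y, pooled_var = FALSE, alpha = 0.05) {
  stopifnot(length(x) >= 3L, length(y) >= 3L)
  norm <- function(v) {
    if (stats::sd(v) < .Machine$double.eps^0.5) return(FALSE) # degenerate: ties
    stats::shapiro.test(v)$p.value >= 0.05
  }
  nx <- norm(x); ny <- norm(y)
  if (nx && ny) {
    ht <- stats::t.test(x, y, var.equal = pooled_var)
    out <- list(test_used = "student_t", p_value = ht$p.value,
                estimate_x = mean(x), estimate_y = mean(y),
                spread_x = stats::sd(x), spread_y = stats::sd(y))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    out <- list(test_used = "mann_whitney", p_value = ht$p.value,
                estimate_x = stats::median(x), estimate_y = stats::median(y),
                spread_x = stats::IQR(x), spread_y = stats::IQR(y))
  }
  out$significant <- out$p_value < alpha
  out$normal_x <- nx; out$normal_y <- ny
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %.3g (%.3g) vs %.3g (%.3g), p = %.4g%s\n",
              x$test_used, x$estimate_x, x$spread_x, x$estimate_y, x$spread_y,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-sample t-test power at a given sample size
#'
#' Exact power via the noncentral t distribution for a two-sided two-sample
#' t test with equal group sizes.
#'
#' @param n per-group sample size.
#' @param delta true difference in means (same units as `sd`).
#' @param sd common standard deviation.
#' @param alpha two-sided significance level.
#' @return power in `[0, 1]`.
#' @export
power_two_t <- function(n, delta, sd, alpha = 0.05) {
  stopifnot(n >= 2, delta > 0, sd > 0, alpha > 0, alpha < 1)
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Required sample size for a two-sample comparison of means
#'
#' Smallest integer per-group n whose two-sided two-sample t-test power
#' reaches the target, found by iterating the noncentral-t power calculation.
#'
#' @param delta_pp difference to detect (e.g. percentage points), `> 0`.
#' @param sd_pp assumed common standard deviation (same units), `> 0`.
#' @param power target power, in (0, 1).
#' @param alpha two-sided significance level, in (0, 1).
#' @return list with `n_per_group`, `n_total`, `achieved_power`.
#' @examples
#' required_sample_size(10, 15, 0.90, 0.05) # 49 per group, 98 total
#' @export
required_sample_size <- function(delta_pp, sd_pp, power = 0.90, alpha = 0.05) {
  stopifnot(delta_pp > 0, sd_pp > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  n <- 2L
  while (power_two_t(n, delta_pp, sd_pp, alpha) < power) {
    n <- n + 1L
    if (n > 1e6) stop("unattainable design inputs")
  }
  list(n_per_group = n, n_total = 2L * n,
       achieved_power = power_two_t(n, delta_pp, sd_pp, alpha))
}

#' Simulate rater responses against a battery answer key
#'
#' Fixture generator: per scenario, a Bernoulli draw at the rater's
#' sensitivity (asynchronous scenarios; per-type values may be supplied) or
#' specificity (synchronous scenarios) decides whether the answer is correct;
#' incorrect answers are drawn from a confusion distribution over the other
#' labels.
#'
#' @param key answer key as from [answer_key()].
#' @param participant_id id recorded in the output.
#' @param sensitivity scalar or named vector (by asynchrony type) probability
#'   of answering an asynchronous scenario with its exact key label.
#' @param specificity probability of calling a synchronous scenario
#'   synchronous.
#' @param confusion optional named probability vector over labels used for
#'   incorrect answers (renormalized after removing the key label); default
#'   uniform over the other seven labels.
#' @param seed integer seed.
#' @return data.frame with `participant_id`, `scenario_id`, `answered_label`.
#' @export
simulate_rater_responses <- function(key, participant_id = 1L,
                                     sensitivity = 0.6, specificity = 0.9,
                                     confusion = NULL, seed = 1L) {
  stopifnot(all(sensitivity >= 0), all(sensitivity <= 1),
            specificity >= 0, specificity <= 1)
  set.seed(as.integer(seed))
  if (is.null(confusion)) {
    confusion <- stats::setNames(rep(1, length(ASYNC_LABELS)), ASYNC_LABELS)
  }
  ans <- character(nrow(key))
  for (i in seq_len(nrow(key))) {
    truth <- key$primary_label[i]
    p_ok <- if (truth == "synchronous") specificity else if
      (length(sensitivity) > 1L) sensitivity[[truth]] else sensitivity
    if (stats::runif(1) < p_ok) {
      ans[i] <- truth
    } else {
      alt <- confusion[names(confusion) != truth]
      ans[i] <- sample(names(alt), 1L, prob = alt)
    }
  }
  data.frame(participant_id = participant_id, scenario_id = key$scenario_id,
             answered_label = ans)
}
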