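test_that("stratified allocation of 98 balanced participants gives 49 per group", {
  a <- allocate_stratified(balanced_participants(), seed = 1)
  expect_equal(unname(table(a$group)["control"]), 49L)
  expect_equal(unname(table(a$group)["pmus"]), 49L)
  # per-stratum imbalance at most 1 for arbitrary (odd) strata too
  p <- data.frame(id = 1:31,
                  profession = sample(c("physician", "respiratory_therapist"), 31, TRUE),
                  experience = sample(c("<=5y", ">5y"), 31, TRUE))
  a2 <- allocate_stratified(p, seed = 2)
  tab <- table(a2$group, interaction(a2$profession, a2$experience, drop = TRUE))
  expect_true(all(abs(tab["control", ] - tab["pmus", ]) <= 1))
  # single participant: one group of one, one of zero
  a3 <- allocate_stratified(p[1, ], seed = 3)
  expect_true(a3$group %in% c("control", "pmus"))
  # same seed reproduces the allocation
  expect_identical(allocate_stratified(balanced_participants(), seed = 9),
                   allocate_stratified(balanced_participants(), seed = 9))
})

test_that("scoring matches the brute-force confusion tally and the forced arithmetic", {
  key <- answer_key()
  # perfect rater
  perfect <- simulate_rater_responses(key, 1, sensitivity = 1, specificity = 1,
                                      seed = 1)
  sc <- score_responses(perfect, key)
  expect_equal(sc$performance$sensitivity, 1)
  expect_equal(sc$performance$specificity, 1)
  # imperfect raters against the oracle
  resp <- do.call(rbind, lapply(1:8, function(i)
    simulate_rater_responses(key, i, sensitivity = 0.6, specificity = 0.8,
                             seed = 100 + i)))
  got <- score_responses(resp, key)$performance
  want <- oracle_score(resp, key)
  expect_equal(got$sensitivity, want$sensitivity)
  expect_equal(got$specificity, want$specificity)
  # 30 of 40 asynchronous scenarios correctly typed -> 0.75
  k2 <- data.frame(scenario_id = 1:41,
                   primary_label = c(rep("ineffective_effort", 40), "synchronous"))
  r2 <- data.frame(participant_id = 1, scenario_id = 1:41,
                   answered_label = c(rep("ineffective_effort", 30),
                                      rep("auto_triggering", 10), "synchronous"))
  expect_equal(score_responses(r2, k2)$performance$sensitivity, 0.75)
  # a wrong-type answer counts against both types' tallies
  pt <- score_responses(r2, k2)$per_type
  expect_equal(pt$n_correct[pt$type == "ineffective_effort"], 30)
  expect_equal(pt$n_correct[pt$type == "auto_triggering"], 0)
})

test_that("missing responses flag the participant with a warning", {
  key <- answer_key()
  resp <- simulate_rater_responses(key, 1, 0.8, 0.9, seed = 2)[-5, ]
  expect_warning(sc <- score_responses(resp, key), "incomplete")
  expect_false(sc$performance$complete)
})

test_that("the rater simulator is calibrated and seeded", {
  key <- answer_key()
  resp <- do.call(rbind, lapply(1:400, function(i)
    simulate_rater_responses(key, i, sensitivity = 0.6, specificity = 0.9,
                             seed = i)))
  perf <- score_responses(resp, key)$performance
  expect_equal(mean(perf$sensitivity), 0.6, tolerance = 0.02)
  expect_equal(mean(perf$specificity), 0.9, tolerance = 0.03)
  expect_identical(simulate_rater_responses(key, 1, 0.6, 0.9, seed = 7),
                   simulate_rater_responses(key, 1, 0.6, 0.9, seed = 7))
})

test_that("the normality gate picks the documented test and reporting", {
  set.seed(21)
  x <- rnorm(49, 0.66, 0.15)
  # identical groups: t test, p = 1, zero difference
  same <- compare_groups(x, x)
  expect_equal(same$test_used, "student_t")
  expect_equal(same$p_value, 1)
  expect_equal(same$estimate_x - same$estimate_y, 0)
  # normal vs normal with a real difference
  y <- rnorm(49, 0.53, 0.15)
  gc <- compare_groups(x, y)
  expect_equal(gc$test_used, "student_t")
  expect_true(gc$significant)
  # heavily skewed data fall back to Mann-Whitney with median/IQR
  ys <- rexp(49, 3)^2
  gs <- compare_groups(x, ys)
  expect_equal(gs$test_used, "mann_whitney")
  expect_equal(gs$estimate_y, median(ys))
})

test_that("rejection rate at the design assumptions reaches the planned power", {
  set.seed(31)
  rej <- mean(replicate(1000, {
    stats::t.test(rnorm(49, 0.66, 0.15), rnorm(49, 0.53, 0.15))$p.value < 0.05
  }))
  expect_gte(rej, 0.9)
})

test_that("required_sample_size reproduces the design and is monotone", {
  ss <- required_sample_size(10, 15, 0.90, 0.05)
  expect_equal(ss$n_per_group, 49L)
  expect_equal(ss$n_total, 98L)
  expect_gte(ss$achieved_power, 0.90)
  expect_lte(required_sample_size(30, 15, 0.90, 0.05)$n_per_group, 8)
  # agrees with the stats::power.t.test oracle over a grid
  for (delta in c(5, 10, 20)) {
    for (sd in c(10, 15)) {
      want <- ceiling(stats::power.t.test(delta = delta, sd = sd, power = 0.9,
                                          sig.level = 0.05)$n)
      expect_equal(required_sample_size(delta, sd, 0.9, 0.05)$n_per_group,
                   want, info = paste(delta, sd))
    }
  }
  # monotone: non-increasing in delta, non-decreasing in sd and power
  n_by_delta <- vapply(c(5, 8, 12, 20), function(d)
    required_sample_size(d, 15, 0.9, 0.05)$n_per_group, integer(1))
  expect_true(all(diff(n_by_delta) <= 0))
  n_by_sd <- vapply(c(8, 12, 18), function(s)
    required_sample_size(10, s, 0.9, 0.05)$n_per_group, integer(1))
  expect_true(all(diff(n_by_sd) >= 0))
  n_by_pow <- vapply(c(0.7, 0.8, 0.9, 0.95), function(p)
    required_sample_size(10, 15, p, 0.05)$n_per_group, integer(1))
  expect_true(all(diff(n_by_pow) >= 0))
  expect_error(required_sample_size(-1, 15), "delta")
})
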