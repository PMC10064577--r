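test_that("association pairs triggers to efforts within the window", {
  eff <- effort_episodes(5.0, 5.4, 8, 5.8)
  # trigger 80 ms after onset -> paired
  ev <- breath_events(5.08, 6.0, "patient")
  p <- associate_efforts(eff, ev)
  expect_equal(p$effort_id, 1L)
  expect_equal(p$trigger_delay_s, 0.08)
  # trigger 2 s after effort end -> unpaired
  ev2 <- breath_events(7.8, 8.8, "patient")
  expect_true(is.na(associate_efforts(eff, ev2)$effort_id))
  # one long effort spanning two triggers -> both paired (stacking)
  eff3 <- effort_episodes(5.0, 5.8, 10, 6.6)
  ev3 <- breath_events(c(5.05, 5.9), c(5.7, 6.6), c("patient", "patient"))
  expect_equal(associate_efforts(eff3, ev3)$effort_id, c(1L, 1L))
})

test_that("the labeler applies the definitions rule by rule", {
  # synchronous: trigger at onset+0.08, cycle-off between peak and end
  eff <- effort_episodes(5.0, 5.5, 8, 6.0)
  ev <- breath_events(5.08, 5.8, "patient")
  lb <- label_breaths(ev, efforts = eff)
  expect_equal(lb$breaths$label, "synchronous")
  expect_equal(nrow(lb$unpaired_efforts), 0)
  # premature cycling: cycle-off at 0.9 s, gold peak at 1.2 s
  eff2 <- effort_episodes(0.5, 1.2, 8, 1.9)
  ev2 <- breath_events(0.55, 0.9, "patient")
  expect_equal(label_breaths(ev2, efforts = eff2)$breaths$label,
               "premature_cycling")
  # delayed cycling: cycle-off > effort end + 0.1 s grace
  ev3 <- breath_events(0.55, 2.2, "patient")
  expect_equal(label_breaths(ev3, efforts = eff2)$breaths$label,
               "delayed_cycling")
  # ineffective effort: no trigger anywhere near
  ev4 <- breath_events(10, 11, "machine")
  lb4 <- label_breaths(ev4, efforts = eff2)
  expect_equal(lb4$unpaired_efforts$label, "ineffective_effort")
  expect_equal(lb4$breaths$label, "synchronous")
  # auto-triggering: patient-kind trigger with no effort at all
  lb5 <- label_breaths(breath_events(3, 4, "patient"),
                       efforts = effort_episodes(numeric(0), numeric(0),
                                                 numeric(0), numeric(0)))
  expect_equal(lb5$breaths$label, "auto_triggering")
  # double triggering: one effort, two patient-triggered stacked breaths
  eff6 <- effort_episodes(1.0, 1.8, 12, 2.6)
  ev6 <- breath_events(c(1.05, 1.9), c(1.6, 2.5), c("patient", "patient"))
  expect_equal(label_breaths(ev6, efforts = eff6)$breaths$label,
               rep("double_triggering", 2))
})

test_that("reverse triggering requires a stable delay across three machine breaths", {
  # three machine breaths, efforts following at +0.30 +/- 0.01 s
  trig <- c(2, 7, 12)
  eff <- effort_episodes(trig + c(0.30, 0.31, 0.29), trig + 0.7, 6, trig + 1.1)
  ev <- breath_events(trig, trig + 1.0, rep("machine", 3))
  lb <- label_breaths(ev, efforts = eff)
  expect_equal(lb$breaths$label, rep("reverse_triggering", 3))
  # unstable delays do not entrain
  eff2 <- effort_episodes(trig + c(0.1, 0.5, 0.9), trig + c(0.5, 0.9, 1.3), 6,
                          trig + c(0.9, 1.3, 1.7))
  lb2 <- label_breaths(ev, efforts = eff2)
  expect_false(any(lb2$breaths$label == "reverse_triggering"))
  # stacked second breath upgrades to the double-cycling variant
  trig3 <- c(2, 7, 12)
  eff3 <- effort_episodes(trig3 + 0.5, trig3 + 1.1, 12, trig3 + 1.7)
  ev3 <- breath_events(sort(c(trig3, trig3 + 1.1)),
                       sort(c(trig3 + 1.0, trig3 + 1.8)),
                       rep(c("machine", "patient"), 3))
  lb3 <- label_breaths(ev3, efforts = eff3)
  expect_equal(sort(unique(lb3$breaths$label)),
               "reverse_triggering_double_cycling")
})

test_that("label_breaths matches the brute-force evaluator on random timelines", {
  for (seed in 1:40) {
    tl <- random_timeline(seed)
    if (nrow(tl$events) == 0 && nrow(tl$efforts) == 0) next
    got <- label_breaths(tl$events, efforts = tl$efforts)
    want <- oracle_labels(tl$efforts, tl$events)
    expect_equal(got$breaths$label, want$breath_labels,
                 info = paste("seed", seed))
    expect_equal(sort(got$unpaired_efforts$effort_id), sort(want$ineffective),
                 info = paste("seed", seed))
  }
})

test_that("scenario aggregation uses frequency then precedence", {
  expect_equal(scenario_label(rep("synchronous", 8))$primary, "synchronous")
  expect_equal(scenario_label(c(rep("synchronous", 6),
                                rep("ineffective_effort", 3)))$primary,
               "ineffective_effort")
  # tie between premature and delayed -> premature by rule-order precedence
  expect_equal(scenario_label(c("premature_cycling", "delayed_cycling"))$primary,
               "premature_cycling")
  expect_error(scenario_label(character(0)), "at least one")
})

test_that("labeling is deterministic", {
  tl <- random_timeline(11)
  a <- label_breaths(tl$events, efforts = tl$efforts)
  b <- label_breaths(tl$events, efforts = tl$efforts)
  expect_identical(a, b)
})
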