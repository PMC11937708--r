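test_that("the generator is deterministic given a seed", {
  cfg <- generator_config("B_RCT",
    seed = 123,
    n_per_arm = c(intervention = 15L, control = 15L)
  )
  ch1 <- generate_cohort(cfg)
  ch2 <- generate_cohort(cfg)
  expect_equal(ch1$patients, ch2$patients)
  expect_equal(ch1$events, ch2$events)
  ch3 <- generate_cohort(cfg, seed = 124)
  expect_false(identical(ch1$events, ch3$events))
})

test_that("generated values respect their domains across seeds", {
  for (s in c(1, 2, 3)) {
    for (tr in c("B_RCT", "P_RCT")) {
      cfg <- generator_config(tr,
        seed = s, mode = "item_level",
        n_per_arm = c(intervention = 10L, control = 10L)
      )
      ch <- generate_cohort(cfg)
      expect_true(all(ch$events$cost_sek_2019 >= 0))
      win <- trial_spec(tr)$followup_window_days
      expect_true(all(ch$events$day_offset >= 0 & ch$events$day_offset < win))
      score_cols <- c(
        paste0("baseline_", qlq_dimensions()$dimension),
        paste0("followup_", qlq_dimensions()$dimension)
      )
      scores <- unlist(ch$patients[score_cols])
      expect_true(all(scores >= 0 & scores <= 100))
      expect_true(all(ch$patients$treatment_weeks > 0))
      if (tr == "P_RCT") {
        expect_true(any(ch$events$is_rt_fraction))
        expect_true(all(is.na(ch$patients$nact_cycles)))
      } else {
        expect_false(any(ch$events$is_rt_fraction))
        expect_true(all(ch$patients$nact_cycles >= 1))
      }
    }
  }
})

test_that("equal change means across arms give a null arm effect", {
  # with identical change distributions a two-sample t test on the EQ-5DP
  # change should reject at alpha = 0.01 only rarely
  n_seeds <- 200
  rejections <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- generator_config("B_RCT",
      seed = 1000 + s,
      n_per_arm = c(intervention = 40L, control = 40L),
      utility_change_mean = c(intervention = -0.04, control = -0.04),
      event_rate_outpatient = c(intervention = 0, control = 0),
      event_rate_inpatient = c(intervention = 0, control = 0)
    )
    ch <- generate_cohort(cfg)
    chg <- ch$patients$eq5dp_followup - ch$patients$eq5dp_baseline
    p <- stats::t.test(chg[ch$patients$arm == "intervention"],
      chg[ch$patients$arm == "control"]
    )$p.value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections / n_seeds, 0.05)
})

test_that("direct mode recovers configured arm utility means within 3 SE", {
  cfg <- generator_config("B_RCT", seed = 7)
  ch <- generate_cohort(cfg)
  for (a in c("intervention", "control")) {
    u0 <- ch$patients$eq5dp_baseline[ch$patients$arm == a]
    se <- sd(u0) / sqrt(length(u0))
    expect_lt(abs(mean(u0) - cfg$utility_baseline_mean[[a]]), 3 * se + 0.01)
  }
})

test_that("item-level mode realizes target utilities through the mapping", {
  # away from the mapping's ceiling the mapped EQ-5DP mean should sit
  # within 3 SE of the configured mean
  cfg <- generator_config("B_RCT",
    seed = 21, mode = "item_level",
    n_per_arm = c(intervention = 40L, control = 40L),
    utility_baseline_mean = c(intervention = 0.7, control = 0.7),
    utility_baseline_sd = c(intervention = 0.05, control = 0.05),
    utility_change_mean = c(intervention = -0.05, control = -0.05),
    utility_change_sd = c(intervention = 0.02, control = 0.02),
    event_rate_outpatient = c(intervention = 0, control = 0),
    event_rate_inpatient = c(intervention = 0, control = 0)
  )
  ch <- generate_cohort(cfg)
  score_cols <- paste0("baseline_", qlq_dimensions()$dimension)
  scores <- stats::setNames(
    ch$patients[score_cols], qlq_dimensions()$dimension
  )
  u <- eq5dp(scores)
  se <- sd(u) / sqrt(length(u))
  expect_lt(abs(mean(u) - 0.7), 3 * se)
})

test_that("missingness injection blanks the configured counts exactly", {
  cfg <- generator_config("P_RCT", seed = 42)
  ch <- generate_cohort(cfg)
  chm <- inject_missingness(ch, cfg, seed = 11)
  log <- attr(chm, "missingness_log")
  fup <- log[log$field == "followup_qlq", ]
  expect_equal(fup$n_blanked[fup$arm == "intervention"], 15)
  expect_equal(fup$n_blanked[fup$arm == "control"], 20)
  base <- log[log$field == "baseline_qlq", ]
  expect_equal(sort(base$n_blanked), c(2, 2))
  cost <- log[log$field == "costs", ]
  expect_equal(cost$n_blanked[cost$arm == "intervention"], 2)
  # blanked follow-up rows are fully missing and flagged incomplete
  blanked <- chm$patients$patient_id %in% unlist(fup$patient_ids)
  expect_equal(sum(blanked), 35)
  expect_true(all(is.na(chm$patients$eq5dp_followup[blanked])))
  expect_false(any(chm$patients$completed_followup[blanked]))
})

test_that("zero and full missingness fractions are boundary-exact", {
  cfg0 <- generator_config("B_RCT",
    seed = 3,
    n_per_arm = c(intervention = 10L, control = 10L),
    missing_baseline_fraction = c(intervention = 0, control = 0),
    missing_followup_fraction = c(intervention = 0, control = 0),
    missing_cost_fraction = c(intervention = 0, control = 0)
  )
  ch <- generate_cohort(cfg0)
  chm <- inject_missingness(ch, cfg0, seed = 1)
  expect_equal(chm$patients, ch$patients)

  cfg1 <- generator_config("B_RCT",
    seed = 3,
    n_per_arm = c(intervention = 10L, control = 10L),
    missing_followup_fraction = c(intervention = 1, control = 1)
  )
  chm1 <- inject_missingness(generate_cohort(cfg1), cfg1, seed = 1)
  expect_true(all(is.na(chm1$patients$eq5dp_followup)))
})

test_that("generated cohorts round-trip through text files", {
  cfg <- generator_config("P_RCT",
    seed = 9,
    n_per_arm = c(intervention = 8L, control = 8L)
  )
  ch <- generate_cohort(cfg)
  pp <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, pp, ep)
  back <- read_cohort(pp, ep)
  expect_equal(
    as.data.frame(back$patients[names(ch$patients)]),
    as.data.frame(ch$patients)
  )
  expect_equal(as.data.frame(back$events), as.data.frame(ch$events))
})
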