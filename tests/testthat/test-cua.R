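test_that("group-mean imputation fills cells and preserves observed means", {
  d <- tibble::tibble(
    trial = "B_RCT",
    arm = rep(c("intervention", "control"), each = 3),
    u = c(0.8, 0.9, NA, 0.7, NA, 0.5)
  )
  out <- suppressWarnings(impute_group_means(d, "u"))
  expect_equal(out$u[3], 0.85)
  expect_equal(out$u[5], 0.6)
  # imputation preserves each cell's observed mean exactly
  expect_equal(mean(out$u[1:3]), 0.85)
  expect_equal(mean(out$u[4:6]), 0.6)
  log <- imputation_log(out)
  expect_equal(sum(log$n_missing), 2)

  # untouched data come back unchanged with an all-zero log
  clean <- tibble::tibble(trial = "B_RCT", arm = "control", u = c(1, 2))
  out2 <- impute_group_means(clean, "u")
  expect_equal(out2$u, clean$u)
  expect_equal(sum(imputation_log(out2)$n_missing), 0)
})

test_that("imputation warns above 10% cell missingness and errors on empty cells", {
  d <- tibble::tibble(
    trial = "P_RCT", arm = rep("intervention", 5),
    u = c(1, 2, 3, NA, NA)
  )
  expect_warning(impute_group_means(d, "u"), "10%")
  d_empty <- tibble::tibble(
    trial = "P_RCT", arm = rep("control", 2), u = c(NA_real_, NA_real_)
  )
  expect_error(
    impute_group_means(d_empty, "u"),
    class = "eprocua_imputation_error"
  )
})

test_that("two missing cost records are imputed at the arm mean", {
  pts <- direct_patients(10, 10)
  pts$costs_missing[c(1, 2)] <- TRUE
  ev <- tibble::tibble(
    patient_id = pts$patient_id[3:10],
    day_offset = 1L, setting = "outpatient", acute = FALSE,
    unplanned_admission = FALSE, icd_codes = "Z511",
    cost_sek_2019 = seq(1000, 8000, by = 1000), is_rt_fraction = FALSE
  )
  ch <- cohort(pts, ev)
  pc <- patient_costs(ch)
  joined <- dplyr::left_join(
    dplyr::select(ch$patients, "patient_id", "trial", "arm"),
    pc,
    by = "patient_id"
  )
  out <- suppressWarnings(impute_group_means(joined, c("total", "acute_total")))
  log <- imputation_log(out)
  tot_log <- log[log$field == "total" & log$arm == "intervention", ]
  expect_equal(tot_log$n_missing, 2)
  observed_mean <- mean(joined$total[joined$arm == "intervention"], na.rm = TRUE)
  expect_equal(out$total[1], observed_mean)
  expect_equal(out$total[2], observed_mean)
})

test_that("QALY loss matches the linear accrual formula", {
  expect_equal(qaly_loss(0.8, 0.8, 20), 0)
  expect_equal(qaly_loss(0.87, 0.80, 15), ((0.80 - 0.87) / 2) * (15 / 52))
  expect_lt(abs(qaly_loss(0.87, 0.80, 15) - (-0.010096)), 1e-6)
  expect_lt(abs(qaly_loss(0.86, 0.84, 15) - (-0.002885)), 1e-6)
  expect_error(qaly_loss(0.8, 0.7, 0), class = "eprocua_validation_error")
  expect_error(qaly_loss(0.8, 0.7, -2), class = "eprocua_validation_error")
})

test_that("ICER point estimates divide incremental cost by incremental QALY", {
  d <- cua_data(
    ig_cost = c(92, 92), ig_qaly = c(-0.004, -0.004),
    cg_cost = c(0, 0), cg_qaly = c(-0.0116, -0.0116)
  )
  res <- icer_point(d, "ICERc")
  expect_equal(res$incremental_cost, 92)
  expect_equal(res$incremental_qaly, 0.0076, tolerance = 1e-12)
  expect_equal(res$icer, 92 / 0.0076, tolerance = 1e-9)
  expect_equal(res$icer, 12105.26, tolerance = 1e-6)
  expect_equal(res$dominance, "tradeoff_NE")
})

test_that("dominance labels follow the sign quadrant", {
  lab <- function(ig_c, cg_c, ig_q, cg_q) {
    icer_point(cua_data(ig_c, ig_q, cg_c, cg_q), "ICERa")$dominance
  }
  expect_equal(lab(c(10, 10), c(60, 60), c(0.01, 0.01), c(0, 0)), "dominant")
  expect_equal(lab(c(60, 60), c(10, 10), c(0, 0), c(0.01, 0.01)), "dominated")
  expect_equal(lab(c(60, 60), c(10, 10), c(0.01, 0.01), c(0, 0)), "tradeoff_NE")
  expect_equal(lab(c(10, 10), c(60, 60), c(0, 0), c(0.01, 0.01)), "tradeoff_SW")
  # identical arms: zero increments, undefined ICER
  same <- icer_point(cua_data(c(5, 5), c(0.1, 0.1), c(5, 5), c(0.1, 0.1)), "ICERb")
  expect_false(same$icer_defined)
  expect_true(is.na(same$icer))
})

test_that("bootstrap with one patient per arm is degenerate", {
  d <- cua_data(100, 0.01, 50, 0.002)
  b <- bootstrap_icer(d, "ICERa", B = 50, seed = 1)
  expect_equal(unique(b$replicates$icer), b$point$icer)
  expect_equal(b$icer_sd, 0)
  expect_equal(b$n_excluded, 0)
  expect_error(bootstrap_icer(d, "ICERa", B = 0), class = "eprocua_validation_error")
})

test_that("bootstrap is reproducible and satisfies the ICER identity", {
  set.seed(4)
  d <- cua_data(
    ig_cost = rgamma(20, 2, scale = 50), ig_qaly = rnorm(20, -0.004, 0.002),
    cg_cost = rgamma(20, 2, scale = 45), cg_qaly = rnorm(20, -0.012, 0.002)
  )
  b1 <- bootstrap_icer(d, "ICERa", B = 200, seed = 99)
  b2 <- bootstrap_icer(d, "ICERa", B = 200, seed = 99)
  expect_equal(b1$replicates, b2$replicates)
  ok <- !is.na(b1$replicates$icer)
  expect_equal(
    b1$replicates$icer[ok] * b1$replicates$incremental_qaly[ok],
    b1$replicates$incremental_cost[ok],
    tolerance = 1e-9
  )
  expect_equal(b1$point$icer * b1$point$incremental_qaly,
    b1$point$incremental_cost,
    tolerance = 1e-9
  )
  expect_lte(b1$ci95[1], b1$ci95[2])
})

test_that("replicate means converge to the point estimate at large B", {
  set.seed(8)
  d <- cua_data(
    ig_cost = rgamma(30, 2, scale = 60), ig_qaly = rnorm(30, -0.005, 0.002),
    cg_cost = rgamma(30, 2, scale = 55), cg_qaly = rnorm(30, -0.011, 0.002)
  )
  b <- bootstrap_icer(d, "ICERa", B = 4000, seed = 5)
  for (col in c("incremental_cost", "incremental_qaly")) {
    reps <- b$replicates[[col]]
    mc_se <- sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - b$point[[col]]), 3 * mc_se)
  }
})

test_that("with constant costs all ICER variance comes from the QALYs", {
  set.seed(2)
  n <- 15
  d <- cua_data(
    ig_cost = rep(81.5, n), ig_qaly = rnorm(n, -0.004, 0.002),
    cg_cost = rep(0, n), cg_qaly = rnorm(n, -0.012, 0.002)
  )
  b <- bootstrap_icer(d, "ICERc", B = 300, seed = 10)
  expect_equal(sd(b$replicates$incremental_cost), 0)
  expect_gt(sd(b$replicates$incremental_qaly), 0)
})

test_that("NBHW classification respects band edges and dominance", {
  expect_equal(classify_icer(9685, "tradeoff_NE"), "low")
  expect_equal(classify_icer(9686, "tradeoff_NE"), "moderate")
  expect_equal(classify_icer(48423, "tradeoff_NE"), "moderate")
  expect_equal(classify_icer(50000, "tradeoff_NE"), "high")
  expect_equal(classify_icer(96846, "tradeoff_NE"), "high")
  expect_equal(classify_icer(200000, "tradeoff_NE"), "very high")
  expect_equal(classify_icer(-12000, "dominant"), "dominant")
  expect_equal(classify_icer(-12000, "dominated"), "dominated")
  expect_error(threshold_bands(10, 5, 20))
})

test_that("Cohen's d uses the pooled n-1 weighted SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(6)
  a <- rnorm(50, 1, 1)
  b <- rnorm(50, 0, 1)
  d <- cohens_d(a, b)
  sp <- sqrt((var(a) * 49 + var(b) * 49) / 98)
  expect_equal(d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(cohens_d(1, c(1, 2)), class = "eprocua_validation_error")
})

test_that("CE plane quadrant tallies are conserved", {
  set.seed(3)
  d <- cua_data(
    ig_cost = rnorm(10, 100, 50), ig_qaly = rnorm(10, 0, 0.005),
    cg_cost = rnorm(10, 100, 50), cg_qaly = rnorm(10, 0, 0.005)
  )
  b <- bootstrap_icer(d, "ICERa", B = 500, seed = 12)
  pts <- ce_plane_points(b)
  counts <- attr(pts, "quadrant_counts")
  expect_equal(sum(counts), 500)
  expect_equal(nrow(pts), 500)
  # all-NE input lands entirely in NE
  d_ne <- cua_data(
    ig_cost = c(200, 210), ig_qaly = c(0.02, 0.021),
    cg_cost = c(10, 11), cg_qaly = c(0.001, 0.0012)
  )
  b_ne <- bootstrap_icer(d_ne, "ICERa", B = 100, seed = 1)
  counts_ne <- attr(ce_plane_points(b_ne), "quadrant_counts")
  expect_equal(unname(counts_ne["NE"]), 100)
})

test_that("a cost-saving QALY-gaining truth fills the dominant quadrant", {
  set.seed(44)
  n <- 150
  d <- cua_data(
    ig_cost = rnorm(n, 800, 100), ig_qaly = rnorm(n, 0.012, 0.004),
    cg_cost = rnorm(n, 1000, 100), cg_qaly = rnorm(n, 0.002, 0.004)
  )
  b <- bootstrap_icer(d, "ICERa", B = 400, seed = 9)
  counts <- attr(ce_plane_points(b), "quadrant_counts")
  expect_gt(counts[["SE"]], 0.9 * 400)
})

test_that("the CUA table composes utilities, costs and QALY losses", {
  ch <- tiny_cohort()
  tbl <- cua_patient_table(ch)
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$eq5dp_before, c(0.86, 0.87))
  expect_equal(tbl$qaly_loss, qaly_loss(c(0.86, 0.87), c(0.84, 0.80), c(15, 16)))
  # control arm pays no intervention cost
  expect_equal(tbl$intervention_cost[tbl$arm == "control"], 0)
  expect_equal(
    tbl$intervention_cost[tbl$arm == "intervention"],
    intervention_cost(15, cost_model("B_RCT"))
  )
  expect_equal(tbl$cost_c, tbl$intervention_cost)
  expect_equal(tbl$cost_a, tbl$intervention_cost + tbl$total_cost)
  expect_equal(tbl$cost_b, tbl$intervention_cost + tbl$acute_cost)
})
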