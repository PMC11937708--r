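# In-code fixture builders shared across the suite.

empty_qlq_cols <- function(n) {
  cols <- c(
    paste0("baseline_", qlq_dimensions()$dimension),
    paste0("followup_", qlq_dimensions()$dimension)
  )
  out <- as.data.frame(matrix(NA_real_, nrow = n, ncol = length(cols)))
  names(out) <- cols
  out
}

# minimal two-patient / three-event cohort with direct utilities
tiny_cohort <- function() {
  patients <- dplyr::bind_cols(
    tibble::tibble(
      patient_id = c("P1", "P2"),
      trial = "B_RCT",
      arm = c("intervention", "control"),
      age_years = c(50, 55),
      charlson_score = c(0L, 1L),
      treatment_weeks = c(15, 16),
      nact_cycles = c(6L, 5L),
      completed_followup = TRUE,
      costs_missing = FALSE,
      eq5dp_baseline = c(0.86, 0.87),
      eq5dp_followup = c(0.84, 0.80)
    ),
    empty_qlq_cols(2)
  )
  events <- tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    day_offset = c(10L, 40L, 100L),
    setting = c("outpatient", "inpatient", "outpatient"),
    acute = c(FALSE, TRUE, TRUE),
    unplanned_admission = c(FALSE, TRUE, FALSE),
    icd_codes = c("Z511", "R502;D649", "N390"),
    cost_sek_2019 = c(1000, 50000, 2000),
    is_rt_fraction = FALSE
  )
  cohort(patients, events)
}

# direct-utility patient table sized n per arm, optionally with events
direct_patients <- function(n_int, n_ctrl, trial = "B_RCT",
                            u0_int = 0.86, u0_ctrl = 0.87,
                            u1_int = 0.84, u1_ctrl = 0.80,
                            weeks = 15) {
  n <- n_int + n_ctrl
  nact <- if (trial == "B_RCT") 6L else NA_integer_
  dplyr::bind_cols(
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      trial = trial,
      arm = rep(c("intervention", "control"), c(n_int, n_ctrl)),
      age_years = 60,
      charlson_score = 0L,
      treatment_weeks = weeks,
      nact_cycles = nact,
      completed_followup = TRUE,
      costs_missing = FALSE,
      eq5dp_baseline = rep(c(u0_int, u0_ctrl), c(n_int, n_ctrl)),
      eq5dp_followup = rep(c(u1_int, u1_ctrl), c(n_int, n_ctrl))
    ),
    empty_qlq_cols(n)
  )
}

empty_events <- function() {
  tibble::tibble(
    patient_id = character(0), day_offset = integer(0),
    setting = character(0), acute = logical(0),
    unplanned_admission = logical(0), icd_codes = character(0),
    cost_sek_2019 = numeric(0), is_rt_fraction = logical(0)
  )
}

# hand-assembled CUA analysis table (the bootstrap input contract)
cua_data <- function(ig_cost, ig_qaly, cg_cost, cg_qaly) {
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(length(ig_cost) + length(cg_cost))),
    arm = rep(c("intervention", "control"), c(length(ig_cost), length(cg_cost))),
    qaly_loss = c(ig_qaly, cg_qaly),
    cost_a = c(ig_cost, cg_cost),
    cost_b = c(ig_cost, cg_cost),
    cost_c = c(ig_cost, cg_cost)
  )
}

# Exhaustive enumeration oracle for the within-arm bootstrap: iterates all
# ordered index tuples (n^n per arm, each equally likely) and returns the
# exact expectations of the incremental cost, incremental QALY and ICER.
exact_bootstrap_moments <- function(ig_cost, ig_qaly, cg_cost, cg_qaly) {
  tuples <- function(n) {
    as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  }
  ig_t <- tuples(length(ig_cost))
  cg_t <- tuples(length(cg_cost))
  ig_means <- cbind(
    cost = rowMeans(matrix(ig_cost[ig_t], nrow(ig_t))),
    qaly = rowMeans(matrix(ig_qaly[ig_t], nrow(ig_t)))
  )
  cg_means <- cbind(
    cost = rowMeans(matrix(cg_cost[cg_t], nrow(cg_t))),
    qaly = rowMeans(matrix(cg_qaly[cg_t], nrow(cg_t)))
  )
  grid <- expand.grid(i = seq_len(nrow(ig_means)), j = seq_len(nrow(cg_means)))
  d_cost <- ig_means[grid$i, "cost"] - cg_means[grid$j, "cost"]
  d_qaly <- ig_means[grid$i, "qaly"] - cg_means[grid$j, "qaly"]
  icer <- d_cost / d_qaly
  list(
    mean_d_cost = mean(d_cost),
    mean_d_qaly = mean(d_qaly),
    mean_icer = mean(icer),
    sd_icer = stats::sd(icer)
  )
}

# per-patient utilization data simulated from a known count model
sim_util_data <- function(n, group_beta = 0, dispersion = 1, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(
    arm = rep(c("control", "intervention"), length.out = n),
    age_years = rnorm(n, 60, 10),
    charlson_score = rpois(n, 0.8),
    eq5dp_baseline = runif(n, 0.5, 1)
  )
  eta <- 0.3 + group_beta * (d$arm == "intervention")
  mu <- exp(eta)
  if (dispersion <= 1) {
    d$y <- rpois(n, mu)
  } else {
    # NB with variance = dispersion * mean: size = mu / (dispersion - 1)
    d$y <- stats::rnbinom(n, size = mu / (dispersion - 1), mu = mu)
  }
  d
}

# two-pass mean/SD oracle used against summarize_arm
two_pass_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)))
}
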