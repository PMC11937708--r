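arm_vec <- function(intervention, control) {
  c(intervention = intervention, control = control)
}

default_icd_pools <- function(trial) {
  if (trial == "B_RCT") {
    list(
      acute = tibble(
        code = c(
          "R502", "R508", "R509", "D709C", "K521", "A047",
          "D649", "N390", "R11", "J069"
        ),
        weight = c(0.25, 0.10, 0.10, 0.10, 0.08, 0.04, 0.08, 0.05, 0.10, 0.10)
      ),
      routine = tibble(
        code = c("Z511", "C509"),
        weight = c(0.7, 0.3)
      )
    )
  } else {
    list(
      acute = tibble(
        code = c(
          "R060", "I214", "N390", "R339", "N304", "R301",
          "D649", "K521", "R509", "T830", "J189"
        ),
        weight = c(0.15, 0.08, 0.15, 0.10, 0.08, 0.07, 0.07, 0.05, 0.10, 0.05, 0.10)
      ),
      routine = tibble(
        code = c("Z509", "C619"),
        weight = c(0.6, 0.4)
      )
    )
  }
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the two-arm RCT a synthetic cohort should emulate: arm sizes,
#' per-arm baseline utility and utility-change distributions, treatment
#' durations, per-setting care-event rates and acute mix, right-skewed
#' (gamma) event costs in 2019 SEK, ICD code pools, and per-arm missingness
#' fractions. Defaults are calibrated to the published arm summaries of the
#' breast-cancer (74/75 patients) and prostate-cancer (75/75) ePRO trials;
#' see the methods vignette for the calibration.
#'
#' @param trial `"B_RCT"` or `"P_RCT"`.
#' @param n_per_arm Named integer vector `c(intervention=, control=)`.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param mode `"direct"` (EQ-5DP utilities attached as precomputed
#'   columns; QLQ scores left empty) or `"item_level"` (QLQ dimension
#'   scores sampled so that their mapped EQ-5DP matches the sampled utility
#'   within `utility_tolerance`).
#' @param utility_baseline_mean,utility_baseline_sd Per-arm baseline EQ-5DP
#'   distribution, truncated to \[-0.594, 1\].
#' @param utility_change_mean,utility_change_sd Per-arm distribution of the
#'   pre-to-post utility change (negative = deterioration); the arm effect
#'   is the difference in change means.
#' @param treatment_weeks_mean,treatment_weeks_sd Per-arm weeks in
#'   treatment plus app-reporting tail (truncated at 1 week).
#' @param age_mean,age_sd,charlson_lambda,nact_lambda Covariate
#'   distributions (ages truncated to \[25, 95\]; `nact_lambda` ignored for
#'   P-RCT).
#' @param event_rate_outpatient,event_rate_inpatient Per-arm expected
#'   number of care contacts per patient over the follow-up window
#'   (Poisson). Outpatient excludes RT fractions.
#' @param acute_probability Named vector `c(outpatient=, inpatient=)`.
#' @param unplanned_admission_probability Probability that an acute
#'   inpatient episode is an unplanned admission.
#' @param cost_shape,cost_scale Named vectors `c(outpatient=, inpatient=)`
#'   of gamma parameters for per-event costs in 2019 SEK.
#' @param rt_fractions_per_week,rt_cost_shape,rt_cost_scale Radiotherapy
#'   fraction schedule and per-fraction gamma cost (P-RCT only; fractions
#'   are delivered over the treatment weeks minus the reporting tail).
#' @param icd_pools List with tibbles `acute` and `routine` (columns
#'   `code`, `weight`) to draw diagnosis codes from.
#' @param second_code_probability Probability an event carries a second
#'   ICD code.
#' @param missing_baseline_fraction,missing_followup_fraction,missing_cost_fraction
#'   Per-arm fractions in \[0, 1\] used by [inject_missingness()];
#'   `round(fraction * arm size)` patients are blanked without replacement,
#'   so configured counts are hit exactly.
#' @param utility_tolerance Item-level mode: maximum allowed gap between a
#'   patient's sampled utility and the mapped EQ-5DP of the sampled scores.
#' @param mapping_model,value_set Objects used by item-level mode (defaults:
#'   shipped fixtures).
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(trial = c("B_RCT", "P_RCT"),
                             n_per_arm = NULL,
                             seed = NULL,
                             mode = c("direct", "item_level"),
                             utility_baseline_mean = NULL,
                             utility_baseline_sd = NULL,
                             utility_change_mean = NULL,
                             utility_change_sd = NULL,
                             treatment_weeks_mean = NULL,
                             treatment_weeks_sd = NULL,
                             age_mean = NULL, age_sd = NULL,
                             charlson_lambda = NULL, nact_lambda = 5,
                             event_rate_outpatient = NULL,
                             event_rate_inpatient = NULL,
                             acute_probability = NULL,
                             unplanned_admission_probability = 0.7,
                             cost_shape = NULL, cost_scale = NULL,
                             rt_fractions_per_week = 5,
                             rt_cost_shape = 50, rt_cost_scale = 100,
                             icd_pools = NULL,
                             second_code_probability = 0.2,
                             missing_baseline_fraction = NULL,
                             missing_followup_fraction = NULL,
                             missing_cost_fraction = NULL,
                             utility_tolerance = 0.02,
                             mapping_model = NULL, value_set = NULL) {
  trial <- match.arg(trial)
  mode <- match.arg(mode)
  b <- trial == "B_RCT"
  cfg <- list(
    trial = trial,
    n_per_arm = n_per_arm %||% if (b) arm_vec(74L, 75L) else arm_vec(75L, 75L),
    seed = seed,
    mode = mode,
    utility_baseline_mean = utility_baseline_mean %||%
      if (b) arm_vec(0.86, 0.87) else arm_vec(0.88, 0.89),
    utility_baseline_sd = utility_baseline_sd %||%
      if (b) arm_vec(0.12, 0.12) else arm_vec(0.10, 0.10),
    utility_change_mean = utility_change_mean %||%
      if (b) arm_vec(-0.02, -0.07) else arm_vec(-0.01, -0.01),
    utility_change_sd = utility_change_sd %||%
      if (b) arm_vec(0.10, 0.10) else arm_vec(0.04, 0.04),
    treatment_weeks_mean = treatment_weeks_mean %||%
      if (b) arm_vec(17, 17) else arm_vec(8, 8),
    treatment_weeks_sd = treatment_weeks_sd %||%
      if (b) arm_vec(2, 2) else arm_vec(0.5, 0.5),
    age_mean = age_mean %||% if (b) 52 else 70,
    age_sd = age_sd %||% if (b) 11 else 7,
    charlson_lambda = charlson_lambda %||% if (b) 0.5 else 1.0,
    nact_lambda = nact_lambda,
    event_rate_outpatient = event_rate_outpatient %||%
      if (b) arm_vec(35, 35) else arm_vec(8, 8),
    event_rate_inpatient = event_rate_inpatient %||%
      if (b) arm_vec(1.5, 1.5) else arm_vec(0.2, 0.2),
    acute_probability = acute_probability %||%
      if (b) c(outpatient = 0.03, inpatient = 0.35) else c(outpatient = 0.06, inpatient = 0.8),
    unplanned_admission_probability = unplanned_admission_probability,
    cost_shape = cost_shape %||%
      if (b) c(outpatient = 2, inpatient = 1.5) else c(outpatient = 1.2, inpatient = 0.8),
    cost_scale = cost_scale %||%
      if (b) c(outpatient = 3800, inpatient = 39000) else c(outpatient = 2080, inpatient = 62500),
    rt_fractions_per_week = rt_fractions_per_week,
    rt_cost_shape = rt_cost_shape,
    rt_cost_scale = rt_cost_scale,
    icd_pools = icd_pools %||% default_icd_pools(trial),
    second_code_probability = second_code_probability,
    missing_baseline_fraction = missing_baseline_fraction %||%
      if (b) arm_vec(0, 0) else arm_vec(2 / 75, 2 / 75),
    missing_followup_fraction = missing_followup_fraction %||%
      if (b) arm_vec(5 / 74, 4 / 75) else arm_vec(15 / 75, 20 / 75),
    missing_cost_fraction = missing_cost_fraction %||%
      if (b) arm_vec(2 / 74, 0) else arm_vec(2 / 75, 0),
    utility_tolerance = utility_tolerance,
    mapping_model = mapping_model,
    value_set = value_set
  )
  # YAML/JSON configs deliver lists (possibly unnamed) where named vectors
  # are expected; normalize to named vectors keyed by arm or setting
  normalize_pair <- function(x, keys) {
    x <- unlist(x)
    if (length(x) == 1 && is.null(names(x))) x <- rep(x, 2)
    if (is.null(names(x)) && length(x) == length(keys)) names(x) <- keys
    missing_k <- setdiff(keys, names(x))
    if (length(missing_k)) {
      abort(
        paste0("config vector lacks entries for: ", paste(missing_k, collapse = ", ")),
        class = "eprocua_config_error"
      )
    }
    x
  }
  arm_fields <- c(
    "n_per_arm", "utility_baseline_mean", "utility_baseline_sd",
    "utility_change_mean", "utility_change_sd", "treatment_weeks_mean",
    "treatment_weeks_sd", "event_rate_outpatient", "event_rate_inpatient",
    "missing_baseline_fraction", "missing_followup_fraction",
    "missing_cost_fraction"
  )
  for (f in arm_fields) cfg[[f]] <- normalize_pair(cfg[[f]], arm_levels())
  setting_fields <- c("acute_probability", "cost_shape", "cost_scale")
  for (f in setting_fields) {
    cfg[[f]] <- normalize_pair(cfg[[f]], c("outpatient", "inpatient"))
  }
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (any(cfg$n_per_arm < 1)) {
    abort("n_per_arm must be positive in both arms.", class = "eprocua_config_error")
  }
  fracs <- c(
    cfg$missing_baseline_fraction, cfg$missing_followup_fraction,
    cfg$missing_cost_fraction, cfg$acute_probability,
    cfg$second_code_probability, cfg$unplanned_admission_probability
  )
  if (any(fracs < 0 | fracs > 1)) {
    abort("fractions/probabilities must lie in [0, 1].", class = "eprocua_config_error")
  }
  if (any(c(cfg$cost_shape, cfg$cost_scale) <= 0)) {
    abort("gamma cost parameters must be > 0.", class = "eprocua_config_error")
  }
  if (any(cfg$utility_baseline_mean < -0.594 | cfg$utility_baseline_mean > 1)) {
    abort("baseline utility means must lie in [-0.594, 1].", class = "eprocua_config_error")
  }
  invisible(TRUE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# severity in [0, 1] -> QLQ-C30 profile (0 = best health, 1 = worst)
severity_profile <- function(s) {
  dims <- qlq_dimensions()
  out <- purrr::map2(dims$dimension, dims$type, function(d, ty) {
    if (ty == "symptom") 100 * s else 100 * (1 - s)
  })
  as_tibble(setNames(out, dims$dimension))
}

severity_curve <- function(model, values, n_grid = 201) {
  s <- seq(0, 1, length.out = n_grid)
  u <- eq5dp(severity_profile(s), model, values)
  list(s = s, u = u)
}

scores_for_utility <- function(target, model, values, tolerance = 0.02,
                               jitter = 2) {
  curve <- severity_curve(model, values)
  tgt <- clamp(target, min(curve$u), max(curve$u))
  # u(s) is monotone decreasing in severity; invert on the reversed grid
  # so approx() sees ascending x
  s_hat <- approx(rev(curve$u), rev(curve$s), xout = tgt, ties = "ordered")$y
  clean <- severity_profile(s_hat)
  noisy <- clean |>
    mutate(across(everything(), ~ clamp(.x + runif(dplyr::n(), -jitter, jitter), 0, 100)))
  u_noisy <- eq5dp(noisy, model, values)
  ok <- abs(u_noisy - tgt) <= tolerance
  out <- noisy
  out[!ok, ] <- clean[!ok, ]
  out
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  clamp(rnorm(n, mean, sd), lo, hi)
}

sample_codes <- function(n, pool, second_p) {
  if (n == 0) {
    return(character(0))
  }
  first <- sample(pool$code, n, replace = TRUE, prob = pool$weight)
  extra <- runif(n) < second_p
  second <- sample(pool$code, n, replace = TRUE, prob = pool$weight)
  ifelse(extra & second != first, paste(first, second, sep = ";"), first)
}

#' Generate a synthetic two-arm trial cohort
#'
#' Draws a complete cohort (patients and care events) from a
#' [generator_config()]. Given the same config and seed, the output is
#' identical across runs and platforms.
#'
#' @param config A [generator_config()].
#' @param seed Overrides `config$seed` if given.
#' @return A [cohort()] object. In `"direct"` mode patients carry
#'   `eq5dp_baseline` / `eq5dp_followup` columns and empty QLQ scores; in
#'   `"item_level"` mode they carry QLQ dimension scores whose mapped
#'   EQ-5DP matches the sampled utilities within the configured tolerance.
#'   Missingness is not applied here; see [inject_missingness()].
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  spec <- trial_spec(config$trial)
  window <- spec$followup_window_days

  arms <- arm_levels()
  patients <- purrr::map(arms, function(a) {
    n <- config$n_per_arm[[a]]
    wt <- pmax(1, rnorm(n, config$treatment_weeks_mean[[a]], config$treatment_weeks_sd[[a]]))
    u0 <- rnorm_trunc(n, config$utility_baseline_mean[[a]], config$utility_baseline_sd[[a]], -0.594, 1)
    du <- rnorm(n, config$utility_change_mean[[a]], config$utility_change_sd[[a]])
    u1 <- clamp(u0 + du, -0.594, 1)
    tibble(
      patient_id = sprintf("%s-%s-%03d", config$trial, toupper(substr(a, 1, 1)), seq_len(n)),
      trial = config$trial,
      arm = a,
      age_years = round(rnorm_trunc(n, config$age_mean, config$age_sd, 25, 95), 1),
      charlson_score = rpois(n, config$charlson_lambda),
      treatment_weeks = round(wt, 2),
      nact_cycles = if (config$trial == "B_RCT") 1L + rpois(n, config$nact_lambda) else NA_integer_,
      completed_followup = TRUE,
      costs_missing = FALSE,
      eq5dp_baseline = u0,
      eq5dp_followup = u1
    )
  }) |>
    dplyr::bind_rows()

  score_cols <- c(
    paste0("baseline_", qlq_dimension_names()),
    paste0("followup_", qlq_dimension_names())
  )
  patients[score_cols] <- NA_real_

  if (config$mode == "item_level") {
    model <- config$mapping_model %||% read_mapping_model()
    values <- config$value_set %||% read_value_set()
    sc0 <- scores_for_utility(
      patients$eq5dp_baseline, model, values,
      config$utility_tolerance
    )
    sc1 <- scores_for_utility(
      patients$eq5dp_followup, model, values,
      config$utility_tolerance
    )
    patients[paste0("baseline_", qlq_dimension_names())] <- sc0
    patients[paste0("followup_", qlq_dimension_names())] <- sc1
    # the sampled utilities are realized through the scores; drop the
    # precomputed columns so downstream stages exercise the mapping
    patients$eq5dp_baseline <- NA_real_
    patients$eq5dp_followup <- NA_real_
  }

  events <- purrr::map(arms, function(a) {
    ids <- patients$patient_id[patients$arm == a]
    n <- length(ids)
    per_setting <- purrr::map(c("outpatient", "inpatient"), function(st) {
      rate <- if (st == "outpatient") {
        config$event_rate_outpatient[[a]]
      } else {
        config$event_rate_inpatient[[a]]
      }
      counts <- rpois(n, rate)
      m <- sum(counts)
      if (m == 0) {
        return(NULL)
      }
      acute <- runif(m) < config$acute_probability[[st]]
      codes <- character(m)
      codes[acute] <- sample_codes(
        sum(acute), config$icd_pools$acute,
        config$second_code_probability
      )
      codes[!acute] <- sample_codes(
        sum(!acute), config$icd_pools$routine,
        config$second_code_probability
      )
      tibble(
        patient_id = rep(ids, counts),
        day_offset = sample.int(window, m, replace = TRUE) - 1L,
        setting = st,
        acute = acute,
        unplanned_admission = st == "inpatient" & acute &
          runif(m) < config$unplanned_admission_probability,
        icd_codes = codes,
        cost_sek_2019 = rgamma(m, shape = config$cost_shape[[st]], scale = config$cost_scale[[st]]),
        is_rt_fraction = FALSE
      )
    })
    dplyr::bind_rows(per_setting)
  }) |>
    dplyr::bind_rows()

  if (config$trial == "P_RCT" && config$rt_fractions_per_week > 0) {
    tail_w <- spec$reporting_tail_weeks
    n_frac <- pmax(0L, as.integer(round(
      (patients$treatment_weeks - tail_w) * config$rt_fractions_per_week
    )))
    m <- sum(n_frac)
    if (m > 0) {
      treat_days <- pmax(1L, as.integer(ceiling((patients$treatment_weeks - tail_w) * 7)))
      rt <- tibble(
        patient_id = rep(patients$patient_id, n_frac),
        day_offset = as.integer(unlist(purrr::map2(
          treat_days, n_frac,
          function(d, k) if (k) sort(sample.int(min(d, window), k, replace = TRUE)) - 1L else integer(0)
        ))),
        setting = "outpatient",
        acute = FALSE,
        unplanned_admission = FALSE,
        icd_codes = "Z510",
        cost_sek_2019 = rgamma(m, shape = config$rt_cost_shape, scale = config$rt_cost_scale),
        is_rt_fraction = TRUE
      )
      events <- dplyr::bind_rows(events, rt)
    }
  }

  if (is.null(events) || !nrow(events)) {
    events <- tibble(
      patient_id = character(0), day_offset = integer(0),
      setting = character(0), acute = logical(0),
      unplanned_admission = logical(0), icd_codes = character(0),
      cost_sek_2019 = numeric(0), is_rt_fraction = logical(0)
    )
  }
  cohort(patients, events)
}

#' Blank follow-up scores and cost records completely at random
#'
#' Emulates the missingness the analysis has to absorb: missing baseline or
#' follow-up questionnaires and administratively missing cost records. For
#' each trial arm, `round(fraction * arm size)` patients are drawn without
#' replacement (so configured counts are hit exactly for a fixed seed) and
#' the targeted fields are blanked. The mechanism is missing completely at
#' random, matching the assumption under which group-mean imputation is
#' unbiased.
#'
#' @param cohort A [cohort()] object.
#' @param config The [generator_config()] carrying the per-arm
#'   `missing_*_fraction`s.
#' @param seed Optional seed for the draw.
#' @return The cohort with fields blanked: follow-up (or baseline) QLQ
#'   scores and `eq5dp_*` columns set to `NA` (follow-up blanking also
#'   clears `completed_followup`), and `costs_missing` flagged for
#'   cost-blanked patients. A `missingness_log` attribute records, per
#'   trial, arm and field, how many and which patients were blanked, so
#'   imputation targets can be verified.
#' @export
inject_missingness <- function(cohort, config, seed = NULL) {
  stopifnot(inherits(cohort, "cua_cohort"), inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  pts <- cohort$patients
  log <- list()
  for (a in arm_levels()) {
    idx <- which(pts$arm == a & pts$trial == config$trial)
    n <- length(idx)
    if (!n) next
    blank <- function(frac) {
      k <- round(frac * n)
      if (k > 0) sample(idx, k) else integer(0)
    }
    b_base <- blank(config$missing_baseline_fraction[[a]])
    b_fup <- blank(config$missing_followup_fraction[[a]])
    b_cost <- blank(config$missing_cost_fraction[[a]])
    if (length(b_base)) {
      pts[b_base, paste0("baseline_", qlq_dimension_names())] <- NA_real_
      if ("eq5dp_baseline" %in% names(pts)) pts$eq5dp_baseline[b_base] <- NA_real_
    }
    if (length(b_fup)) {
      pts[b_fup, paste0("followup_", qlq_dimension_names())] <- NA_real_
      if ("eq5dp_followup" %in% names(pts)) pts$eq5dp_followup[b_fup] <- NA_real_
      pts$completed_followup[b_fup] <- FALSE
    }
    if (length(b_cost)) pts$costs_missing[b_cost] <- TRUE
    log[[a]] <- tibble(
      trial = config$trial, arm = a,
      field = c("baseline_qlq", "followup_qlq", "costs"),
      n_blanked = c(length(b_base), length(b_fup), length(b_cost)),
      patient_ids = list(
        pts$patient_id[b_base], pts$patient_id[b_fup], pts$patient_id[b_cost]
      )
    )
  }
  out <- cohort
  out$patients <- pts
  attr(out, "missingness_log") <- dplyr::bind_rows(log)
  out
}
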