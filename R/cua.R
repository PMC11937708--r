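#' Intention-to-treat group-mean imputation
#'
#' Replaces each missing value of the requested fields by the mean of the
#' observed values in the same cell (by default the trial-by-arm cell; time
#' is implicit in the field, e.g. `baseline_pf` vs `followup_pf`). This is
#' the simple single-imputation scheme appropriate for an ITT analysis of a
#' small RCT under a missing-completely-at-random mechanism; it preserves
#' each cell's observed mean exactly.
#'
#' @param data A data frame (e.g. `cohort$patients`, or a per-patient cost
#'   table joined with `trial`/`arm`).
#' @param fields Character vector of numeric columns to complete.
#' @param by Cell-defining columns (default `c("trial", "arm")`).
#' @param max_missing_warn Warn when a cell's missing fraction exceeds this
#'   (default 0.10, above which imputation is considered bias-prone).
#'
#' @return The completed tibble, with an `imputation_log` attribute
#'   (tibble: cell columns, `field`, `n_missing`, `n_observed`,
#'   `imputed_value`, `frac_missing`); retrieve it with [imputation_log()].
#'   A cell with zero observed values for a field is an error.
#' @examples
#' d <- data.frame(trial = "B_RCT", arm = "intervention", u = c(0.8, 0.9, NA))
#' imputation_log(impute_group_means(d, "u"))
#' @export
impute_group_means <- function(data, fields, by = c("trial", "arm"),
                               max_missing_warn = 0.10) {
  data <- as_tibble(data)
  missing_f <- setdiff(c(fields, by), names(data))
  if (length(missing_f)) {
    abort(
      paste0("unknown column(s): ", paste(missing_f, collapse = ", ")),
      class = "eprocua_schema_error"
    )
  }
  data$.orig_order <- seq_len(nrow(data))
  cells <- dplyr::group_split(dplyr::group_by(data, across(all_of(by))))
  log <- list()
  out <- purrr::map(cells, function(cell) {
    for (f in fields) {
      x <- cell[[f]]
      n_mis <- sum(is.na(x))
      n_obs <- sum(!is.na(x))
      if (n_mis > 0 && n_obs == 0) {
        abort(
          paste0(
            "cannot impute `", f, "` in cell ",
            paste(unlist(cell[1, by]), collapse = "/"),
            ": no observed values."
          ),
          class = "eprocua_imputation_error"
        )
      }
      m <- if (n_obs) mean(x, na.rm = TRUE) else NA_real_
      if (n_mis > 0) cell[[f]][is.na(x)] <- m
      log[[length(log) + 1]] <<- dplyr::bind_cols(
        cell[1, by],
        tibble(
          field = f, n_missing = n_mis, n_observed = n_obs,
          imputed_value = if (n_mis) m else NA_real_,
          frac_missing = n_mis / (n_mis + n_obs)
        )
      )
    }
    cell
  })
  log <- dplyr::bind_rows(log)
  high <- log[log$frac_missing > max_missing_warn & log$n_missing > 0, ]
  if (nrow(high)) {
    warn(sprintf(
      "%d cell/field combination(s) exceed %.0f%% missingness (up to %.0f%%); group-mean imputation is bias-prone there.",
      nrow(high), 100 * max_missing_warn, 100 * max(high$frac_missing)
    ))
  }
  res <- dplyr::bind_rows(out) |>
    arrange(.data$.orig_order) |>
    select(-".orig_order")
  attr(res, "imputation_log") <- log
  res
}

#' @rdname impute_group_means
#' @param x A tibble returned by [impute_group_means()].
#' @export
imputation_log <- function(x) attr(x, "imputation_log")

#' QALY loss over the treatment period
#'
#' Linear (trapezoid) accrual of the utility change over the individual
#' treatment duration: `((after - before) / 2) * (wt / 52)`. Negative
#' values are QALYs lost.
#'
#' @param eq5dp_before,eq5dp_after Utilities before/after treatment.
#' @param wt Individual treatment duration in weeks (`> 0`).
#' @return QALYs (vectorized).
#' @examples
#' qaly_loss(0.87, 0.80, 15) # -0.0100962
#' @export
qaly_loss <- function(eq5dp_before, eq5dp_after, wt) {
  if (any(is.na(wt)) || any(wt <= 0)) {
    abort("`wt` must be positive.", class = "eprocua_validation_error")
  }
  ((eq5dp_after - eq5dp_before) / 2) * (wt / 52)
}

icer_variants <- function() c("ICERa", "ICERb", "ICERc")

#' Swedish cost-per-QALY threshold bands
#'
#' The National Board of Health and Welfare bands used to interpret a cost
#' per QALY: up to 9685 EUR low, above 48,423 EUR high, above 96,846 EUR
#' very high (the range between the first two is read as moderate).
#'
#' @param low,high,very_high Band edges in EUR/QALY.
#' @return A list of class `threshold_bands`.
#' @export
threshold_bands <- function(low = 9685, high = 48423, very_high = 96846) {
  stopifnot(low < high, high < very_high)
  structure(list(low = low, high = high, very_high = very_high),
    class = "threshold_bands"
  )
}

#' Classify an ICER against the threshold bands
#'
#' @param icer ICER point estimate(s), EUR/QALY.
#' @param dominance Dominance label(s) from [icer_point()]; `"dominant"`
#'   and `"dominated"` short-circuit the bands.
#' @param bands A [threshold_bands()].
#' @return Character vector: `"dominant"`, `"dominated"`, `"low"`,
#'   `"moderate"`, `"high"` or `"very high"` (band edges inclusive).
#' @examples
#' classify_icer(9685, "tradeoff_NE") # "low"
#' classify_icer(50000, "tradeoff_NE") # "high"
#' @export
classify_icer <- function(icer, dominance = "tradeoff_NE", bands = threshold_bands()) {
  stopifnot(inherits(bands, "threshold_bands"))
  n <- max(length(icer), length(dominance))
  icer <- rep_len(icer, n)
  dominance <- rep_len(dominance, n)
  out <- dplyr::case_when(
    dominance == "dominant" ~ "dominant",
    dominance == "dominated" ~ "dominated",
    icer <= bands$low ~ "low",
    icer <= bands$high ~ "moderate",
    icer <= bands$very_high ~ "high",
    .default = "very high"
  )
  out
}

dominance_label <- function(d_cost, d_qaly) {
  dplyr::case_when(
    d_cost <= 0 & d_qaly >= 0 & !(d_cost == 0 & d_qaly == 0) ~ "dominant",
    d_cost >= 0 & d_qaly <= 0 & !(d_cost == 0 & d_qaly == 0) ~ "dominated",
    d_cost > 0 & d_qaly > 0 ~ "tradeoff_NE",
    d_cost < 0 & d_qaly < 0 ~ "tradeoff_SW",
    .default = "undefined"
  )
}

#' Assemble the per-patient cost-utility analysis table
#'
#' Runs the deterministic front half of the CUA for one trial: imputes
#' missing utilities/scores per group and time, maps QLQ scores to EQ-5DP
#' where no precomputed utilities exist, aggregates and imputes per-patient
#' health-care costs, computes intervention costs from individual treatment
#' weeks, and derives each patient's QALY loss and the cost bases of the
#' three ICER variants.
#'
#' @param cohort A [cohort()] object holding one trial.
#' @param model,values Mapping model and value set (used when EQ-5DP
#'   columns are absent or incomplete).
#' @param cmodel A [cost_model()] (default: the trial's).
#' @param ctx A [money_context()].
#' @param exclude_rt Passed to [patient_costs()] (default `"auto"`:
#'   RT fractions excluded for P-RCT).
#' @param categories Passed to [patient_costs()].
#' @param rule EQ-5DP valuation rule, see [expected_utility()].
#'
#' @return A tibble with one row per patient: `patient_id`, `trial`, `arm`,
#'   `eq5dp_before`, `eq5dp_after`, `treatment_weeks`, `qaly_loss`,
#'   `intervention_cost` (zero in the control arm), `total_cost`,
#'   `acute_cost`, and the variant cost bases `cost_a` (intervention + all
#'   health care), `cost_b` (intervention + acute health care), `cost_c`
#'   (intervention only).
#' @export
cua_patient_table <- function(cohort,
                              model = read_mapping_model(),
                              values = read_value_set(),
                              cmodel = NULL,
                              ctx = money_context(),
                              exclude_rt = "auto",
                              categories = icd_category_map(),
                              rule = "expected") {
  stopifnot(inherits(cohort, "cua_cohort"))
  pts <- cohort$patients
  tr <- unique(pts$trial)
  if (length(tr) != 1) {
    abort("cua_patient_table expects a single-trial cohort; split by trial first.",
      class = "eprocua_validation_error"
    )
  }
  cmodel <- cmodel %||% cost_model(tr)

  has_direct <- all(c("eq5dp_baseline", "eq5dp_followup") %in% names(pts)) &&
    any(!is.na(pts$eq5dp_baseline))
  if (has_direct) {
    pts <- impute_group_means(pts, c("eq5dp_baseline", "eq5dp_followup"))
    before <- pts$eq5dp_baseline
    after <- pts$eq5dp_followup
  } else {
    score_cols <- c(
      paste0("baseline_", qlq_dimension_names()),
      paste0("followup_", qlq_dimension_names())
    )
    pts <- impute_group_means(pts, score_cols)
    before <- eq5dp(
      setNames(
        pts[paste0("baseline_", qlq_dimension_names())],
        qlq_dimension_names()
      ),
      model, values, rule
    )
    after <- eq5dp(
      setNames(
        pts[paste0("followup_", qlq_dimension_names())],
        qlq_dimension_names()
      ),
      model, values, rule
    )
  }

  costs <- patient_costs(cohort, ctx, exclude_rt, categories)
  costs <- dplyr::left_join(
    dplyr::select(pts, "patient_id", "trial", "arm"), costs,
    by = "patient_id"
  )
  costs <- impute_group_means(costs, c("total", "acute_total"))

  tibble(
    patient_id = pts$patient_id,
    trial = pts$trial,
    arm = pts$arm,
    eq5dp_before = before,
    eq5dp_after = after,
    treatment_weeks = pts$treatment_weeks,
    qaly_loss = qaly_loss(before, after, pts$treatment_weeks),
    intervention_cost = ifelse(
      pts$arm == "intervention",
      intervention_cost(pts$treatment_weeks, cmodel), 0
    ),
    total_cost = costs$total[match(pts$patient_id, costs$patient_id)],
    acute_cost = costs$acute_total[match(pts$patient_id, costs$patient_id)]
  ) |>
    mutate(
      cost_a = .data$intervention_cost + .data$total_cost,
      cost_b = .data$intervention_cost + .data$acute_cost,
      cost_c = .data$intervention_cost
    )
}

variant_cost_col <- function(variant) {
  switch(variant,
    ICERa = "cost_a",
    ICERb = "cost_b",
    ICERc = "cost_c",
    abort(paste0("unknown ICER variant: ", variant), class = "eprocua_config_error")
  )
}

#' ICER point estimate for one cost-basis variant
#'
#' Incremental cost is the intervention-arm mean of the variant's cost
#' basis minus the control-arm mean (the control arm's intervention cost is
#' identically zero); incremental QALYs are the difference in mean QALY
#' change (intervention minus control, positive favoring the intervention).
#'
#' @param data A [cua_patient_table()].
#' @param variant `"ICERa"` (intervention + all health care), `"ICERb"`
#'   (intervention + acute health care) or `"ICERc"` (intervention costs
#'   only).
#' @return A one-row tibble: `variant`, `n_intervention`, `n_control`,
#'   `incremental_cost`, `incremental_qaly`, `icer` (`NA` with
#'   `icer_defined = FALSE` when the incremental QALY is zero), and
#'   `dominance` (`"dominant"`, `"dominated"`, `"tradeoff_NE"`,
#'   `"tradeoff_SW"`).
#' @export
icer_point <- function(data, variant = c("ICERa", "ICERb", "ICERc")) {
  variant <- match.arg(variant)
  col <- variant_cost_col(variant)
  ig <- data[data$arm == "intervention", ]
  cg <- data[data$arm == "control", ]
  if (!nrow(ig) || !nrow(cg)) {
    abort("both arms must be non-empty.", class = "eprocua_empty_arm_error")
  }
  d_cost <- mean(ig[[col]]) - mean(cg[[col]])
  d_qaly <- mean(ig$qaly_loss) - mean(cg$qaly_loss)
  defined <- d_qaly != 0
  tibble(
    variant = variant,
    n_intervention = nrow(ig),
    n_control = nrow(cg),
    incremental_cost = d_cost,
    incremental_qaly = d_qaly,
    icer = if (defined) d_cost / d_qaly else NA_real_,
    icer_defined = defined,
    dominance = dominance_label(d_cost, d_qaly)
  )
}

#' Nonparametric bootstrap of an ICER
#'
#' Resamples patients with replacement within each arm at the original arm
#' sizes (each patient's paired cost and QALY values travel together),
#' recomputing the incremental cost, incremental QALY and their ratio for
#' each replicate. Summaries report the mean and SD of replicate ICERs, a
#' 95% CI (percentile by default), and the ratio of replicate means; all
#' replicates are kept for cost-effectiveness-plane plotting.
#'
#' Replicates whose |incremental QALY| falls below `epsilon` are retained
#' as plane points but excluded from the ICER mean/SD/CI (an unbounded
#' ratio would otherwise dominate the summaries); the exclusion count is
#' reported.
#'
#' @param data A [cua_patient_table()].
#' @param variant ICER variant, see [icer_point()].
#' @param B Number of bootstrap replications (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @param epsilon Degenerate-denominator guard (default 1e-12).
#' @param ci `"percentile"` (default) or `"normal"` (mean +/- 1.96 SD of
#'   replicate ICERs).
#'
#' @return An object of class `cua_bootstrap`: list with `variant`, `B`,
#'   `seed`, `point` (the [icer_point()] row), `replicates` (tibble `rep`,
#'   `incremental_cost`, `incremental_qaly`, `icer`), `icer_mean`,
#'   `icer_sd`, `ci95`, `icer_of_means`, `n_excluded`, `ci_method`.
#'   Methods: [tidy()] (replicates), [glance()] (one-row summary),
#'   [autoplot()] (cost-effectiveness plane).
#' @export
bootstrap_icer <- function(data, variant = c("ICERa", "ICERb", "ICERc"),
                           B = 1000, seed = NULL, epsilon = 1e-12,
                           ci = c("percentile", "normal")) {
  variant <- match.arg(variant)
  ci <- match.arg(ci)
  if (!is.numeric(B) || B < 1) {
    abort("B must be >= 1.", class = "eprocua_validation_error")
  }
  B <- as.integer(B)
  point <- icer_point(data, variant)
  col <- variant_cost_col(variant)
  if (!is.null(seed)) set.seed(seed)

  arm_means <- function(cost, qaly) {
    n <- length(cost)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    list(
      cost = colMeans(matrix(cost[idx], nrow = n)),
      qaly = colMeans(matrix(qaly[idx], nrow = n))
    )
  }
  ig <- data[data$arm == "intervention", ]
  cg <- data[data$arm == "control", ]
  mi <- arm_means(ig[[col]], ig$qaly_loss)
  mc <- arm_means(cg[[col]], cg$qaly_loss)
  d_cost <- mi$cost - mc$cost
  d_qaly <- mi$qaly - mc$qaly
  icer <- ifelse(abs(d_qaly) < epsilon, NA_real_, d_cost / d_qaly)
  reps <- tibble(
    rep = seq_len(B),
    incremental_cost = d_cost,
    incremental_qaly = d_qaly,
    icer = icer
  )
  kept <- icer[!is.na(icer)]
  icer_mean <- mean(kept)
  icer_sd <- if (length(kept) > 1) sd(kept) else 0
  ci95 <- if (ci == "percentile") {
    unname(quantile(kept, c(0.025, 0.975), type = 7, na.rm = TRUE))
  } else {
    icer_mean + c(-1, 1) * qnorm(0.975) * icer_sd
  }
  structure(
    list(
      variant = variant, B = B, seed = seed, point = point,
      replicates = reps,
      icer_mean = icer_mean, icer_sd = icer_sd,
      ci95 = ci95,
      icer_of_means = {
        dq <- mean(d_qaly)
        if (abs(dq) < epsilon) NA_real_ else mean(d_cost) / dq
      },
      n_excluded = sum(is.na(icer)),
      ci_method = ci
    ),
    class = "cua_bootstrap"
  )
}

#' @export
print.cua_bootstrap <- function(x, ...) {
  cat("<cua_bootstrap> ", x$variant, ", B=", x$B, "\n", sep = "")
  cat(sprintf(
    "  point ICER %.1f EUR/QALY (d-cost %.1f, d-QALY %.5f, %s)\n",
    x$point$icer, x$point$incremental_cost, x$point$incremental_qaly,
    x$point$dominance
  ))
  cat(sprintf(
    "  replicate ICER mean %.1f (SD %.1f), 95%% CI [%.1f, %.1f] (%s), %d/%d excluded\n",
    x$icer_mean, x$icer_sd, x$ci95[1], x$ci95[2], x$ci_method,
    x$n_excluded, x$B
  ))
  invisible(x)
}

#' @export
tidy.cua_bootstrap <- function(x, ...) {
  mutate(x$replicates, variant = x$variant, .before = 1)
}

#' @export
glance.cua_bootstrap <- function(x, ...) {
  tibble(
    variant = x$variant,
    B = x$B,
    incremental_cost = x$point$incremental_cost,
    incremental_qaly = x$point$incremental_qaly,
    icer_point = x$point$icer,
    dominance = x$point$dominance,
    icer_boot_mean = x$icer_mean,
    icer_boot_sd = x$icer_sd,
    ci95_lo = x$ci95[1],
    ci95_hi = x$ci95[2],
    icer_of_means = x$icer_of_means,
    n_excluded = x$n_excluded,
    classification = classify_icer(x$point$icer, x$point$dominance)
  )
}

#' Cost-effectiveness plane points and quadrant tallies
#'
#' @param result A [bootstrap_icer()] result.
#' @return A tibble of all B replicates with `incremental_qaly` (x),
#'   `incremental_cost` (y) and `quadrant` (`NE`, `NW`, `SE`, `SW`;
#'   boundary points on an axis count toward the north/east side), plus a
#'   `quadrant_counts` attribute whose four tallies sum to B.
#' @export
ce_plane_points <- function(result) {
  stopifnot(inherits(result, "cua_bootstrap"))
  pts <- result$replicates |>
    mutate(
      quadrant = paste0(
        ifelse(.data$incremental_cost >= 0, "N", "S"),
        ifelse(.data$incremental_qaly >= 0, "E", "W")
      )
    ) |>
    select("rep", "incremental_qaly", "incremental_cost", "quadrant")
  counts <- table(factor(pts$quadrant, levels = c("NE", "NW", "SE", "SW")))
  attr(pts, "quadrant_counts") <- setNames(as.integer(counts), names(counts))
  pts
}

#' @param object A `cua_bootstrap` object.
#' @param ... Unused.
#' @rdname bootstrap_icer
#' @export
autoplot.cua_bootstrap <- function(object, ...) {
  pts <- ce_plane_points(object)
  ggplot2::ggplot(
    pts,
    ggplot2::aes(x = .data$incremental_qaly, y = .data$incremental_cost)
  ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Incremental QALYs (intervention - control)",
      y = "Incremental cost (EUR 2022)",
      title = paste0(
        "Cost-effectiveness plane, ", object$variant,
        " (B = ", object$B, ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled SD weighted by n - 1.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return Effect size d (`NaN` if the pooled SD is zero).
#' @examples
#' cohens_d(c(2, 4), c(1, 3)) # 0.7071
#' @export
cohens_d <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) {
    abort("both groups need >= 2 values.", class = "eprocua_validation_error")
  }
  sp <- sqrt(((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2))
  (mean(group_a) - mean(group_b)) / sp
}
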