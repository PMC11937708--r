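#' Render a cost-effectiveness plane to an image file
#'
#' @param result A [bootstrap_icer()] result (or list of them, overlaid
#'   with a variant legend).
#' @param path Output path; the extension picks the device (`.png`,
#'   `.svg`, `.pdf`).
#' @param width,height,dpi Device settings in inches / dots per inch.
#' @return `path`, invisibly.
#' @export
render_ce_plane <- function(result, path, width = 6, height = 5, dpi = 150) {
  if (inherits(result, "cua_bootstrap")) result <- list(result)
  if (!length(result) || !all(purrr::map_lgl(result, inherits, "cua_bootstrap"))) {
    abort("`result` must be one or more cua_bootstrap objects.",
      class = "eprocua_validation_error"
    )
  }
  pts <- purrr::map(result, function(r) {
    mutate(ce_plane_points(r), variant = r$variant)
  }) |>
    dplyr::bind_rows()
  if (!nrow(pts)) {
    abort("no plane points to plot.", class = "eprocua_validation_error")
  }
  p <- ggplot2::ggplot(
    pts,
    ggplot2::aes(
      x = .data$incremental_qaly, y = .data$incremental_cost,
      colour = .data$variant
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "Incremental QALYs (intervention - control)",
      y = "Incremental cost (EUR 2022)",
      colour = "Variant"
    ) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}

default_run_config <- function() {
  list(
    trial = "B_RCT",
    generator = list(),
    patients_path = NULL,
    events_path = NULL,
    bootstrap_B = 1000,
    seed = NULL,
    ci_method = "percentile",
    epsilon = 1e-12,
    exclude_rt = "auto",
    value_set = NULL,
    mapping_model = NULL,
    icd_map = NULL,
    utilization_outcomes = list(
      list(outcome = "n_acute_inpatient", kind = "count")
    ),
    render_planes = FALSE,
    outdir = NULL
  )
}

#' Run the full cost-utility pipeline
#'
#' Orchestrates one reproducible analysis run for one trial:
#' read or generate the cohort, inject and then impute missingness, map
#' utilities, aggregate costs, compute the three ICER variants with
#' bootstrap uncertainty, fit utilization regressions, and (optionally)
#' write publication-style outputs. Identical config and seed give
#' identical numeric outputs.
#'
#' @param config A named list (or path to a YAML/JSON file) with keys:
#'   `trial`; either `generator` (a list of [generator_config()] overrides;
#'   an empty list uses the trial's calibrated defaults) or
#'   `patients_path` + `events_path`; `bootstrap_B`; `seed`; `ci_method`;
#'   `epsilon`; `exclude_rt`; optional `value_set`, `mapping_model`,
#'   `icd_map` file paths; `utilization_outcomes` (list of
#'   `list(outcome=, kind=)`); `render_planes`; `outdir` (`NULL` = no files
#'   written).
#' @param seed Overrides `config$seed`.
#'
#' @return A list of class `cua_run`: `manifest` (stages with row counts,
#'   seed, config hash, package version), `cohort`, `cua_table`,
#'   `cua_summary` (one [glance()] row per variant with NBHW
#'   classification), `bootstraps` (named list of [bootstrap_icer()]
#'   results), `utilization` (named list of [fit_utilization_glm()] fits),
#'   `arm_summary`.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) {
    abort("config must set a seed: every stochastic stage requires one.",
      class = "eprocua_config_error"
    )
  }
  stages <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(
        paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)),
        class = "eprocua_pipeline_error", parent = e
      )
    })
  }

  model <- stage("configure", {
    if (is.null(cfg$mapping_model)) read_mapping_model() else read_mapping_model(cfg$mapping_model)
  })
  values <- stage("configure", {
    if (is.null(cfg$value_set)) read_value_set() else read_value_set(cfg$value_set)
  })
  categories <- stage("configure", {
    if (is.null(cfg$icd_map)) icd_category_map() else icd_category_map(cfg$icd_map)
  })

  stages$configure <- list(
    value_set = values$name, mapping_model = model$name
  )

  ch <- stage("cohort", {
    if (!is.null(cfg$patients_path)) {
      read_cohort(cfg$patients_path, cfg$events_path)
    } else {
      gcfg <- do.call(
        generator_config,
        c(list(trial = cfg$trial, seed = cfg$seed), cfg$generator)
      )
      inject_missingness(generate_cohort(gcfg), gcfg)
    }
  })
  stages$cohort <- list(
    patients = nrow(ch$patients), events = nrow(ch$events)
  )

  stages$impute <- list(
    cells = if (!is.null(attr(ch, "missingness_log"))) {
      nrow(attr(ch, "missingness_log"))
    } else {
      0L
    }
  )

  cua_tbl <- stage("cua_table", {
    cua_patient_table(
      ch,
      model = model, values = values,
      ctx = money_context(), exclude_rt = cfg$exclude_rt,
      categories = categories
    )
  })
  stages$cua_table <- list(rows = nrow(cua_tbl))

  boots <- stage("bootstrap", {
    out <- purrr::map(icer_variants(), function(v) {
      bootstrap_icer(
        cua_tbl,
        variant = v, B = cfg$bootstrap_B,
        seed = cfg$seed + match(v, icer_variants()),
        epsilon = cfg$epsilon, ci = cfg$ci_method
      )
    })
    setNames(out, icer_variants())
  })
  cua_summary <- dplyr::bind_rows(purrr::map(boots, glance))
  stages$bootstrap <- list(variants = length(boots), B = cfg$bootstrap_B)

  util_data <- stage("utilization_data", {
    pc <- patient_costs(ch,
      ctx = money_context(),
      exclude_rt = cfg$exclude_rt, categories = categories
    )
    dplyr::left_join(
      dplyr::select(
        cua_tbl, "patient_id", "trial", "arm",
        "eq5dp_baseline" = "eq5dp_before", "treatment_weeks"
      ),
      pc,
      by = "patient_id"
    ) |>
      dplyr::left_join(
        dplyr::select(
          ch$patients, "patient_id", "age_years",
          "charlson_score", "nact_cycles"
        ),
        by = "patient_id"
      ) |>
      impute_group_means(
        fields = setdiff(
          names(pc), c("patient_id")
        )
      )
  })

  utilization <- stage("utilization_models", {
    covars <- c("age_years", "charlson_score", "eq5dp_baseline")
    if (cfg$trial == "B_RCT") covars <- c(covars, "nact_cycles")
    fits <- purrr::map(cfg$utilization_outcomes, function(spec) {
      fit_utilization_glm(
        util_data,
        outcome = spec$outcome,
        kind = spec$kind %||% "count",
        covariates = covars,
        family = spec$family %||% NULL
      )
    })
    setNames(fits, purrr::map_chr(cfg$utilization_outcomes, "outcome"))
  })
  stages$utilization <- list(models = length(utilization))

  arm_summary <- stage("report", {
    summarize_arm(
      dplyr::left_join(
        cua_tbl,
        dplyr::select(util_data, "patient_id", "acute_outpatient", "acute_inpatient",
          "outpatient_total", "inpatient_total"),
        by = "patient_id"
      ),
      fields = c(
        "eq5dp_before", "eq5dp_after", "qaly_loss", "intervention_cost",
        "outpatient_total", "inpatient_total", "total_cost",
        "acute_outpatient", "acute_inpatient", "acute_cost",
        "cost_a", "cost_b", "cost_c"
      )
    )
  })

  stages$report <- list(rows = nrow(arm_summary))

  manifest <- list(
    package_version = as.character(utils::packageVersion("eprocua")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    trial = cfg$trial,
    currency = "EUR-2022",
    stages = stages,
    stages_completed = length(stages)
  )

  run <- structure(
    list(
      manifest = manifest, config = cfg, cohort = ch,
      cua_table = cua_tbl, cua_summary = cua_summary,
      bootstraps = boots, utilization = utilization,
      arm_summary = arm_summary
    ),
    class = "cua_run"
  )
  if (!is.null(cfg$outdir)) write_run(run, cfg$outdir)
  run
}

read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config file must be .yaml/.yml or .json.", class = "eprocua_config_error")
  }
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$cua_summary, file.path(outdir, "cua_summary.csv"))
  readr::write_csv(
    dplyr::bind_rows(purrr::map(run$bootstraps, tidy)),
    file.path(outdir, "bootstrap_replicates.csv")
  )
  readr::write_csv(run$arm_summary, file.path(outdir, "arm_summary.csv"))
  readr::write_csv(
    dplyr::bind_rows(purrr::map(run$utilization, function(f) {
      mutate(tidy(f), outcome = f$outcome, family = f$family, .before = 1)
    })),
    file.path(outdir, "utilization_models.csv")
  )
  write_cohort(
    run$cohort,
    file.path(outdir, "patients.csv"), file.path(outdir, "events.csv")
  )
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  if (isTRUE(run$config$render_planes)) {
    render_ce_plane(
      run$bootstraps[c("ICERa", "ICERb")],
      file.path(outdir, "ce_plane_a_b.png")
    )
    render_ce_plane(
      run$bootstraps["ICERc"],
      file.path(outdir, "ce_plane_c.png")
    )
  }
  invisible(outdir)
}

#' @export
print.cua_run <- function(x, ...) {
  cat("<cua_run> trial ", x$manifest$trial, ", seed ", x$manifest$seed,
    ", B=", x$config$bootstrap_B, "\n",
    sep = ""
  )
  print(
    dplyr::select(
      x$cua_summary, "variant", "incremental_cost", "incremental_qaly",
      "icer_point", "ci95_lo", "ci95_hi", "classification"
    )
  )
  invisible(x)
}
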