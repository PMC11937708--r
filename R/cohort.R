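#' Build a validated cohort from patient and event tables
#'
#' A cohort bundles one row per trial participant with one row per
#' health-care contact, the two tables the whole analysis pipeline consumes.
#'
#' @param patients A data frame with columns `patient_id`, `trial`
#'   (`"B_RCT"`/`"P_RCT"`), `arm` (`"intervention"`/`"control"`),
#'   `age_years`, `charlson_score`, `treatment_weeks`, `nact_cycles`
#'   (B-RCT only; `NA` for P-RCT), `completed_followup`, the 15 baseline and
#'   15 follow-up QLQ-C30 dimension scores (`baseline_ql` ... `followup_fi`,
#'   `NA` = missing), and optionally `eq5dp_baseline`, `eq5dp_followup`
#'   (precomputed utilities) and `costs_missing`.
#' @param events A data frame with columns `patient_id`, `day_offset`
#'   (days from first treatment day), `setting`
#'   (`"outpatient"`/`"inpatient"`), `acute`, `unplanned_admission`,
#'   `icd_codes` (semicolon-separated ICD-10 codes), `cost_sek_2019`,
#'   `is_rt_fraction`. May have zero rows.
#'
#' @return An object of class `cua_cohort`: a list with tibbles `patients`
#'   and `events`.
#'
#' @details Validation enforces: every event's `patient_id` exists in
#'   `patients`; both arms non-empty within each trial present; positive
#'   `treatment_weeks`; non-negative costs; day offsets inside the trial's
#'   half-open follow-up window `[0, followup_window_days)`.
#' @export
cohort <- function(patients, events) {
  patients <- as_tibble(patients)
  events <- as_tibble(events)
  if (!"costs_missing" %in% names(patients)) patients$costs_missing <- FALSE
  validate_cohort(patients, events)
  structure(list(patients = patients, events = events), class = "cua_cohort")
}

patient_required_cols <- function() {
  c(
    "patient_id", "trial", "arm", "age_years", "charlson_score",
    "treatment_weeks", "nact_cycles", "completed_followup",
    paste0("baseline_", qlq_dimension_names()),
    paste0("followup_", qlq_dimension_names())
  )
}

event_required_cols <- function() {
  c(
    "patient_id", "day_offset", "setting", "acute", "unplanned_admission",
    "icd_codes", "cost_sek_2019", "is_rt_fraction"
  )
}

validate_cohort <- function(patients, events) {
  miss_p <- setdiff(patient_required_cols(), names(patients))
  if (length(miss_p)) {
    abort(
      paste0("patients table is missing column(s): ", paste(miss_p, collapse = ", ")),
      class = "eprocua_schema_error"
    )
  }
  miss_e <- setdiff(event_required_cols(), names(events))
  if (length(miss_e)) {
    abort(
      paste0("events table is missing column(s): ", paste(miss_e, collapse = ", ")),
      class = "eprocua_schema_error"
    )
  }
  if (anyDuplicated(patients$patient_id)) {
    abort("duplicated patient_id in patients table.", class = "eprocua_validation_error")
  }
  bad_trial <- setdiff(unique(patients$trial), trial_ids())
  if (length(bad_trial)) {
    abort(
      paste0("unknown trial id(s): ", paste(bad_trial, collapse = ", ")),
      class = "eprocua_validation_error"
    )
  }
  bad_arm <- setdiff(unique(patients$arm), arm_levels())
  if (length(bad_arm)) {
    abort(
      paste0("unknown arm(s): ", paste(bad_arm, collapse = ", ")),
      class = "eprocua_validation_error"
    )
  }
  arm_counts <- dplyr::count(patients, .data$trial, .data$arm)
  for (tr in unique(patients$trial)) {
    present <- arm_counts$arm[arm_counts$trial == tr]
    if (!setequal(present, arm_levels())) {
      abort(
        paste0("trial ", tr, " does not have both non-empty arms."),
        class = "eprocua_validation_error"
      )
    }
  }
  if (any(!is.finite(patients$treatment_weeks) | patients$treatment_weeks <= 0)) {
    abort("treatment_weeks must be positive.", class = "eprocua_validation_error")
  }
  nact_bad <- patients$trial == "B_RCT" & is.na(patients$nact_cycles)
  if (any(nact_bad)) {
    abort(
      paste0(
        "nact_cycles missing for B_RCT patient(s): ",
        paste(head(patients$patient_id[nact_bad], 5), collapse = ", ")
      ),
      class = "eprocua_validation_error"
    )
  }
  if (nrow(events)) {
    orphan <- setdiff(unique(events$patient_id), patients$patient_id)
    if (length(orphan)) {
      abort(
        paste0(
          "event(s) reference unknown patient_id(s): ",
          paste(orphan, collapse = ", ")
        ),
        class = "eprocua_referential_error"
      )
    }
    if (any(events$cost_sek_2019 < 0, na.rm = TRUE)) {
      abort("event costs must be non-negative.", class = "eprocua_validation_error")
    }
    window <- vapply(
      patients$trial,
      function(tr) trial_spec(tr)$followup_window_days, integer(1)
    )
    win <- window[match(events$patient_id, patients$patient_id)]
    out_of_window <- events$day_offset < 0 | events$day_offset >= win
    if (any(out_of_window, na.rm = TRUE)) {
      abort(
        sprintf(
          "%d event(s) fall outside the follow-up window [0, window).",
          sum(out_of_window, na.rm = TRUE)
        ),
        class = "eprocua_validation_error"
      )
    }
    bad_setting <- setdiff(unique(events$setting), c("outpatient", "inpatient"))
    if (length(bad_setting)) {
      abort(
        paste0("unknown event setting(s): ", paste(bad_setting, collapse = ", ")),
        class = "eprocua_validation_error"
      )
    }
  }
  invisible(TRUE)
}

#' @export
print.cua_cohort <- function(x, ...) {
  counts <- dplyr::count(x$patients, .data$trial, .data$arm)
  cat("<cua_cohort> ", nrow(x$patients), " patients, ",
    nrow(x$events), " care events\n",
    sep = ""
  )
  for (i in seq_len(nrow(counts))) {
    cat("  ", counts$trial[i], "/", counts$arm[i], ": n=", counts$n[i], "\n", sep = "")
  }
  invisible(x)
}

patient_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    trial = readr::col_character(),
    arm = readr::col_character(),
    age_years = readr::col_double(),
    charlson_score = readr::col_integer(),
    treatment_weeks = readr::col_double(),
    nact_cycles = readr::col_integer(),
    completed_followup = readr::col_logical(),
    costs_missing = readr::col_logical(),
    .default = readr::col_double()
  )
}

event_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    day_offset = readr::col_integer(),
    setting = readr::col_character(),
    acute = readr::col_logical(),
    unplanned_admission = readr::col_logical(),
    icd_codes = readr::col_character(),
    cost_sek_2019 = readr::col_double(),
    is_rt_fraction = readr::col_logical()
  )
}

#' Read a cohort from delimited text files
#'
#' @param patients_path,events_path Paths to delimited-text files with the
#'   column schemas documented in [cohort()]. An events file with only a
#'   header yields an empty events table.
#' @param delim Field delimiter (default comma).
#'
#' @return A validated [cohort()] object.
#' @details Rows whose mandatory fields fail to parse are rejected with
#'   their row numbers; an event referencing an unknown patient raises a
#'   referential error naming the id.
#' @export
read_cohort <- function(patients_path, events_path, delim = ",") {
  patients <- read_checked(patients_path, patient_col_types(), delim, "patients")
  events <- read_checked(events_path, event_col_types(), delim, "events")
  if (!"costs_missing" %in% names(patients)) patients$costs_missing <- FALSE
  if (nrow(events) && !is.character(events$icd_codes)) {
    events$icd_codes <- as.character(events$icd_codes)
  }
  if (nrow(events)) events$icd_codes[is.na(events$icd_codes)] <- ""
  cohort(patients, events)
}

read_checked <- function(path, col_types, delim, what) {
  tbl <- readr::read_delim(
    path,
    delim = delim, col_types = col_types,
    na = c("", "NA"), show_col_types = FALSE, progress = FALSE
  )
  probs <- readr::problems(tbl)
  if (nrow(probs)) {
    abort(
      sprintf(
        "%s file %s: %d unparseable value(s), first at row %d column %d.",
        what, path, nrow(probs), probs$row[1], probs$col[1]
      ),
      class = "eprocua_schema_error"
    )
  }
  tbl
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]; numeric fields round-trip exactly.
#'
#' @param cohort A [cohort()] object.
#' @param patients_path,events_path Output paths.
#' @param delim Field delimiter (default comma).
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, patients_path, events_path, delim = ",") {
  stopifnot(inherits(cohort, "cua_cohort"))
  readr::write_delim(cohort$patients, patients_path, delim = delim, na = "")
  readr::write_delim(cohort$events, events_path, delim = delim, na = "")
  invisible(cohort)
}

#' Proportion of an arm's patients with at least one matching event
#'
#' Counts distinct patients in one arm having one or more care events that
#' satisfy a filter expression, e.g. acute inpatient admissions carrying a
#' fever ICD code.
#'
#' @param cohort A [cohort()] object.
#' @param arm `"intervention"` or `"control"`.
#' @param predicate An unquoted filter expression evaluated on the events
#'   table (columns `setting`, `acute`, `icd_codes`, ...). Use
#'   [icd_matches_any()] for ICD-code predicates.
#' @param trial Optional trial id to restrict to (needed when the cohort
#'   holds both trials).
#'
#' @return A one-row tibble: `arm`, `numerator`, `denominator`,
#'   `proportion` and `percent` (rounded to the nearest integer, the usual
#'   reporting convention).
#' @examples
#' \dontrun{
#' proportion_with_event(ch, "intervention",
#'   acute & setting == "inpatient" &
#'     icd_matches_any(icd_codes, c("R502", "R508", "R509", "D709C"))
#' )
#' }
#' @export
proportion_with_event <- function(cohort, arm, predicate, trial = NULL) {
  stopifnot(inherits(cohort, "cua_cohort"))
  arm <- match.arg(arm, arm_levels())
  pts <- cohort$patients
  if (!is.null(trial)) pts <- pts[pts$trial == trial, ]
  ids <- pts$patient_id[pts$arm == arm]
  if (!length(ids)) {
    abort("arm is empty: proportion denominator undefined.",
      class = "eprocua_empty_arm_error"
    )
  }
  ev <- cohort$events[cohort$events$patient_id %in% ids, , drop = FALSE]
  keep <- eval_tidy(enquo(predicate), data = ev)
  num <- dplyr::n_distinct(ev$patient_id[keep %in% TRUE])
  tibble(
    arm = arm,
    numerator = num,
    denominator = length(ids),
    proportion = num / length(ids),
    percent = round(100 * num / length(ids))
  )
}

#' Does a semicolon-separated ICD string contain any of the given codes?
#'
#' Codes are compared after normalization (uppercase, dots and whitespace
#' stripped), so `"R50.2"` matches `"R502"`.
#'
#' @param icd_codes Character vector of semicolon-separated code strings.
#' @param codes Character vector of target codes.
#' @return Logical vector along `icd_codes`.
#' @export
icd_matches_any <- function(icd_codes, codes) {
  target <- normalize_icd(codes)
  purrr::map_lgl(
    strsplit(ifelse(is.na(icd_codes), "", icd_codes), ";", fixed = TRUE),
    function(x) any(normalize_icd(x) %in% target)
  )
}

#' Per-arm means and standard deviations
#'
#' Summary statistics in the style of a trial baseline table: mean and SD
#' (n - 1 denominator) per arm for each requested numeric column. With a
#' single observation the SD is reported as `NA` (undefined).
#'
#' @param data A data frame with an `arm` column (e.g. `cohort$patients`
#'   joined with [patient_costs()]).
#' @param fields Character vector of numeric column names to summarize.
#' @param by Grouping columns (default `"arm"`).
#' @param na.rm Drop missing values within each cell (default `TRUE`).
#'
#' @return A tibble with columns `by`..., `field`, `n`, `mean`, `sd`.
#' @examples
#' summarize_arm(
#'   data.frame(arm = c("a", "a", "a"), x = c(1, 2, 3)),
#'   fields = "x"
#' )
#' @export
summarize_arm <- function(data, fields, by = "arm", na.rm = TRUE) {
  data <- as_tibble(data)
  missing_f <- setdiff(fields, names(data))
  if (length(missing_f)) {
    abort(
      paste0("unknown field(s): ", paste(missing_f, collapse = ", ")),
      class = "eprocua_schema_error"
    )
  }
  data |>
    tidyr::pivot_longer(all_of(fields), names_to = "field", values_to = ".value") |>
    group_by(across(all_of(c(by, "field")))) |>
    summarize(
      n = if (na.rm) sum(!is.na(.data$.value)) else dplyr::n(),
      mean = mean(.data$.value, na.rm = na.rm),
      sd = sd(.data$.value, na.rm = na.rm),
      .groups = "drop"
    )
}
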