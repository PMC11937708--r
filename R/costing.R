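#' Intervention cost model
#'
#' Per-patient cost of running the ePRO app: a one-time implementation /
#' startup cost amortized over the regional patient pool treated with the
#' trial's regimen over three years, plus weekly license fees for nurses
#' (5 nurses per 100 patients) and for the patient, accrued over the
#' patient's weeks in treatment and app reporting.
#'
#' @param trial `"B_RCT"` (pool of 518 patients) or `"P_RCT"` (683).
#' @param startup_cost_eur One-time startup cost, EUR (default 5212).
#' @param nurse_weekly_license_eur Weekly nurse license, EUR (default 39).
#' @param nurses_per_100_patients Nurse staffing ratio (default 5).
#' @param patient_weekly_license_eur Weekly patient license, EUR
#'   (default 2.25).
#'
#' @return A list of class `cost_model`.
#' @details License prices are treated as already expressed in 2022 EUR and
#'   are not passed through the inflation/exchange pipeline, which applies
#'   only to SEK-denominated health-care costs.
#' @export
cost_model <- function(trial = c("B_RCT", "P_RCT"),
                       startup_cost_eur = 5212,
                       nurse_weekly_license_eur = 39,
                       nurses_per_100_patients = 5,
                       patient_weekly_license_eur = 2.25) {
  trial <- match.arg(trial)
  stopifnot(
    startup_cost_eur >= 0, nurse_weekly_license_eur >= 0,
    nurses_per_100_patients >= 0, patient_weekly_license_eur >= 0
  )
  structure(
    list(
      trial = trial,
      startup_cost_eur = startup_cost_eur,
      startup_pool_n = trial_spec(trial)$startup_pool_n,
      nurse_weekly_license_eur = nurse_weekly_license_eur,
      nurses_per_100_patients = nurses_per_100_patients,
      patient_weekly_license_eur = patient_weekly_license_eur
    ),
    class = "cost_model"
  )
}

#' Per-patient intervention cost
#'
#' `startup/pool + (nurse_license * nurses_per_100/100) * wt +
#' patient_license * wt`, i.e. an affine function of the individual weeks
#' in treatment `wt` with slope 4.2 EUR/week at the default prices.
#'
#' @param wt Weeks in treatment and app reporting (vectorized, `>= 0`).
#' @param model A [cost_model()].
#' @return Cost in EUR, same length as `wt`.
#' @examples
#' intervention_cost(15, cost_model("B_RCT")) # 73.0618
#' intervention_cost(8, cost_model("P_RCT")) # 41.2310
#' @export
intervention_cost <- function(wt, model) {
  stopifnot(inherits(model, "cost_model"))
  if (any(is.na(wt)) || any(wt < 0)) {
    abort("`wt` must be non-negative and non-missing.",
      class = "eprocua_validation_error"
    )
  }
  model$startup_cost_eur / model$startup_pool_n +
    (model$nurse_weekly_license_eur * model$nurses_per_100_patients / 100) * wt +
    model$patient_weekly_license_eur * wt
}

#' Currency/price-year context
#'
#' Health-care costs arrive in 2019 SEK; analysis is reported in 2022 EUR.
#' Costs are first inflated within SEK (2019 to 2022) and then converted at
#' the April-2022 average exchange rate, in that order.
#'
#' @param inflation_factor_2019_to_2022 SEK inflation factor
#'   (default 1.0764).
#' @param sek_per_eur Exchange rate, SEK per EUR (default 10.3257).
#' @return A list of class `money_context`.
#' @export
money_context <- function(inflation_factor_2019_to_2022 = 1.0764,
                          sek_per_eur = 10.3257) {
  stopifnot(inflation_factor_2019_to_2022 > 0, sek_per_eur > 0)
  structure(
    list(
      inflation_factor_2019_to_2022 = inflation_factor_2019_to_2022,
      sek_per_eur = sek_per_eur
    ),
    class = "money_context"
  )
}

#' Convert 2019 SEK amounts to 2022 EUR
#'
#' @param amount_sek_2019 Amount(s) in 2019 SEK.
#' @param ctx A [money_context()].
#' @return Amount(s) in 2022 EUR.
#' @examples
#' to_eur_2022(10325.7, money_context()) # 1076.40
#' @export
to_eur_2022 <- function(amount_sek_2019, ctx = money_context()) {
  stopifnot(inherits(ctx, "money_context"))
  amount_sek_2019 * ctx$inflation_factor_2019_to_2022 / ctx$sek_per_eur
}

#' Convert 2022 EUR amounts back to 2019 SEK
#'
#' Exact algebraic inverse of [to_eur_2022()].
#' @inheritParams to_eur_2022
#' @param amount_eur_2022 Amount(s) in 2022 EUR.
#' @return Amount(s) in 2019 SEK.
#' @export
from_eur_2022 <- function(amount_eur_2022, ctx = money_context()) {
  stopifnot(inherits(ctx, "money_context"))
  amount_eur_2022 * ctx$sek_per_eur / ctx$inflation_factor_2019_to_2022
}

normalize_icd <- function(x) {
  toupper(gsub("[.[:space:]]", "", x))
}

#' ICD-10 category map for acute-care exploration
#'
#' Loads a category-to-code table used to group acute-care diagnoses into
#' clinically similar families (fever/neutropenia, gastroenteritis/colitis,
#' anemia, urinary tract infection, urinary problems, ...). A code maps to
#' at most one category: the first matching row in file order wins, so a
#' code listed under an earlier category is not re-assigned by a later one.
#'
#' @param path Path to a TSV with columns `category` and `code`; default is
#'   the map shipped with the package.
#' @return A tibble of class `icd_category_map` with columns `category` and
#'   `code` (normalized).
#' @export
icd_category_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "icd_categories.tsv", package = "eprocua")
  map <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("category", "code") %in% names(map))) {
    abort("ICD category map needs columns `category` and `code`.",
      class = "eprocua_schema_error"
    )
  }
  map$code <- normalize_icd(map$code)
  # first occurrence of a code wins
  map <- map[!duplicated(map$code), ]
  class(map) <- c("icd_category_map", class(map))
  map
}

#' Categorize ICD-10 codes
#'
#' Normalizes each code (uppercase, dots and whitespace stripped) and looks
#' it up in the category map; unmatched codes return `"uncategorized"`.
#' Swedish dialect suffix letters (e.g. `"D709C"`, `"N390X"`) are matched
#' exactly as listed.
#'
#' @param code Character vector of single ICD-10 codes.
#' @param categories An [icd_category_map()].
#' @param prefix_fallback If `TRUE`, a code with no exact match falls back
#'   to the longest listed code that is a prefix of it (off by default).
#' @return Character vector of category names.
#' @examples
#' categorize_icd(c("R50.2", "K521", "Z000"), icd_category_map())
#' @export
categorize_icd <- function(code, categories = icd_category_map(),
                           prefix_fallback = FALSE) {
  if (any(!nzchar(code) | is.na(code))) {
    abort("empty ICD code.", class = "eprocua_validation_error")
  }
  norm <- normalize_icd(code)
  idx <- match(norm, categories$code)
  out <- categories$category[idx]
  if (prefix_fallback && anyNA(idx)) {
    for (i in which(is.na(idx))) {
      hits <- categories$code[startsWith(norm[i], categories$code)]
      if (length(hits)) {
        best <- hits[which.max(nchar(hits))]
        out[i] <- categories$category[match(best, categories$code)]
      }
    }
  }
  out[is.na(out)] <- "uncategorized"
  out
}

#' Percentage of a cost total that is acute
#'
#' @param acute_total,overall_total Non-negative money amounts with
#'   `acute_total <= overall_total` and `overall_total > 0`.
#' @param digits Decimal places for reporting (default 2).
#' @return Percentage in \[0, 100\], rounded to `digits`.
#' @examples
#' acute_cost_share(2932, 9207) # 31.85
#' @export
acute_cost_share <- function(acute_total, overall_total, digits = 2) {
  if (any(overall_total <= 0)) {
    abort("overall_total must be > 0: share undefined.",
      class = "eprocua_undefined_share_error"
    )
  }
  if (any(acute_total < 0 | acute_total > overall_total)) {
    abort("need 0 <= acute_total <= overall_total.",
      class = "eprocua_validation_error"
    )
  }
  round(100 * acute_total / overall_total, digits)
}

#' Per-patient cost and visit breakdown
#'
#' Aggregates each patient's care events into 2022-EUR totals by setting
#' and acuteness, plus acute visit/cost totals per ICD category. Every
#' patient in the cohort gets a row; patients without events get zeros;
#' patients flagged `costs_missing` get `NA` cost fields (to be imputed
#' downstream by [impute_group_means()]).
#'
#' @param cohort A [cohort()] object.
#' @param ctx A [money_context()].
#' @param exclude_rt Drop radiotherapy-fraction events before aggregating.
#'   The default `"auto"` excludes them for P-RCT patients (RT there is
#'   standardized with minimal between-patient variation) and keeps
#'   everything for B-RCT. Use `TRUE`/`FALSE` to force.
#' @param categories An [icd_category_map()], or `NULL` to skip per-category
#'   columns. Category columns are computed over acute events only, the
#'   setting in which diagnosis grouping is used.
#'
#' @return A tibble keyed by `patient_id` with visit counts
#'   (`n_outpatient`, `n_inpatient`, `n_acute_outpatient`,
#'   `n_acute_inpatient`, `n_unplanned_admissions`), EUR-2022 cost totals
#'   (`outpatient_total`, `inpatient_total`, `acute_outpatient`,
#'   `acute_inpatient`, `total`, `acute_total`), and per-category
#'   `visits_<category>` / `cost_<category>` columns. An event whose codes
#'   hit two categories contributes its full cost to both (categories are
#'   exploratory, not a partition).
#' @export
patient_costs <- function(cohort, ctx = money_context(), exclude_rt = "auto",
                          categories = icd_category_map()) {
  stopifnot(inherits(cohort, "cua_cohort"))
  pts <- cohort$patients
  ev <- cohort$events
  if (identical(exclude_rt, "auto")) {
    p_ids <- pts$patient_id[pts$trial == "P_RCT"]
    drop <- ev$is_rt_fraction & ev$patient_id %in% p_ids
  } else {
    drop <- if (isTRUE(exclude_rt)) ev$is_rt_fraction else rep(FALSE, nrow(ev))
  }
  ev <- ev[!drop, , drop = FALSE]
  ev$cost_eur <- to_eur_2022(ev$cost_sek_2019, ctx)

  base <- ev |>
    group_by(.data$patient_id) |>
    summarize(
      n_outpatient = sum(.data$setting == "outpatient"),
      n_inpatient = sum(.data$setting == "inpatient"),
      n_acute_outpatient = sum(.data$acute & .data$setting == "outpatient"),
      n_acute_inpatient = sum(.data$acute & .data$setting == "inpatient"),
      n_unplanned_admissions = sum(.data$unplanned_admission),
      outpatient_total = sum(.data$cost_eur[.data$setting == "outpatient"]),
      inpatient_total = sum(.data$cost_eur[.data$setting == "inpatient"]),
      acute_outpatient = sum(.data$cost_eur[.data$acute & .data$setting == "outpatient"]),
      acute_inpatient = sum(.data$cost_eur[.data$acute & .data$setting == "inpatient"]),
      .groups = "drop"
    ) |>
    mutate(
      total = .data$outpatient_total + .data$inpatient_total,
      acute_total = .data$acute_outpatient + .data$acute_inpatient
    )

  out <- tibble(patient_id = pts$patient_id) |>
    left_join(base, by = "patient_id")
  num_cols <- setdiff(names(out), "patient_id")
  out <- out |>
    mutate(across(all_of(num_cols), ~ tidyr::replace_na(.x, 0)))

  if (!is.null(categories)) {
    acute_ev <- ev[ev$acute & nzchar(ev$icd_codes), , drop = FALSE]
    cat_names <- unique(categories$category)
    if (nrow(acute_ev)) {
      cat_tbl <- acute_ev |>
        mutate(.event = dplyr::row_number()) |>
        tidyr::separate_longer_delim("icd_codes", delim = ";") |>
        mutate(category = categorize_icd(.data$icd_codes, categories)) |>
        filter(.data$category != "uncategorized") |>
        distinct(.data$patient_id, .data$.event, .data$cost_eur, .data$category) |>
        group_by(.data$patient_id, .data$category) |>
        summarize(
          visits = dplyr::n(),
          cost = sum(.data$cost_eur),
          .groups = "drop"
        )
      wide <- cat_tbl |>
        tidyr::pivot_wider(
          names_from = "category",
          values_from = c("visits", "cost"),
          names_glue = "{.value}_{category}",
          values_fill = 0
        )
      out <- left_join(out, wide, by = "patient_id")
    }
    for (cn in cat_names) {
      for (pref in c("visits_", "cost_")) {
        col <- paste0(pref, cn)
        if (!col %in% names(out)) out[[col]] <- 0
        out[[col]][is.na(out[[col]])] <- 0
      }
    }
  }

  if (any(pts$costs_missing)) {
    na_cols <- setdiff(names(out), "patient_id")
    out[match(pts$patient_id[pts$costs_missing], out$patient_id), na_cols] <- NA
  }
  out
}
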