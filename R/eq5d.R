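eq5d_dimension_names <- function() {
  c("mobility", "self_care", "usual_activities", "pain_discomfort", "anxiety_depression")
}

#' Read a QLQ-C30 to EQ-5D-3L response-mapping model
#'
#' A response-mapping model predicts, for each of the five EQ-5D-3L
#' dimensions, the probabilities of answering at levels 1-3 from a
#' patient's QLQ-C30 dimension scores, via a multinomial logit: level 1 is
#' the reference (linear predictor 0) and levels 2 and 3 each have an
#' intercept plus coefficients on named QLQ-C30 scores (0-100 scale), with
#' `P(level L) = exp(eta_L) / sum_k exp(eta_k)`.
#'
#' The published mapping coefficients are not redistributable here, so the
#' package ships a synthetic coefficient file with the same structure
#' (`mapping_model_synthetic.json`), adequate for testing and simulation;
#' substitute a published coefficient file for real analyses.
#'
#' @param path Path to a JSON model file; default is the synthetic fixture.
#' @return An object of class `mapping_model`: list with `name` and
#'   `dimensions`, each dimension holding per-level named coefficient
#'   vectors (element `"(Intercept)"` plus QLQ dimension codes).
#' @export
read_mapping_model <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mapping_model_synthetic.json",
    package = "eprocua"
  )
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- raw$dimensions
  missing_d <- setdiff(eq5d_dimension_names(), names(dims))
  if (length(missing_d)) {
    abort(
      paste0(
        "mapping model is missing EQ-5D dimension(s): ",
        paste(missing_d, collapse = ", ")
      ),
      class = "eprocua_config_error"
    )
  }
  dims <- purrr::map(dims, function(d) {
    purrr::map(d, ~ unlist(.x))
  })
  structure(
    list(name = raw$name %||% basename(path), dimensions = dims),
    class = "mapping_model"
  )
}

#' @export
print.mapping_model <- function(x, ...) {
  cat("<mapping_model> ", x$name, " (5 EQ-5D dimensions, levels 2-3 vs 1)\n", sep = "")
  invisible(x)
}

#' Map QLQ-C30 scores to EQ-5D-3L response probabilities
#'
#' @param scores A data frame of QLQ-C30 dimension scores (columns named as
#'   in [qlq_dimensions()]; one row per patient) or a single named vector.
#'   Scores needed by the model must be non-missing: imputation happens
#'   upstream.
#' @param model A [read_mapping_model()] object.
#' @return A tibble of class `eq5d_response_dist` with columns `.row`
#'   (input row), `dimension`, `p1`, `p2`, `p3`; each probability triple is
#'   non-negative and sums to 1.
#' @export
map_scores_to_response_probs <- function(scores, model = read_mapping_model()) {
  stopifnot(inherits(model, "mapping_model"))
  if (is.numeric(scores) && is.null(dim(scores))) {
    scores <- as_tibble(as.list(scores))
  }
  scores <- as_tibble(scores)
  n <- nrow(scores)
  out <- purrr::imap(model$dimensions, function(levels, dim_name) {
    eta <- purrr::map(c(l2 = "2", l3 = "3"), function(lv) {
      beta <- levels[[lv]]
      if (is.null(beta)) {
        abort(
          paste0("mapping model dimension ", dim_name, " lacks level ", lv),
          class = "eprocua_config_error"
        )
      }
      covars <- setdiff(names(beta), "(Intercept)")
      missing_c <- setdiff(covars, names(scores))
      if (length(missing_c)) {
        abort(
          paste0(
            "scores lack model covariate(s): ",
            paste(missing_c, collapse = ", ")
          ),
          class = "eprocua_config_error"
        )
      }
      sub <- scores[covars]
      if (anyNA(sub)) {
        abort("missing QLQ scores at mapping time; impute upstream.",
          class = "eprocua_validation_error"
        )
      }
      x <- as.matrix(sub)
      drop(beta[["(Intercept)"]] + x %*% beta[covars])
    })
    # softmax with eta_1 = 0, guarded against overflow
    m <- pmax(0, eta$l2, eta$l3)
    e1 <- exp(-m)
    e2 <- exp(eta$l2 - m)
    e3 <- exp(eta$l3 - m)
    z <- e1 + e2 + e3
    tibble(
      .row = seq_len(n), dimension = dim_name,
      p1 = e1 / z, p2 = e2 / z, p3 = e3 / z
    )
  })
  res <- dplyr::bind_rows(out) |> arrange(.data$.row)
  class(res) <- c("eq5d_response_dist", class(res))
  res
}

#' Read an EQ-5D-3L value set (tariff)
#'
#' A value set converts an EQ-5D-3L profile to a utility on the dead = 0,
#' full health = 1 scale, as an additive decrement table: a full-health
#' anchor, decrements per dimension for levels 2 and 3, and optional extra
#' terms (`any_dysfunction`: subtracted once if any dimension is above
#' level 1; `any_level3`: subtracted once if any dimension is at level 3).
#'
#' The file is a TSV with columns `dimension`, `level`, `decrement`;
#' reserved dimension names `anchor`, `any_dysfunction` and `any_level3`
#' carry the anchor and extra terms (their `level` is ignored). The package
#' ships the British time-trade-off tariff (`value_set_uk.tsv`) and a
#' synthetic Swedish-style experience-based set with the milder decrements
#' typical of that system (`value_set_swedish_style_synthetic.tsv`).
#'
#' @param path Path to a TSV file; default is the British tariff fixture.
#' @return An object of class `value_set`: list with `name`, `anchor`,
#'   `any_dysfunction`, `any_level3` and a 5 x 2 `decrements` matrix
#'   (rows = dimensions, columns = levels 2 and 3).
#' @export
read_value_set <- function(path = NULL) {
  path <- path %||% system.file("extdata", "value_set_uk.tsv", package = "eprocua")
  tbl <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  stopifnot(all(c("dimension", "level", "decrement") %in% names(tbl)))
  get1 <- function(nm, default = 0) {
    v <- tbl$decrement[tbl$dimension == nm]
    if (length(v)) v[1] else default
  }
  dec <- matrix(0,
    nrow = 5, ncol = 2,
    dimnames = list(eq5d_dimension_names(), c("2", "3"))
  )
  for (d in eq5d_dimension_names()) {
    for (lv in c("2", "3")) {
      v <- tbl$decrement[tbl$dimension == d & tbl$level == lv]
      if (length(v) != 1) {
        abort(
          paste0("value set lacks a decrement for ", d, " level ", lv),
          class = "eprocua_config_error"
        )
      }
      dec[d, lv] <- v
    }
  }
  if (any(dec < 0)) {
    abort("value-set decrements must be >= 0.", class = "eprocua_validation_error")
  }
  structure(
    list(
      name = attr(path, "name") %||% basename(path),
      anchor = get1("anchor", 1),
      any_dysfunction = get1("any_dysfunction", 0),
      any_level3 = get1("any_level3", 0),
      decrements = dec
    ),
    class = "value_set"
  )
}

#' @export
print.value_set <- function(x, ...) {
  cat("<value_set> ", x$name, ": anchor ", x$anchor,
    ", any-dysfunction ", x$any_dysfunction,
    ", any-level-3 ", x$any_level3, "\n",
    sep = ""
  )
  invisible(x)
}

#' Utility of a deterministic EQ-5D-3L profile
#'
#' @param profile Integer vector of 5 levels in 1..3, ordered as
#'   `eq5d_dimension_names()` (e.g. `c(1, 1, 1, 1, 1)` = full health), or a
#'   5-column matrix of profiles.
#' @param values A [read_value_set()] object.
#' @return Utility (vector if `profile` is a matrix).
#' @export
profile_utility <- function(profile, values) {
  stopifnot(inherits(values, "value_set"))
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  stopifnot(ncol(profile) == 5, all(profile %in% 1:3))
  dec <- values$decrements
  u <- rep(values$anchor, nrow(profile))
  for (d in 1:5) {
    u <- u - ifelse(profile[, d] == 2, dec[d, "2"],
      ifelse(profile[, d] == 3, dec[d, "3"], 0)
    )
  }
  u <- u - values$any_dysfunction * (rowSums(profile > 1) > 0)
  u <- u - values$any_level3 * (rowSums(profile == 3) > 0)
  u
}

#' Expected EQ-5D utility (EQ-5DP) from a response distribution
#'
#' The default `"expected"` rule is the probability-weighted utility: from
#' the anchor, subtract each dimension-level decrement weighted by its
#' response probability; extra value-set terms (any-dysfunction,
#' any-level-3 constants) are weighted by their joint probability computed
#' under independence across dimensions. The `"modal"` rule instead values
#' the most-likely profile exactly.
#'
#' @param dist An [map_scores_to_response_probs()] result (columns `.row`,
#'   `dimension`, `p1`, `p2`, `p3`).
#' @param values A [read_value_set()] object.
#' @param rule `"expected"` (default) or `"modal"`.
#' @return Numeric vector of utilities, one per input row.
#' @export
expected_utility <- function(dist, values, rule = c("expected", "modal")) {
  stopifnot(inherits(values, "value_set"))
  rule <- match.arg(rule)
  dims <- eq5d_dimension_names()
  rows <- sort(unique(dist$.row))
  p <- array(NA_real_, dim = c(length(rows), 5, 3))
  for (j in seq_along(dims)) {
    sub <- dist[dist$dimension == dims[j], ]
    sub <- sub[match(rows, sub$.row), ]
    p[, j, 1] <- sub$p1
    p[, j, 2] <- sub$p2
    p[, j, 3] <- sub$p3
  }
  if (anyNA(p)) {
    abort("response distribution does not cover all 5 dimensions.",
      class = "eprocua_config_error"
    )
  }
  if (rule == "modal") {
    prof <- apply(p, c(1, 2), which.max)
    return(profile_utility(prof, values))
  }
  dec <- values$decrements
  u <- rep(values$anchor, length(rows))
  for (j in 1:5) {
    u <- u - p[, j, 2] * dec[j, "2"] - p[, j, 3] * dec[j, "3"]
  }
  p_all_l1 <- apply(p[, , 1, drop = FALSE], 1, prod)
  p_no_l3 <- apply(1 - p[, , 3, drop = FALSE], 1, prod)
  u - values$any_dysfunction * (1 - p_all_l1) - values$any_level3 * (1 - p_no_l3)
}

#' Map QLQ-C30 scores straight to EQ-5DP utilities
#'
#' Convenience composition of [map_scores_to_response_probs()] and
#' [expected_utility()].
#'
#' @inheritParams map_scores_to_response_probs
#' @inheritParams expected_utility
#' @return Numeric vector of EQ-5DP utilities, one per row of `scores`.
#' @export
eq5dp <- function(scores, model = read_mapping_model(),
                  values = read_value_set(), rule = c("expected", "modal")) {
  expected_utility(map_scores_to_response_probs(scores, model), values, rule)
}

#' Change in EQ-5DP over treatment
#'
#' Returns `after - before`, so a negative change is a deterioration.
#' (Report-layer tables may present before-minus-after; the sign convention
#' here keeps "less utility lost" positive.)
#'
#' @param before,after EQ-5DP utilities (vectorized).
#' @return `after - before`.
#' @examples
#' eq5dp_change(0.86, 0.84) # -0.02
#' @export
eq5dp_change <- function(before, after) {
  after - before
}
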