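#' Pearson overdispersion statistic of a fitted count model
#'
#' Pearson chi-squared divided by the residual degrees of freedom: the sum
#' of squared (observed - fitted) over the model variance, divided by
#' `df.residual`. Values near 1 indicate the Poisson variance assumption
#' holds; values well above 1 indicate overdispersion.
#'
#' @param fit A fitted `glm` (Poisson, negative binomial or binomial).
#' @return Pearson chi-squared / df (0 for a perfect fit).
#' @export
overdispersion_statistic <- function(fit) {
  df <- df.residual(fit)
  if (is.null(df) || df <= 0) {
    abort("model has no residual degrees of freedom.",
      class = "eprocua_validation_error"
    )
  }
  sum(residuals(fit, type = "pearson")^2) / df
}

#' Choose a regression family from the outcome kind and overdispersion
#'
#' Binary outcomes always get logistic regression. Count (and rounded
#' cost) outcomes get Poisson unless the Pearson chi-squared/df exceeds the
#' threshold, in which case negative binomial is used.
#'
#' @param kind `"count"`, `"binary"` or `"cost"`.
#' @param dispersion Pearson chi-squared / df from a Poisson fit (ignored
#'   for binary outcomes).
#' @param threshold Overdispersion cutoff (default 1.5).
#' @return `"logistic"`, `"poisson"` or `"negative_binomial"`.
#' @examples
#' select_model_family("count", 1.0) # "poisson"
#' select_model_family("count", 2.0) # "negative_binomial"
#' @export
select_model_family <- function(kind = c("count", "binary", "cost"),
                                dispersion = NULL, threshold = 1.5) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    return("logistic")
  }
  if (is.null(dispersion) || dispersion < 0) {
    abort("`dispersion` must be a non-negative number.",
      class = "eprocua_validation_error"
    )
  }
  if (dispersion > threshold) "negative_binomial" else "poisson"
}

#' Fit an exploratory utilization regression
#'
#' Regresses a per-patient utilization outcome (visit counts, a binary
#' had-a-visit indicator, or costs) on trial arm and patient covariates:
#' age, Charlson comorbidity score, baseline EQ-5DP and (breast trial only)
#' number of chemotherapy cycles. Count and cost outcomes use a log link
#' (cost values are rounded to whole EUR and treated as counts by default,
#' with a gamma-log alternative); the family is chosen by the
#' overdispersion rule of [select_model_family()] unless forced.
#'
#' @param data Per-patient data frame: the outcome column, `arm`, and the
#'   covariate columns. Rows with missing values are an error; impute
#'   upstream.
#' @param outcome Name of the outcome column.
#' @param kind `"count"`, `"binary"` or `"cost"`.
#' @param covariates Covariate column names (besides the arm term).
#' @param family `NULL` (auto by overdispersion), `"poisson"`,
#'   `"negative_binomial"`, `"logistic"` or `"gamma"` (cost outcomes).
#' @param reference Arm coded 0 (default `"control"`, so the group
#'   coefficient is the intervention effect; flip to reproduce tables coded
#'   the other way).
#' @param dispersion_threshold Cutoff for the auto family choice.
#'
#' @return An object of class `utilization_fit` wrapping the `glm` fit,
#'   with [tidy()] (per term: `estimate` B, `std.error`, `exp_b`, Wald 95%
#'   CI on the exp scale, `p.value`) and [glance()] (family used, Pearson
#'   chi-squared/df, omnibus likelihood-ratio p-value, convergence flag).
#' @export
fit_utilization_glm <- function(data, outcome, kind = c("count", "binary", "cost"),
                                covariates = c("age_years", "charlson_score", "eq5dp_baseline"),
                                family = NULL,
                                reference = c("control", "intervention"),
                                dispersion_threshold = 1.5) {
  kind <- match.arg(kind)
  reference <- match.arg(reference)
  data <- as_tibble(data)
  need <- c(outcome, "arm", covariates)
  missing_c <- setdiff(need, names(data))
  if (length(missing_c)) {
    abort(
      paste0("missing column(s): ", paste(missing_c, collapse = ", ")),
      class = "eprocua_schema_error"
    )
  }
  if (any(!complete.cases(data[need]))) {
    abort("missing values in outcome or covariates; impute upstream.",
      class = "eprocua_validation_error"
    )
  }
  d <- data[need]
  d$group <- as.numeric(d$arm != reference)
  y <- d[[outcome]]
  if (kind %in% c("count", "cost")) {
    # group-mean imputation can leave non-integer values; Poisson/NB
    # likelihoods need whole numbers (gamma-log takes costs as-is)
    if (!identical(family, "gamma")) d[[outcome]] <- round(y)
    if (any(d[[outcome]] < 0)) {
      abort("count/cost outcomes must be non-negative.",
        class = "eprocua_validation_error"
      )
    }
  } else if (!all(y %in% c(0, 1))) {
    abort("binary outcome must be 0/1.", class = "eprocua_validation_error")
  }

  fml <- stats::as.formula(paste(
    outcome, "~ group +", paste(covariates, collapse = " + ")
  ))

  dispersion_poisson <- NA_real_
  if (kind == "binary") {
    family_used <- "logistic"
  } else if (is.null(family)) {
    pois <- glm(fml, data = d, family = poisson())
    dispersion_poisson <- overdispersion_statistic(pois)
    family_used <- select_model_family(kind, dispersion_poisson, dispersion_threshold)
  } else {
    family_used <- family
  }

  flags <- character(0)
  fit <- switch(family_used,
    poisson = glm(fml, data = d, family = poisson()),
    logistic = glm(fml, data = d, family = binomial()),
    gamma = glm(fml, data = d, family = stats::Gamma(link = "log")),
    negative_binomial = tryCatch(
      suppressWarnings(MASS::glm.nb(fml, data = d)),
      error = function(e) {
        flags <<- c(flags, paste0("nb_fallback_poisson: ", conditionMessage(e)))
        glm(fml, data = d, family = poisson())
      }
    ),
    abort(paste0("unknown family: ", family_used), class = "eprocua_config_error")
  )
  if (!isTRUE(fit$converged)) flags <- c(flags, "non_convergence")
  if (family_used == "logistic") {
    p_hat <- fitted(fit)
    if (any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8)) {
      flags <- c(flags, "possible_separation")
    }
  }

  null_fit <- stats::update(fit, . ~ 1)
  lr <- as.numeric(2 * (logLik(fit) - logLik(null_fit)))
  omnibus_p <- pchisq(max(lr, 0),
    df = length(coef(fit)) - 1, lower.tail = FALSE
  )

  structure(
    list(
      fit = fit, outcome = outcome, kind = kind,
      family = family_used, reference = reference,
      dispersion_poisson = dispersion_poisson,
      pearson_chisq_df = overdispersion_statistic(fit),
      omnibus_p = omnibus_p, flags = flags
    ),
    class = "utilization_fit"
  )
}

#' @export
print.utilization_fit <- function(x, ...) {
  cat("<utilization_fit> ", x$outcome, " (", x$kind, "), family ", x$family,
    ", Pearson chi2/df ", sprintf("%.3f", x$pearson_chisq_df),
    ", omnibus p ", format.pval(x$omnibus_p, digits = 3), "\n",
    sep = ""
  )
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.utilization_fit <- function(x, conf.level = 0.95, ...) {
  b <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- qnorm(1 - (1 - conf.level) / 2)
  p <- 2 * pnorm(-abs(b / se))
  tibble(
    term = names(b),
    estimate = unname(b),
    std.error = unname(se),
    exp_b = exp(unname(b)),
    conf.low = exp(unname(b - z * se)),
    conf.high = exp(unname(b + z * se)),
    p.value = unname(p)
  )
}

#' @export
glance.utilization_fit <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    kind = x$kind,
    family = x$family,
    n = length(x$fit$y),
    dispersion_poisson = x$dispersion_poisson,
    pearson_chisq_df = x$pearson_chisq_df,
    omnibus_p = x$omnibus_p,
    converged = isTRUE(x$fit$converged),
    flags = paste(x$flags, collapse = ";")
  )
}
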