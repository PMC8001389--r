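# Development-time analysis: per-condition summaries, Poisson log-link
# regression with Type-II analysis of deviance, Tukey HSD letter groupings
# on the linear-predictor scale, and colour-stage duration summaries.

#' Summarise development time per condition
#'
#' Mean, standard error and n of hatch age per condition, over eggs that
#' completed development (hatched) only. Conditions with no hatched eggs are
#' absent from the summary rather than reported as zero.
#'
#' @param fates Per-egg fate tibble.
#' @param by Character vector of grouping columns.
#' @return A tibble with the grouping columns plus `mean_days`, `se_days`,
#'   `n`.
#' @export
#' @examples
#' fates <- simulate_experiment(clusters_per_condition = 3, seed = 2)$fates
#' summarize_development(fates)
summarize_development <- function(fates, by = c("temperature_c", "rh_regime")) {
  validate_fates(fates) %>%
    filter(.data$outcome == "hatched") %>%
    group_by(across(all_of(by))) %>%
    summarise(
      mean_days = mean(.data$event_age_days),
      se_days = sd(.data$event_age_days) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Poisson regression of development time
#'
#' Fits duration (integer days) against experimental factors with a Poisson
#' log-link GLM (IRLS to deviance convergence 1e-8), and computes per-term
#' likelihood-ratio chi-squares by Type-II analysis of deviance (each term
#' tested against the model containing all other terms of equal or lower
#' order). Durations in whole days are treated as Poisson counts; the
#' deviance/df dispersion is reported as a diagnostic but not corrected.
#'
#' @param fates Per-egg fate tibble, or any data frame holding the model
#'   variables. Only hatched eggs enter the fit when `fates` carries an
#'   `outcome` column.
#' @param formula Model formula, or `NULL` (default) for hatch age on
#'   temperature (as a factor), RH regime and their interaction; factors
#'   without variation in the data are dropped from the default.
#' @return An object of class `duration_glm`: a list with the fitted `glm`
#'   (`$fit`), the Type-II analysis-of-deviance tibble (`$anova`: `term`,
#'   `chi2`, `df`, `p_value`), the dispersion estimate, and per-cell fitted
#'   means (`$fitted_means`). Use [tidy()] / [glance()] to extract tidy
#'   summaries.
#' @export
#' @examples
#' fates <- simulate_experiment(clusters_per_condition = 3, seed = 2)$fates
#' fit <- fit_duration_glm(fates)
#' tidy(fit)
fit_duration_glm <- function(fates, formula = NULL) {
  data <- as_tibble(fates)
  if ("outcome" %in% names(data)) {
    data <- data %>% filter(.data$outcome == "hatched")
  }
  if (is.null(formula)) {
    # default: temperature x RH factorial, dropping factors without
    # variation so single-regime (or single-temperature) data still fit
    terms <- c(
      if (dplyr::n_distinct(data$temperature_c) > 1) "factor(temperature_c)",
      if (dplyr::n_distinct(data$rh_regime) > 1) "rh_regime"
    )
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " * ")
    formula <- stats::as.formula(paste("event_age_days ~", rhs))
  }
  response <- all.vars(formula)[1]
  y <- data[[response]]
  if (is.null(y)) abort(sprintf("Response column %s not found.", response))
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y))) {
    abort("Response must be non-negative integer days.",
          class = "eggtherm_input_error")
  }
  data <- droplevels(data)
  fit <- glm(formula, family = poisson(link = "log"), data = data,
             control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    abort("Poisson GLM did not converge within 100 IRLS iterations.",
          class = "eggtherm_convergence_error")
  }

  aod <- car::Anova(fit, type = 2, test.statistic = "LR")
  anova_tbl <- tibble(
    term = rownames(aod),
    chi2 = aod[["LR Chisq"]],
    df = as.integer(aod[["Df"]]),
    p_value = aod[["Pr(>Chisq)"]]
  )

  cells <- data %>%
    distinct(across(all_of(setdiff(all.vars(formula), response))))
  cells$fitted_mean_days <- as.numeric(
    predict(fit, newdata = cells, type = "response")
  )

  structure(
    list(
      fit = fit,
      formula = formula,
      anova = anova_tbl,
      dispersion = fit$deviance / fit$df.residual,
      fitted_means = cells,
      data = data
    ),
    class = "duration_glm"
  )
}

#' @export
print.duration_glm <- function(x, ...) {
  cat("Poisson log-link development-time model\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d, residual deviance = %.2f on %d df (dispersion %.2f)\n",
              stats::nobs(x$fit), x$fit$deviance, x$fit$df.residual,
              x$dispersion))
  cat("Type-II analysis of deviance:\n")
  print(as.data.frame(x$anova), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_duration_glm
#' @param x,object A `duration_glm` object.
#' @param ... Unused.
#' @method tidy duration_glm
#' @export
tidy.duration_glm <- function(x, ...) x$anova

#' @rdname fit_duration_glm
#' @method glance duration_glm
#' @export
glance.duration_glm <- function(x, ...) {
  tibble(
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    df_residual = x$fit$df.residual,
    dispersion = x$dispersion,
    AIC = stats::AIC(x$fit),
    nobs = stats::nobs(x$fit)
  )
}

#' Tukey HSD groupings of factor levels
#'
#' All pairwise comparisons of level means on the linear-predictor (log)
#' scale, using studentized-range critical values at the model's residual
#' degrees of freedom, followed by a compact letter display built greedily
#' from the sorted means. Levels sharing a letter are not significantly
#' different at `alpha`. For a Poisson log-link model the level mean on the
#' linear-predictor scale is `log(mean(y))` with variance `1 / sum(y)`.
#'
#' @param fit A [fit_duration_glm()] object.
#' @param factor Name of a factor column used in the model.
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `posthoc_groups`: `level`, `mean_days`,
#'   `letters`, ordered by increasing mean.
#' @export
posthoc_groups <- function(fit, factor, alpha = 0.05) {
  stopifnot(inherits(fit, "duration_glm"), alpha > 0, alpha < 1)
  data <- fit$data
  if (!factor %in% names(data)) {
    abort(sprintf("Factor %s not found in the model data.", factor))
  }
  f <- droplevels(as.factor(data[[factor]]))
  if (nlevels(f) < 2) {
    abort(sprintf("Factor %s has fewer than two observed levels.", factor))
  }
  response <- all.vars(fit$formula)[1]
  y <- data[[response]]

  stats_tbl <- tibble(level = levels(f)) %>%
    mutate(
      total = vapply(.data$level, function(l) sum(y[f == l]), numeric(1)),
      n = vapply(.data$level, function(l) sum(f == l), numeric(1)),
      m = log(.data$total / .data$n),   # linear-predictor scale
      se = sqrt(1 / .data$total)
    )
  k <- nrow(stats_tbl)
  df_resid <- fit$fit$df.residual
  qcrit <- qtukey(1 - alpha, nmeans = k, df = df_resid)

  ord <- order(stats_tbl$m)
  m <- stats_tbl$m[ord]
  se <- stats_tbl$se[ord]
  different <- function(i, j) {
    abs(m[i] - m[j]) / sqrt(se[i]^2 + se[j]^2) > qcrit / sqrt(2)
  }

  # maximal runs of consecutive (sorted) levels whose extremes do not differ
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !different(i, j + 1)) j <- j + 1
    covered <- any(vapply(runs, function(r) i >= r[1] && j <= r[2],
                          logical(1)))
    if (!covered) runs[[length(runs) + 1]] <- c(i, j)
  }
  letter_mat <- vapply(seq_along(runs), function(g) {
    r <- runs[[g]]
    seq_len(k) >= r[1] & seq_len(k) <= r[2]
  }, logical(k))
  letter_mat <- matrix(letter_mat, nrow = k)
  labels <- vapply(seq_len(k), function(i) {
    paste(letters[which(letter_mat[i, ])], collapse = "")
  }, character(1))

  out <- tibble(
    level = stats_tbl$level[ord],
    mean_days = exp(m),
    letters = labels
  )
  class(out) <- c("posthoc_groups", class(out))
  out
}

#' Colour-stage duration summaries
#'
#' Mean duration of the yellow, brown and head-capsule (blackhead) stages
#' per condition, over hatched eggs carrying stage durations. Per egg the
#' three stages partition the total development time, so the stage means sum
#' exactly to the mean hatch age.
#'
#' @inheritParams summarize_development
#' @return A tibble with the grouping columns plus `mean_yellow`,
#'   `mean_brown`, `mean_blackhead`, `mean_total`, `n`; zero rows (with a
#'   warning) when no stage data are available.
#' @export
colour_stage_durations <- function(fates, by = c("temperature_c", "rh_regime")) {
  fates <- validate_fates(fates) %>%
    filter(.data$outcome == "hatched", !is.na(.data$d_yellow))
  if (nrow(fates) == 0) {
    warn("No per-egg colour-stage durations available.")
    return(tibble(temperature_c = numeric(0), rh_regime = character(0),
                  mean_yellow = numeric(0), mean_brown = numeric(0),
                  mean_blackhead = numeric(0), mean_total = numeric(0),
                  n = integer(0)))
  }
  fates %>%
    group_by(across(all_of(by))) %>%
    summarise(
      mean_yellow = mean(.data$d_yellow),
      mean_brown = mean(.data$d_brown),
      mean_blackhead = mean(.data$d_blackhead),
      mean_total = mean(.data$event_age_days),
      n = dplyr::n(),
      .groups = "drop"
    )
}
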