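# Product-limit survival estimation and log-rank tests, implemented from
# first principles. The event is death of the egg; hatching leaves the egg
# stage alive, so hatched (and horizon-censored) eggs are right-censored at
# their event age. Deaths are processed before censorings at tied ages
# (standard risk-set convention: both are still at risk at the tied age).

# Core product-limit estimate on integer event ages.
km_core <- function(time, is_death) {
  times <- sort(unique(time))
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(time == t & is_death), numeric(1))
  n_censor <- vapply(times, function(t) sum(time == t & !is_death), numeric(1))
  tibble(
    time = times,
    n_risk = n_risk,
    n_event = n_event,
    n_censor = n_censor,
    estimate = cumprod(1 - n_event / n_risk)
  )
}

group_key <- function(fates, by) {
  missing <- setdiff(by, names(fates))
  if (length(missing) > 0) {
    abort(sprintf("Grouping column(s) not found: %s.",
                  paste(missing, collapse = ", ")))
  }
  interaction(fates[by], drop = TRUE, sep = "/", lex.order = TRUE)
}

#' Kaplan-Meier survival curves for egg cohorts
#'
#' Estimates the age-specific survival rate lx (the probability at laying of
#' being alive at age x) per group by the product-limit method. Death is the
#' event; hatched and censored eggs are right-censored at their event age.
#'
#' @param fates Per-egg fate tibble (from [derive_fates()] or
#'   [simulate_experiment()]).
#' @param by Character vector of grouping columns (default: condition).
#' @return A tibble of class `km_curves` with the grouping columns plus
#'   `time` (age, days), `n_risk`, `n_event`, `n_censor` and `estimate`
#'   (lx); `estimate` is non-increasing within each group and equals 1
#'   before the first death.
#' @seealso [logrank_test()], [plot_survival()]
#' @export
#' @examples
#' fates <- simulate_experiment(design_conditions(24),
#'                              clusters_per_condition = 5,
#'                              seed = 7)$fates
#' kaplan_meier(fates)
kaplan_meier <- function(fates, by = c("temperature_c", "rh_regime")) {
  fates <- validate_fates(fates)
  key <- group_key(fates, by)
  if (any(table(key) < 1)) abort("Each group needs at least one egg.")
  curves <- fates %>%
    group_by(across(all_of(by))) %>%
    group_split() %>%
    purrr::map(function(g) {
      res <- km_core(g$event_age_days, g$outcome == "died")
      for (col in by) res[[col]] <- g[[col]][1]
      res
    }) %>%
    bind_rows() %>%
    select(all_of(by), "time", "n_risk", "n_event", "n_censor", "estimate")
  class(curves) <- c("km_curves", class(curves))
  curves
}

# k-sample log-rank machinery on raw vectors; returns chi2 and df.
logrank_core <- function(time, is_death, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2) abort("Log-rank test needs at least two groups.")
  death_times <- sort(unique(time[is_death]))
  if (length(death_times) == 0) {
    return(list(chi2 = 0, df = k - 1))
  }
  O <- numeric(k)
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in death_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    if (n < 1) next
    n_i <- tabulate(group[at_risk], nbins = k)
    d_i <- tabulate(group[at_risk & time == t & is_death], nbins = k)
    d <- sum(d_i)
    O <- O + d_i
    E <- E + d * n_i / n
    if (n > 1) {
      p_i <- n_i / n
      V <- V + d * (n - d) / (n - 1) * (diag(p_i, k) - tcrossprod(p_i))
    }
  }
  U <- (O - E)[-k]
  V11 <- V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(
    drop(t(U) %*% solve(V11, U)),
    error = function(e) drop(t(U) %*% MASS::ginv(V11) %*% U)
  )
  list(chi2 = max(0, chi2), df = k - 1)
}

#' k-sample log-rank test
#'
#' Compares survival curves across groups with the standard log-rank
#' statistic: at each distinct death age, observed minus expected deaths per
#' group under the hypergeometric model; the quadratic form uses the
#' covariance of `k - 1` groups (a generalized inverse is used if that
#' block is singular). With zero deaths the statistic is 0 and p = 1.
#'
#' @inheritParams kaplan_meier
#' @return A one-row tibble: `chi2`, `df` (`k - 1`), `p_value`, `n_groups`,
#'   `n_events`.
#' @export
#' @examples
#' fates <- simulate_experiment(design_conditions(c(8, 32)),
#'                              clusters_per_condition = 5,
#'                              seed = 7)$fates
#' logrank_test(fates)              # 6 groups, df = 5
#' logrank_test(fates, by = "rh_regime")
logrank_test <- function(fates, by = c("temperature_c", "rh_regime")) {
  fates <- validate_fates(fates)
  key <- group_key(fates, by)
  res <- logrank_core(fates$event_age_days, fates$outcome == "died", key)
  tibble(
    chi2 = res$chi2,
    df = res$df,
    p_value = pchisq(res$chi2, res$df, lower.tail = FALSE),
    n_groups = res$df + 1L,
    n_events = sum(fates$outcome == "died")
  )
}

#' Pairwise two-group log-rank tests
#'
#' One two-group log-rank test (df = 1) per unordered pair of groups, with
#' raw unadjusted p-values.
#'
#' @inheritParams kaplan_meier
#' @return A tibble with `group1`, `group2`, `chi2`, `df`, `p_value`.
#' @export
pairwise_logrank <- function(fates, by = "rh_regime") {
  fates <- validate_fates(fates)
  key <- group_key(fates, by)
  levels_ <- levels(key)
  if (length(levels_) < 2) abort("Need at least two groups.")
  pairs <- utils::combn(levels_, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    sel <- key %in% p
    res <- logrank_core(fates$event_age_days[sel],
                        fates$outcome[sel] == "died",
                        key[sel])
    tibble(group1 = p[1], group2 = p[2], chi2 = res$chi2, df = res$df,
           p_value = pchisq(res$chi2, res$df, lower.tail = FALSE))
  }) %>% bind_rows()
}

#' Per-temperature log-rank comparison of RH regimes
#'
#' For each temperature: the overall 3-regime log-rank plus the three
#' pairwise regime comparisons, the standard summary table of a
#' temperature x RH survival experiment.
#'
#' @inheritParams kaplan_meier
#' @return A tibble with `temperature_c`, `comparison`, `chi2`, `df`,
#'   `p_value`.
#' @export
logrank_by_temperature <- function(fates) {
  fates <- validate_fates(fates)
  fates %>%
    group_by(.data$temperature_c) %>%
    group_split() %>%
    purrr::map(function(g) {
      overall <- logrank_test(g, by = "rh_regime") %>%
        mutate(comparison = sprintf("%d RH", .data$n_groups)) %>%
        select("comparison", "chi2", "df", "p_value")
      pw <- pairwise_logrank(g, by = "rh_regime") %>%
        mutate(comparison = sprintf("%s vs. %s", .data$group1, .data$group2)) %>%
        select("comparison", "chi2", "df", "p_value")
      bind_rows(overall, pw) %>%
        mutate(temperature_c = g$temperature_c[1], .before = 1)
    }) %>%
    bind_rows()
}
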