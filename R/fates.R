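#' Derive per-egg fates from daily cluster observations
#'
#' Converts a validated daily cluster table into one record per egg. An egg
#' whose cumulative hatched count increments between ages `t - 1` and `t`
#' hatched at age `t` (first detection); likewise for deaths. Eggs still
#' alive at the observation horizon are right-censored there. Events are
#' recorded at daily resolution because cages are examined at daily
#' intervals; sub-day timing is unobservable.
#'
#' Cluster-level colour counts do not identify which egg was in which stage,
#' so `stage_durations` (`d_yellow`, `d_brown`, `d_blackhead`) are `NA` here;
#' they are populated when per-egg ground truth is available (e.g. from
#' [simulate_experiment()]).
#'
#' @param observations Daily cluster observation tibble (see [cohort-io]);
#'   each cluster must be observed at every age from 0 with no gaps.
#' @param horizon_days Optional positive integer: truncate observation at
#'   this age, censoring eggs still alive.
#' @return A tibble with one row per egg: `egg_id`, `cluster_id`,
#'   `temperature_c`, `rh_regime`, `outcome` (`hatched`, `died` or
#'   `censored`), `event_age_days`, and `d_yellow`, `d_brown`, `d_blackhead`
#'   (all `NA` here).
#' @export
#' @examples
#' obs <- simulate_experiment(design_conditions(20, "medium"),
#'                            clusters_per_condition = 2, seed = 1)
#' fates <- derive_fates(obs$observations)
#' dplyr::count(fates, outcome)
derive_fates <- function(observations, horizon_days = NULL) {
  obs <- validate_cohort(observations)
  if (!is.null(horizon_days)) {
    stopifnot(is.numeric(horizon_days), horizon_days >= 1)
    obs <- obs %>% filter(.data$age_days <= horizon_days)
  }

  per_cluster <- obs %>%
    group_by(.data$cluster_id, .data$temperature_c, .data$rh_regime) %>%
    group_split()

  fates <- purrr::map(per_cluster, function(cl) {
    ages <- cl$age_days
    if (ages[1] != 0L || any(diff(ages) != 1L)) {
      missing_age <- if (ages[1] != 0L) 0L else ages[which(diff(ages) != 1L)[1]] + 1L
      abort(sprintf(
        "Cluster %s has no observation at age %d (daily records required).",
        cl$cluster_id[1], missing_age
      ), class = "eggtherm_validation_error")
    }
    hatches <- diff(c(0L, cl$n_hatched_cum))
    deaths <- diff(c(0L, cl$n_dead_cum))
    last <- nrow(cl)
    events <- tibble(
      outcome = c(
        rep("hatched", sum(hatches)),
        rep("died", sum(deaths)),
        rep("censored", cl$n_alive[last])
      ),
      event_age_days = c(
        rep(ages, hatches),
        rep(ages, deaths),
        rep(ages[last], cl$n_alive[last])
      )
    )
    events %>%
      arrange(.data$event_age_days, .data$outcome) %>%
      mutate(
        egg_id = sprintf("%s_e%03d", cl$cluster_id[1], row_number()),
        cluster_id = cl$cluster_id[1],
        temperature_c = cl$temperature_c[1],
        rh_regime = cl$rh_regime[1]
      )
  }) %>%
    bind_rows() %>%
    mutate(
      d_yellow = NA_integer_, d_brown = NA_integer_, d_blackhead = NA_integer_
    ) %>%
    select(all_of(fate_columns()))

  bad <- fates$outcome != "censored" & fates$event_age_days < 1
  if (any(bad)) {
    abort("Hatch/death events at age 0 are not interpretable (eggs are set at age 0).",
          class = "eggtherm_validation_error")
  }
  fates
}

fate_columns <- function() {
  c("egg_id", "cluster_id", "temperature_c", "rh_regime", "outcome",
    "event_age_days", "d_yellow", "d_brown", "d_blackhead")
}

validate_fates <- function(fates) {
  fates <- as_tibble(fates)
  check_columns(fates, setdiff(fate_columns(), "egg_id"), "Fate table")
  bad <- setdiff(unique(fates$outcome), c("hatched", "died", "censored"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown outcome: %s.", bad[1]),
          class = "eggtherm_validation_error")
  }
  if (any(fates$event_age_days < 1 & fates$outcome != "censored")) {
    abort("event_age_days must be >= 1 for hatched/died eggs.",
          class = "eggtherm_validation_error")
  }
  fates %>% mutate(rh_regime = as_rh_factor(.data$rh_regime))
}
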