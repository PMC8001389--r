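#' @name cohort-io
#' @title Read and write cohort, temperature and field-record tables
#'
#' @description
#' CSV interchange for the three tabular inputs of the pipeline. All files
#' are comma-separated, UTF-8, ISO-8601 dates, dot decimal separator.
#'
#' * `cohort.csv`: daily egg-cluster observations with columns `cluster_id`,
#'   `temperature_c`, `rh_regime`, `age_days`, `n_alive`, `n_yellow`,
#'   `n_brown`, `n_blackhead`, `n_hatched_cum`, `n_dead_cum`.
#' * `temps.csv`: daily mean temperatures with columns `area`, `date`,
#'   `tmean_c`.
#' * `field.csv`: field stage records with columns `date`, `area`,
#'   `record_kind`, `count`.
#'
#' Readers validate every structural invariant (see [validate_cohort()]) and
#' fail with an error naming the offending column, cluster or date.
#'
#' @param path File path of the CSV to read or write.
#' @param data Tibble to write (validated first).
#' @return Readers return a validated tibble; writers return `path`
#'   invisibly.
NULL

cohort_columns <- function() {
  c("cluster_id", "temperature_c", "rh_regime", "age_days", "n_alive",
    "n_yellow", "n_brown", "n_blackhead", "n_hatched_cum", "n_dead_cum")
}

field_kinds <- function() {
  c("larva", "egg_yellow", "egg_brown", "egg_blackhead",
    "adult_reproductive", "adult_nonreproductive")
}

check_columns <- function(data, expected, what) {
  missing <- setdiff(expected, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ), class = "eggtherm_schema_error")
  }
  invisible(data)
}

#' Validate a cohort observation table
#'
#' Checks the structural invariants of daily egg-cluster observations:
#' colour counts partition the living eggs
#' (`n_yellow + n_brown + n_blackhead == n_alive`), eggs are conserved
#' (`n_alive + n_hatched_cum + n_dead_cum` is constant within a cluster),
#' cumulative counts never decrease with age, and initial egg counts are in
#' `[1, 10000]`.
#'
#' @param observations Tibble of cluster observations (see [cohort-io] for
#'   the column schema).
#' @return The validated tibble, sorted by `(cluster_id, age_days)`,
#'   invisibly usable in a pipe.
#' @export
validate_cohort <- function(observations) {
  observations <- as_tibble(observations)
  check_columns(observations, cohort_columns(), "Cohort table")
  obs <- observations %>%
    mutate(rh_regime = as_rh_factor(.data$rh_regime)) %>%
    arrange(.data$cluster_id, .data$age_days)

  int_cols <- c("age_days", "n_alive", "n_yellow", "n_brown", "n_blackhead",
                "n_hatched_cum", "n_dead_cum")
  for (col in int_cols) {
    v <- obs[[col]]
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      abort(sprintf("Column %s must contain non-negative integers.", col),
            class = "eggtherm_validation_error")
    }
    obs[[col]] <- as.integer(v)
  }
  if (any(!is.finite(obs$temperature_c))) {
    abort("Column temperature_c must be finite.",
          class = "eggtherm_validation_error")
  }

  bad <- obs %>%
    filter(.data$n_yellow + .data$n_brown + .data$n_blackhead != .data$n_alive)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Colour counts do not sum to n_alive for cluster %s at age %d.",
      bad$cluster_id[1], bad$age_days[1]
    ), class = "eggtherm_validation_error")
  }

  per_cluster <- obs %>%
    group_by(.data$cluster_id) %>%
    mutate(total = .data$n_alive + .data$n_hatched_cum + .data$n_dead_cum) %>%
    summarise(
      n_totals = dplyr::n_distinct(.data$total),
      initial = first(.data$total),
      hatch_drop = any(diff(.data$n_hatched_cum) < 0),
      dead_drop = any(diff(.data$n_dead_cum) < 0),
      n_cond = dplyr::n_distinct(paste(.data$temperature_c, .data$rh_regime)),
      .groups = "drop"
    )
  problem <- function(flag, msg) {
    bad <- per_cluster %>% filter({{ flag }})
    if (nrow(bad) > 0) {
      abort(sprintf(msg, bad$cluster_id[1]),
            class = "eggtherm_validation_error")
    }
  }
  problem(.data$n_totals > 1,
          "Egg count not conserved across ages in cluster %s.")
  problem(.data$initial < 1 | .data$initial > 10000,
          "Initial egg count out of [1, 10000] in cluster %s.")
  problem(.data$hatch_drop,
          "Cumulative hatched count decreases in cluster %s.")
  problem(.data$dead_drop,
          "Cumulative dead count decreases in cluster %s.")
  problem(.data$n_cond > 1,
          "Cluster %s is assigned to more than one condition.")
  obs
}

#' @rdname cohort-io
#' @export
read_cohort_observations <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            cluster_id = readr::col_character(),
                            rh_regime = readr::col_character(),
                            .default = readr::col_double()
                          ))
  validate_cohort(data)
}

#' @rdname cohort-io
#' @export
write_cohort_observations <- function(data, path) {
  data <- validate_cohort(data)
  readr::write_csv(data, path)
  invisible(path)
}

validate_temperature_series <- function(series) {
  series <- as_tibble(series)
  check_columns(series, c("area", "date", "tmean_c"), "Temperature series")
  series <- series %>%
    mutate(date = as.Date(.data$date)) %>%
    arrange(.data$area, .data$date)
  if (any(!is.finite(series$tmean_c))) {
    abort("Temperatures must be finite.", class = "eggtherm_validation_error")
  }
  gaps <- series %>%
    group_by(.data$area) %>%
    summarise(
      dup = any(duplicated(.data$date)),
      gap = any(diff(as.integer(.data$date)) != 1),
      .groups = "drop"
    )
  if (any(gaps$dup)) {
    abort(sprintf("Duplicated dates in area %s.",
                  gaps$area[gaps$dup][1]),
          class = "eggtherm_validation_error")
  }
  if (any(gaps$gap)) {
    abort(sprintf(
      "Temperature series for area %s is not daily-contiguous.",
      gaps$area[gaps$gap][1]
    ), class = "eggtherm_validation_error")
  }
  series
}

#' @rdname cohort-io
#' @export
read_temperature_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            area = readr::col_character(),
                            date = readr::col_date(),
                            tmean_c = readr::col_double()
                          ))
  validate_temperature_series(data)
}

#' @rdname cohort-io
#' @export
write_temperature_series <- function(data, path) {
  data <- validate_temperature_series(data)
  readr::write_csv(data, path)
  invisible(path)
}

validate_field_records <- function(records) {
  records <- as_tibble(records)
  check_columns(records, c("date", "area", "record_kind", "count"),
                "Field record table")
  records <- records %>%
    mutate(date = as.Date(.data$date)) %>%
    arrange(.data$area, .data$date, .data$record_kind)
  bad_kind <- setdiff(unique(records$record_kind), field_kinds())
  if (length(bad_kind) > 0) {
    abort(sprintf("Unknown record_kind: %s.", bad_kind[1]),
          class = "eggtherm_validation_error")
  }
  if (any(is.na(records$count)) || any(records$count < 1) ||
      any(records$count != floor(records$count))) {
    abort("Field record counts must be positive integers.",
          class = "eggtherm_validation_error")
  }
  records$count <- as.integer(records$count)
  records
}

#' @rdname cohort-io
#' @export
read_field_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            date = readr::col_date(),
                            area = readr::col_character(),
                            record_kind = readr::col_character(),
                            count = readr::col_double()
                          ))
  validate_field_records(data)
}

#' @rdname cohort-io
#' @export
write_field_records <- function(data, path) {
  data <- validate_field_records(data)
  readr::write_csv(data, path)
  invisible(path)
}
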