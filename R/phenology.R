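# Degree-day phenology: weekly climatology, thermal accumulation over daily
# temperature series, hatch-date forecasting, and back-calculation of the
# oviposition window from field stage records.

#' Weekly-mean climatology of a temperature series
#'
#' Replaces each daily mean by the multi-year mean of its calendar week
#' (weeks of 7 days counted from 1 January; the last short week of the year
#' is pooled with week 52). The result is a daily series, constant within
#' each week, on the same dates as the input -- the standard smoothing used
#' when forecasting from multi-year temperature records.
#'
#' @param series Temperature series tibble (`area`, `date`, `tmean_c`).
#' @return A temperature series tibble with weekly-averaged values.
#' @export
weekly_mean_series <- function(series) {
  series <- validate_temperature_series(series)
  series %>%
    mutate(
      week = pmin(52L, (as.POSIXlt(.data$date)$yday %/% 7L) + 1L)
    ) %>%
    group_by(.data$area, .data$week) %>%
    mutate(tmean_c = mean(.data$tmean_c)) %>%
    ungroup() %>%
    select("area", "date", "tmean_c")
}

#' Accumulate degree-days over a temperature series
#'
#' Daily thermal accumulation by the temperature-mean method: each day
#' contributes `max(0, tmean - T0)` degree-days, with no upper development
#' threshold. Accumulation runs from `from_date` to the end of the series.
#'
#' @param series Temperature series tibble for a single area.
#' @param t0 Lower development threshold (degC).
#' @param from_date Date accumulation starts (default: first date).
#' @return A tibble: `area`, `date`, `tmean_c`, `daily_dd`, `cumulative_dd`
#'   (non-decreasing running sum).
#' @export
#' @examples
#' temps <- simulate_temperature_series(n_days = 30, noise_sd = 0)
#' accumulate_degree_days(temps, t0 = 3.4)
accumulate_degree_days <- function(series, t0, from_date = NULL) {
  series <- validate_temperature_series(series)
  if (dplyr::n_distinct(series$area) > 1) {
    abort("accumulate_degree_days() expects a single area; filter first.")
  }
  if (is.null(from_date)) from_date <- min(series$date)
  from_date <- as.Date(from_date)
  if (from_date < min(series$date) || from_date > max(series$date)) {
    abort(sprintf("from_date %s is outside the series (%s to %s).",
                  from_date, min(series$date), max(series$date)),
          class = "eggtherm_range_error")
  }
  series %>%
    filter(.data$date >= from_date) %>%
    mutate(
      daily_dd = pmax(0, .data$tmean_c - t0),
      cumulative_dd = cumsum(.data$daily_dd)
    )
}

#' Forecast hatch dates by degree-day accumulation
#'
#' For each lay date, the forecast hatch date is the first date at which the
#' degree-days accumulated above `t0` reach the thermal constant `k`.
#' Accumulation starts the day after laying, so at constant temperature the
#' hatch falls exactly `ceiling(k / (T - t0))` days after laying (set
#' `include_lay_date = TRUE` to count the day of laying instead). If the
#' series ends before `k` degree-days accrue, the forecast is marked
#' horizon-exhausted with no hatch date.
#'
#' @param series Temperature series tibble for a single area.
#' @param lay_dates One or more lay dates within the series.
#' @param t0 Lower development threshold (degC).
#' @param k Thermal constant (degree-days).
#' @param include_lay_date Count the lay day's degree-days? Default `FALSE`.
#' @return A tibble: `area`, `lay_date`, `hatch_date` (`NA` when
#'   exhausted), `days_to_hatch`, `dd_at_hatch`, `horizon_exhausted`.
#' @export
#' @examples
#' temps <- simulate_temperature_series(n_days = 60, noise_sd = 0)
#' forecast_hatch(temps, "2018-10-01", t0 = 3.40, k = 230.83)
forecast_hatch <- function(series, lay_dates, t0, k,
                           include_lay_date = FALSE) {
  series <- validate_temperature_series(series)
  stopifnot(k > 0)
  lay_dates <- as.Date(lay_dates)
  purrr::map(lay_dates, function(lay) {
    start <- if (include_lay_date) lay else lay + 1
    if (lay < min(series$date) || lay > max(series$date)) {
      abort(sprintf("Lay date %s is outside the series.", lay),
            class = "eggtherm_range_error")
    }
    if (start > max(series$date)) {
      return(tibble(area = series$area[1], lay_date = lay,
                    hatch_date = as.Date(NA), days_to_hatch = NA_real_,
                    dd_at_hatch = 0, horizon_exhausted = TRUE))
    }
    acc <- accumulate_degree_days(series, t0, from_date = start)
    idx <- which(acc$cumulative_dd >= k)
    if (length(idx) == 0) {
      tibble(area = series$area[1], lay_date = lay,
             hatch_date = as.Date(NA), days_to_hatch = NA_real_,
             dd_at_hatch = max(acc$cumulative_dd),
             horizon_exhausted = TRUE)
    } else {
      hatch <- acc$date[idx[1]]
      tibble(area = series$area[1], lay_date = lay, hatch_date = hatch,
             days_to_hatch = as.numeric(hatch - lay),
             dd_at_hatch = acc$cumulative_dd[idx[1]],
             horizon_exhausted = FALSE)
    }
  }) %>% bind_rows()
}

#' Back-calculate the oviposition window from field stage records
#'
#' Estimates, per area, the calendar interval during which eggs were laid:
#'
#' * start: the earliest of (first larva record minus the total egg-stage
#'   duration and the larva's age at detection) and (first head-capsule egg
#'   record minus the yellow + brown durations); if neither record kind
#'   exists, the first yellow record minus the yellow duration. When
#'   reproductive-adult records exist, the start is clipped to be no
#'   earlier than the first reproductive-adult date (the adult record
#'   validates the back-calculated start).
#' * end: the date of the last yellow-cluster record. A cluster still
#'   yellow on that date was laid within the preceding yellow-stage
#'   duration, so the true end lies in `[end - yellow, end]`; that
#'   uncertainty is reported as `end_lay_earliest`.
#'
#' Stage durations must be those at the reference temperature representative
#' of the field season (8 degC for autumn-winter oviposition).
#'
#' @param field_records Field record tibble (see [cohort-io]).
#' @param stage_durations Named numeric, days at the reference temperature:
#'   `yellow`, `brown`, `blackhead`.
#' @param larval_age_at_detection Assumed age (days) of the first-detected
#'   larva; 0 treats it as newly hatched.
#' @return A tibble of class `oviposition_window`: `area`, `start`, `end`,
#'   `end_lay_earliest`, `start_basis`, `clipped_to_adults`, plus an
#'   `evidence` list-column of the records that bound the window with their
#'   back-dated lay intervals.
#' @export
estimate_oviposition_window <- function(field_records,
                                        stage_durations,
                                        larval_age_at_detection = 0) {
  records <- validate_field_records(field_records)
  stopifnot(all(c("yellow", "brown", "blackhead") %in% names(stage_durations)),
            all(stage_durations > 0), larval_age_at_detection >= 0)
  y <- stage_durations[["yellow"]]
  b <- stage_durations[["brown"]]
  bh <- stage_durations[["blackhead"]]
  total <- y + b + bh

  out <- records %>%
    group_by(.data$area) %>%
    group_split() %>%
    purrr::map(function(g) {
      area <- g$area[1]
      date_of <- function(kind, fun) {
        d <- g$date[g$record_kind == kind]
        if (length(d) == 0) as.Date(NA) else fun(d)
      }
      first_larva <- date_of("larva", min)
      first_bh <- date_of("egg_blackhead", min)
      first_yellow <- date_of("egg_yellow", min)
      last_yellow <- date_of("egg_yellow", max)
      first_adult <- date_of("adult_reproductive", min)

      cand <- c(
        larva = first_larva - total - larval_age_at_detection,
        blackhead = first_bh - (y + b)
      )
      if (all(is.na(cand))) {
        if (is.na(first_yellow)) {
          abort(sprintf(
            "Area %s: no larvae, head-capsule eggs or yellow clusters; window undeterminable.",
            area
          ), class = "eggtherm_window_error")
        }
        cand <- c(yellow = first_yellow - y)
      }
      start0 <- min(cand, na.rm = TRUE)
      basis <- names(cand)[which.min(as.numeric(cand))]
      clipped <- !is.na(first_adult) && first_adult > start0
      start <- if (clipped) first_adult else start0

      end <- if (!is.na(last_yellow)) {
        last_yellow
      } else {
        # latest lay consistent with the latest-staged record present
        max(c(date_of("egg_brown", max) - y,
              date_of("egg_blackhead", max) - (y + b),
              date_of("larva", max) - total - larval_age_at_detection),
            na.rm = TRUE)
      }
      if (end < start) end <- start

      evidence <- g %>%
        filter(.data$record_kind %in%
                 c("larva", "egg_yellow", "egg_brown", "egg_blackhead",
                   "adult_reproductive")) %>%
        mutate(
          lay_earliest = case_when(
            .data$record_kind == "egg_yellow" ~ .data$date - y,
            .data$record_kind == "egg_brown" ~ .data$date - (y + b),
            .data$record_kind == "egg_blackhead" ~ .data$date - total,
            .data$record_kind == "larva" ~
              .data$date - total - larval_age_at_detection - bh,
            TRUE ~ .data$date
          ),
          lay_latest = case_when(
            .data$record_kind == "egg_yellow" ~ .data$date,
            .data$record_kind == "egg_brown" ~ .data$date - y,
            .data$record_kind == "egg_blackhead" ~ .data$date - (y + b),
            .data$record_kind == "larva" ~
              .data$date - total - larval_age_at_detection,
            TRUE ~ .data$date
          )
        )

      tibble(
        area = area,
        start = start,
        end = end,
        end_lay_earliest = end - y,
        start_basis = basis,
        clipped_to_adults = clipped,
        evidence = list(evidence)
      )
    }) %>%
    bind_rows()
  class(out) <- c("oviposition_window", class(out))
  out
}
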