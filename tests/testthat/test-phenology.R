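test_that("weekly climatology averages within calendar weeks across years", {
  const <- simulate_temperature_series(start_date = "2004-01-01",
                                       n_days = 365 * 15 + 4,
                                       annual_mean = 10, annual_amplitude = 0,
                                       noise_sd = 0, seed = 1)
  expect_true(all(weekly_mean_series(const)$tmean_c == 10))

  # two years whose week-1 means are 8 and 12 average to 10
  two <- dplyr::bind_rows(
    tibble::tibble(area = "a",
                   date = seq(as.Date("2018-01-01"), by = "day", length.out = 730))
  ) %>%
    dplyr::mutate(tmean_c = ifelse(format(date, "%Y") == "2018", 8, 12))
  wk <- weekly_mean_series(two)
  expect_true(all(wk$tmean_c[1:7] == 10))

  # sinusoidal input stays within one weekly step of the analytic curve
  sine <- simulate_temperature_series(start_date = "2010-01-01",
                                      n_days = 365, annual_mean = 12,
                                      annual_amplitude = 8, noise_sd = 0,
                                      seed = 1)
  wk2 <- weekly_mean_series(sine)
  weekly_step <- 8 * 2 * pi * 7 / 365.25  # max weekly change of the sinusoid
  expect_lt(max(abs(wk2$tmean_c - sine$tmean_c)), weekly_step)
})

test_that("degree-days accumulate as max(0, tmean - T0) with no upper cutoff", {
  flat8 <- simulate_temperature_series(n_days = 20, annual_mean = 8,
                                       annual_amplitude = 0, noise_sd = 0,
                                       seed = 1)
  acc <- accumulate_degree_days(flat8, t0 = 3.4)
  expect_true(all(acc$daily_dd == 4.6))
  expect_equal(acc$cumulative_dd[10], 46)

  cold <- simulate_temperature_series(n_days = 15, annual_mean = 2,
                                      annual_amplitude = 0, noise_sd = 0,
                                      seed = 1)
  expect_true(all(accumulate_degree_days(cold, t0 = 3.4)$cumulative_dd == 0))

  # brute-force daily summation oracle on a noisy series
  mixed <- simulate_temperature_series(n_days = 60, annual_mean = 5,
                                       annual_amplitude = 4, noise_sd = 2,
                                       seed = 12)
  acc2 <- accumulate_degree_days(mixed, t0 = 3.4)
  brute <- numeric(nrow(mixed))
  total <- 0
  for (i in seq_len(nrow(mixed))) {
    total <- total + max(0, mixed$tmean_c[i] - 3.4)
    brute[i] <- total
  }
  expect_equal(acc2$cumulative_dd, brute, tolerance = 1e-12)
  expect_true(all(diff(acc2$cumulative_dd) >= 0))

  expect_error(accumulate_degree_days(flat8, 3.4, from_date = "2030-01-01"),
               class = "eggtherm_range_error")
})

test_that("hatch forecasts at constant temperature hit the closed form", {
  for (temp in c(12, 20, 28)) {
    series <- simulate_temperature_series(n_days = 120, annual_mean = temp,
                                          annual_amplitude = 0, noise_sd = 0,
                                          seed = 1)
    for (k in c(100, 230.83)) {
      fc <- forecast_hatch(series, "2018-10-05", t0 = 3.40, k = k)
      expect_equal(fc$days_to_hatch, ceiling(k / (temp - 3.40)))
      expect_false(fc$horizon_exhausted)
      # agreement with the continuous prediction within one day
      expect_lt(abs(fc$days_to_hatch - predict_duration(3.40, k, temp)), 1)
    }
  }

  # at the threshold nothing accumulates
  at_t0 <- simulate_temperature_series(n_days = 60, annual_mean = 3.4,
                                       annual_amplitude = 0, noise_sd = 0,
                                       seed = 1)
  fc0 <- forecast_hatch(at_t0, "2018-10-05", t0 = 3.4, k = 50)
  expect_true(fc0$horizon_exhausted)
  expect_true(is.na(fc0$hatch_date))
})

test_that("later laying never hatches earlier on the same series", {
  series <- simulate_temperature_series(n_days = 200, seed = 23)
  lays <- seq(as.Date("2018-10-01"), by = "5 days", length.out = 12)
  fc <- forecast_hatch(series, lays, t0 = 3.40, k = 230.83)
  done <- fc[!fc$horizon_exhausted, ]
  expect_true(all(diff(as.integer(done$hatch_date)) >= 0))
})

test_that("autumn lays on the default climatology hatch in two to three weeks", {
  # early October in the default Ebro-Valley-like series is ~17 degC, so
  # 230.83 DD above 3.40 degC accrue in roughly 2-3 weeks
  series <- simulate_temperature_series(n_days = 150, noise_sd = 0, seed = 1)
  fc <- forecast_hatch(series, "2018-10-03", t0 = 3.40, k = 230.83)
  expect_gte(fc$days_to_hatch, 12)
  expect_lte(fc$days_to_hatch, 21)
})

test_that("oviposition window back-dating follows the stage arithmetic", {
  stages <- c(yellow = 15, brown = 23, blackhead = 7)  # total 45 d at 8 degC
  recs <- tibble::tibble(
    date = as.Date(c("2018-12-20", "2018-10-15", "2019-01-10")),
    area = "urgell",
    record_kind = c("larva", "adult_reproductive", "egg_yellow"),
    count = c(3L, 5L, 2L)
  )
  win <- estimate_oviposition_window(recs, stages)
  expect_equal(win$start, as.Date("2018-12-20") - 45)  # 5 Nov, no clipping
  expect_equal(win$start_basis, "larva")
  expect_false(win$clipped_to_adults)
  expect_equal(win$end, as.Date("2019-01-10"))
  expect_equal(win$end_lay_earliest, as.Date("2019-01-10") - 15)

  # a late first reproductive adult clips the start upward
  recs2 <- recs
  recs2$date[2] <- as.Date("2018-11-20")
  win2 <- estimate_oviposition_window(recs2, stages)
  expect_equal(win2$start, as.Date("2018-11-20"))
  expect_true(win2$clipped_to_adults)

  # nothing to back-date from is an explicit error
  empty <- tibble::tibble(date = as.Date("2018-11-01"), area = "urgell",
                          record_kind = "adult_reproductive", count = 1L)
  expect_error(estimate_oviposition_window(empty, stages),
               class = "eggtherm_window_error")
})

test_that("windows recovered from synthetic field records bracket the truth", {
  stages <- c(yellow = 15, brown = 23, blackhead = 12)
  set.seed(77)
  for (rep in 1:10) {
    start <- as.Date("2018-10-01") + sample(0:30, 1)
    end <- start + sample(60:110, 1)
    sampling <- seq(start - 14, end + 70, by = "7 days")
    recs <- simulate_field_records(start, end, stages,
                                   sampling_dates = sampling)
    win <- estimate_oviposition_window(recs, stages)
    expect_gte(as.numeric(win$start - start), 0)
    expect_lte(as.numeric(win$start - start), 7)
    expect_gte(as.numeric(win$end - end), 0)
    expect_lte(as.numeric(win$end - end), stages[["yellow"]])
    expect_true(win$end_lay_earliest <= end)
  }
})
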