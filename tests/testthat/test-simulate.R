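small_design <- function(temps = c(16, 24), regimes = "medium") {
  design_conditions(temps, regimes)
}

test_that("identical seeds give identical cohorts; different seeds differ", {
  a <- simulate_experiment(small_design(), clusters_per_condition = 3, seed = 11)
  b <- simulate_experiment(small_design(), clusters_per_condition = 3, seed = 11)
  c <- simulate_experiment(small_design(), clusters_per_condition = 3, seed = 12)
  expect_identical(a$observations, b$observations)
  expect_identical(a$fates, b$fates)
  expect_false(identical(a$fates$event_age_days, c$fates$event_age_days))
})

test_that("degenerate generator hits the closed-form duration", {
  # full survival, zero CV: every egg hatches at round(K / (T - T0))
  params <- generator_params(
    true_t0 = c(low = 3.4, medium = 3.4, high = 3.4),
    true_k = c(low = 230.8, medium = 230.8, high = 230.8),
    survival_surface = tibble::tibble(temperature_c = 20,
                                      rh_regime = "medium", p_hatch = 1),
    duration_cv = 0
  )
  sim <- simulate_experiment(design_conditions(20, "medium"),
                             clusters_per_condition = 4, params = params,
                             seed = 1)
  expect_true(all(sim$fates$outcome == "hatched"))
  expect_true(all(sim$fates$event_age_days == round(230.8 / 16.6)))  # 14
})

test_that("temperatures at or below the threshold are rejected unless flagged", {
  params <- generator_params()
  expect_error(
    simulate_experiment(design_conditions(2, "medium"),
                        clusters_per_condition = 2, params = params, seed = 1),
    "non_developing"
  )
  design <- design_conditions(2, "medium")
  design$non_developing <- TRUE
  sim <- simulate_experiment(design, clusters_per_condition = 2,
                             params = params, seed = 1)
  expect_true(all(sim$fates$outcome == "died"))
})

test_that("hatch fractions and durations converge to the generator truth", {
  params <- generator_params(
    survival_surface = tibble::tibble(temperature_c = 20,
                                      rh_regime = "medium", p_hatch = 0.7)
  )
  sim <- simulate_experiment(design_conditions(20, "medium"),
                             clusters_per_condition = 800,
                             eggs_per_cluster = c(12L, 13L),
                             params = params, seed = 8, tables = FALSE)
  n <- nrow(sim$fates)
  expect_gt(n, 9000)
  p_hat <- mean(sim$fates$outcome == "hatched")
  expect_lt(abs(p_hat - 0.7), 4 * sqrt(0.7 * 0.3 / n))

  hatched <- sim$fates$event_age_days[sim$fates$outcome == "hatched"]
  mu <- 230.83 / (20 - 3.40)
  se <- stats::sd(hatched) / sqrt(length(hatched))
  expect_lt(abs(mean(hatched) - mu), 3 * se + 0.5)  # 0.5: integer rounding
})

test_that("generated daily tables are the exact tally of per-egg truth", {
  sim <- simulate_experiment(small_design(c(12, 36), "low"),
                             clusters_per_condition = 4, seed = 21)
  expect_silent(validate_cohort(sim$observations))
  rebuilt <- derive_fates(sim$observations)
  by_cluster <- function(f) {
    dplyr::count(f, cluster_id, outcome) %>% dplyr::arrange(cluster_id, outcome)
  }
  expect_equal(by_cluster(rebuilt), by_cluster(sim$fates))
  # event ages agree egg-for-egg within cluster x outcome
  ages <- function(f) {
    f %>% dplyr::group_by(cluster_id, outcome) %>%
      dplyr::summarise(a = list(sort(event_age_days)), .groups = "drop")
  }
  expect_equal(ages(rebuilt), ages(sim$fates))
})

test_that("colour stages partition each duration with brown longest overall", {
  sim <- simulate_experiment(small_design(c(8, 20, 36),
                                          c("low", "medium", "high")),
                             clusters_per_condition = 6, seed = 31,
                             tables = FALSE)
  h <- dplyr::filter(sim$fates, outcome == "hatched")
  expect_true(all(h$d_yellow + h$d_brown + h$d_blackhead == h$event_age_days))
  stage_means <- colour_stage_durations(sim$fates)
  expect_true(all(stage_means$mean_brown > stage_means$mean_yellow))
  expect_true(all(stage_means$mean_brown > stage_means$mean_blackhead))
})

test_that("temperature series generator honours its contracts", {
  flat <- simulate_temperature_series(n_days = 30, annual_mean = 8,
                                      annual_amplitude = 0, noise_sd = 0,
                                      seed = 1)
  expect_true(all(flat$tmean_c == 8))

  # seasonal shape: with the coldest day in mid-January, October is warmer
  yr <- simulate_temperature_series(start_date = "2018-01-01", n_days = 365,
                                    annual_mean = 12, annual_amplitude = 8,
                                    noise_sd = 0, seed = 1)
  jan <- mean(yr$tmean_c[format(yr$date, "%m") == "01"])
  oct <- mean(yr$tmean_c[format(yr$date, "%m") == "10"])
  expect_gt(oct, jan)

  s1 <- simulate_temperature_series(n_days = 50, seed = 4)
  s2 <- simulate_temperature_series(n_days = 50, seed = 4)
  s3 <- simulate_temperature_series(n_days = 50, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1$tmean_c, s3$tmean_c))
  expect_error(simulate_temperature_series(n_days = 5, noise_sd = -1),
               "non-negative")
})

test_that("field records follow the stage timeline of the lay window", {
  stages <- c(yellow = 8, brown = 15, blackhead = 7)  # total 30 d
  win <- c("2018-10-15", "2019-01-31")

  # 17 days in: yellow and brown cohorts exist, nothing older
  nov1 <- simulate_field_records(win[1], win[2], stages,
                                 sampling_dates = as.Date("2018-11-01"))
  kinds <- unique(nov1$record_kind)
  expect_setequal(setdiff(kinds, "adult_reproductive"),
                  c("egg_yellow", "egg_brown"))

  # at the window start only yellow eggs and reproductive adults
  d0 <- simulate_field_records(win[1], win[2], stages,
                               sampling_dates = as.Date(win[1]))
  expect_setequal(unique(d0$record_kind),
                  c("egg_yellow", "adult_reproductive"))

  # after the window plus all stage durations: larvae, no yellow eggs
  late <- simulate_field_records(win[1], win[2], stages,
                                 sampling_dates = as.Date("2019-03-15"))
  expect_true("larva" %in% late$record_kind)
  expect_false("egg_yellow" %in% late$record_kind)

  expect_error(
    simulate_field_records(win[1], win[2], stages, sampling_dates = as.Date(character(0))),
    "non-empty"
  )
})
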