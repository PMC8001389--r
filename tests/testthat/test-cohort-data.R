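test_that("cohort CSV round trip preserves records and validates schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  obs <- make_cluster_table(hatch_ages = rep(14L, 10), death_ages = c(3L, 5L))
  write_cohort_observations(obs, path)
  back <- read_cohort_observations(path)
  expect_equal(nrow(back), nrow(obs))
  expect_equal(back$n_alive, obs$n_alive)
  expect_equal(back$n_hatched_cum, obs$n_hatched_cum)
  expect_equal(as.character(back$rh_regime), obs$rh_regime)

  # two-row echo: age 0 with 12 alive, age 5 with 10 alive / 2 dead
  two <- tibble::tibble(
    cluster_id = "c9", temperature_c = 20, rh_regime = "medium",
    age_days = c(0L, 5L), n_alive = c(12L, 10L), n_yellow = c(12L, 10L),
    n_brown = 0L, n_blackhead = 0L, n_hatched_cum = 0L,
    n_dead_cum = c(0L, 2L)
  )
  write_cohort_observations(two, path)
  got <- read_cohort_observations(path)
  expect_equal(nrow(got), 2L)
  expect_equal(got$n_alive[1] + got$n_hatched_cum[1] + got$n_dead_cum[1], 12L)

  # schema error names the missing column
  readr::write_csv(two[, -5], path)
  expect_error(read_cohort_observations(path), "n_alive",
               class = "eggtherm_schema_error")
})

test_that("validation rejects colour counts that do not partition the living", {
  obs <- make_cluster_table(hatch_ages = rep(10L, 5))
  obs$n_yellow[2] <- obs$n_yellow[2] - 1L
  expect_error(validate_cohort(obs), "Colour counts",
               class = "eggtherm_validation_error")

  obs2 <- make_cluster_table(hatch_ages = rep(10L, 5))
  obs2$n_hatched_cum[3] <- 2L  # breaks conservation
  expect_error(validate_cohort(obs2), "not conserved",
               class = "eggtherm_validation_error")
})

test_that("derive_fates reproduces hand-traced event histories", {
  # single transition: 10 eggs all hatch at age 14
  f <- derive_fates(make_cluster_table(hatch_ages = rep(14L, 10)))
  expect_equal(nrow(f), 10L)
  expect_true(all(f$outcome == "hatched"))
  expect_true(all(f$event_age_days == 14L))

  # mixed ending: 9 hatched, 3 died
  f2 <- derive_fates(make_cluster_table(hatch_ages = rep(12L, 9),
                                        death_ages = c(2L, 4L, 4L)))
  expect_equal(sum(f2$outcome == "hatched"), 9L)
  expect_equal(sum(f2$outcome == "died"), 3L)
  expect_equal(nrow(f2), 12L)

  # death ages read off the daily table: 2 deaths at age 3, 1 at age 6
  f3 <- derive_fates(make_cluster_table(hatch_ages = rep(10L, 4),
                                        death_ages = c(3L, 3L, 6L)))
  expect_equal(sort(f3$event_age_days[f3$outcome == "died"]), c(3L, 3L, 6L))
})

test_that("derive_fates conserves eggs and matches final cumulative counts", {
  set.seed(41)
  for (rep in 1:10) {
    n_h <- sample(0:8, 1)
    n_d <- sample(0:5, 1)
    if (n_h + n_d == 0) n_h <- 3
    obs <- make_cluster_table(
      cluster_id = sprintf("r%d", rep),
      hatch_ages = sample(5:15, n_h, replace = TRUE),
      death_ages = if (n_d > 0) sample(1:12, n_d, replace = TRUE) else integer(0)
    )
    f <- derive_fates(obs)
    expect_equal(nrow(f), n_h + n_d)
    last <- obs[nrow(obs), ]
    expect_equal(sum(f$outcome == "hatched"), last$n_hatched_cum)
    expect_equal(sum(f$outcome == "died"), last$n_dead_cum)
  }
})

test_that("derive_fates is insensitive to row order and flags age gaps", {
  obs <- make_cluster_table(hatch_ages = rep(9L, 6), death_ages = c(2L, 7L))
  shuffled <- obs[sample(nrow(obs)), ]
  expect_equal(derive_fates(obs), derive_fates(shuffled))

  gap <- obs[obs$age_days != 4L, ]
  expect_error(derive_fates(gap), "age 4",
               class = "eggtherm_validation_error")
})

test_that("censoring at a horizon keeps eggs alive at truncation", {
  obs <- make_cluster_table(hatch_ages = c(5L, 9L, 14L), death_ages = 3L)
  f <- derive_fates(obs, horizon_days = 10)
  expect_equal(sum(f$outcome == "censored"), 1L)
  expect_equal(f$event_age_days[f$outcome == "censored"], 10L)
  expect_equal(nrow(f), 4L)
})

test_that("temperature and field readers validate their invariants", {
  tpath <- withr::local_tempfile(fileext = ".csv")
  temps <- simulate_temperature_series(n_days = 10, seed = 2)
  write_temperature_series(temps, tpath)
  expect_equal(read_temperature_series(tpath), temps)

  gappy <- temps[-4, ]
  expect_error(write_temperature_series(gappy, tpath), "contiguous",
               class = "eggtherm_validation_error")

  fpath <- withr::local_tempfile(fileext = ".csv")
  recs <- simulate_field_records("2018-10-15", "2018-12-01",
                                 c(yellow = 15, brown = 23, blackhead = 12),
                                 sampling_dates = as.Date(c("2018-10-20",
                                                            "2018-11-20")))
  write_field_records(recs, fpath)
  expect_equal(read_field_records(fpath), recs)
  bad <- recs
  bad$record_kind[1] <- "pupa"
  expect_error(validate_field_records(bad), "pupa",
               class = "eggtherm_validation_error")
})
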