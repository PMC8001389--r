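# Synthetic-data generator: laboratory cohorts, seasonal temperature series
# and field stage records with the statistical structure of a factorial
# temperature x RH egg incubation experiment.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Default per-condition hatch probabilities
#'
#' The generator's default survival surface. It is calibrated to the three
#' ordinal survival patterns observed across RH regimes: at the thermal
#' extremes (8 and 36 degC) the medium regime survives best and all three
#' regimes differ; from 12 to 20 degC the high regime is best while medium
#' and low are similar; from 24 to 32 degC the low regime is clearly worst
#' while medium and high are similar. Overall survival is near-total at
#' 8 degC and drops sharply at 32-36 degC, with roughly half the eggs
#' surviving dry conditions at the cold end.
#'
#' @return A tibble with columns `temperature_c`, `rh_regime`, `p_hatch`.
#' @export
#' @examples
#' default_survival_surface()
default_survival_surface <- function() {
  temps <- seq(8, 36, by = 4)
  tibble(
    temperature_c = rep(temps, each = 3),
    rh_regime = as_rh_factor(rep(c("high", "medium", "low"), times = 8)),
    p_hatch = c(
      0.90, 0.97, 0.55,  #  8 degC: medium > high > low, all distinct
      0.95, 0.88, 0.85,  # 12 degC: high best, medium ~ low
      0.95, 0.88, 0.86,  # 16 degC
      0.93, 0.88, 0.86,  # 20 degC
      0.85, 0.87, 0.60,  # 24 degC: low worst, medium ~ high
      0.80, 0.82, 0.55,  # 28 degC
      0.55, 0.57, 0.25,  # 32 degC: sharp decline
      0.25, 0.45, 0.10   # 36 degC: medium best, all distinct
    )
  )
}

#' Generator parameters
#'
#' Bundles the ground-truth parameters of the synthetic cohort generator.
#' Defaults encode the fitted thermal parameters of the egg stage per RH
#' regime (lower threshold `true_t0`, thermal constant `true_k`), a
#' development-duration coefficient of variation of 0.1, colour-stage
#' fractions with the brown stage longest, and a supraoptimal duration
#' inflation applied above 32 degC (development slows again at 36 degC).
#'
#' @param true_t0 Named numeric: lower development threshold (degC) per RH
#'   regime.
#' @param true_k Named numeric: thermal constant (degree-days) per regime.
#' @param survival_surface Tibble with `temperature_c`, `rh_regime`,
#'   `p_hatch` in `[0, 1]` giving the per-condition hatch probability.
#' @param duration_cv Coefficient of variation of development duration
#'   (> 0, or 0 for deterministic durations).
#' @param stage_fractions Positive fractions (yellow, brown, blackhead)
#'   summing to 1; brown largest by default.
#' @param supraoptimal_inflation Multiplicative duration factor (>= 1)
#'   applied above `supraoptimal_above_c`.
#' @param supraoptimal_above_c Temperature (degC) above which the inflation
#'   applies.
#' @param seed Default integer seed for the generator functions.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(true_t0 = c(low = 3.30, medium = 3.40, high = 3.82),
                             true_k = c(low = 246.14, medium = 230.83, high = 209.05),
                             survival_surface = default_survival_surface(),
                             duration_cv = 0.1,
                             stage_fractions = c(yellow = 0.30, brown = 0.45,
                                                 blackhead = 0.25),
                             supraoptimal_inflation = 1.3,
                             supraoptimal_above_c = 32,
                             seed = 1L) {
  stopifnot(
    all(rh_levels() %in% names(true_t0)),
    all(rh_levels() %in% names(true_k)),
    all(true_k > 0),
    is.numeric(duration_cv), duration_cv >= 0,
    length(stage_fractions) == 3, all(stage_fractions > 0),
    abs(sum(stage_fractions) - 1) < 1e-9,
    supraoptimal_inflation >= 1
  )
  surface <- as_tibble(survival_surface)
  check_columns(surface, c("temperature_c", "rh_regime", "p_hatch"),
                "Survival surface")
  if (any(surface$p_hatch < 0 | surface$p_hatch > 1)) {
    abort("Hatch probabilities must lie in [0, 1].")
  }
  structure(
    list(
      true_t0 = true_t0[rh_levels()],
      true_k = true_k[rh_levels()],
      survival_surface = surface %>%
        mutate(rh_regime = as_rh_factor(.data$rh_regime)),
      duration_cv = duration_cv,
      stage_fractions = stage_fractions,
      supraoptimal_inflation = supraoptimal_inflation,
      supraoptimal_above_c = supraoptimal_above_c,
      seed = as.integer(seed)
    ),
    class = "generator_params"
  )
}

# Integer durations from a gamma with given mean and CV, minimum 1 day.
draw_durations <- function(n, mean_days, cv) {
  if (n == 0) return(integer(0))
  if (cv <= 0) return(pmax(1L, as.integer(round(rep(mean_days, n)))))
  shape <- 1 / cv^2
  pmax(1L, as.integer(round(rgamma(n, shape = shape,
                                   scale = mean_days * cv^2 / 1))))
}

# Largest-remainder partition of integer durations into the three colour
# stages; ties broken toward the earlier stage.
stage_partition <- function(dur, fractions) {
  if (length(dur) == 0) {
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("yellow", "brown", "blackhead"))))
  }
  raw <- outer(dur, fractions)
  fl <- floor(raw)
  deficit <- dur - rowSums(fl)
  rem <- raw - fl + matrix(rep(c(3e-12, 2e-12, 1e-12), each = length(dur)),
                           ncol = 3)
  gt <- matrix(0L, nrow = length(dur), ncol = 3)
  for (j in 1:3) {
    for (k in 1:3) {
      if (k != j) gt[, j] <- gt[, j] + (rem[, k] > rem[, j])
    }
  }
  out <- fl + (gt < deficit)
  storage.mode(out) <- "integer"
  colnames(out) <- c("yellow", "brown", "blackhead")
  out
}

#' Simulate a factorial egg incubation experiment
#'
#' Generates per-egg ground truth and (optionally) the daily cluster
#' observation tables an observer would record. Per egg, a Bernoulli draw
#' from the survival surface decides hatch versus death; hatched eggs draw
#' an integer development duration from a discretized gamma with mean
#' `K / (T - T0)` (inflated above the supraoptimal temperature) and the
#' configured CV; dead eggs die at an age uniform on `[1, duration]` of
#' their would-be development span; colour stages partition each duration by
#' `stage_fractions` with largest-remainder rounding. Daily tables are the
#' exact tally of the per-egg ground truth, so they reconcile with
#' [derive_fates()] by construction.
#'
#' @param design Tibble of conditions (`temperature_c`, `rh_regime`),
#'   e.g. from [design_conditions()]. An optional logical column
#'   `non_developing` marks conditions at or below the regime's threshold
#'   (all eggs then die without a drawn duration).
#' @param clusters_per_condition Number of replicate clusters per condition.
#' @param eggs_per_cluster Integer interval `c(min, max)`; cluster sizes are
#'   drawn uniformly from it.
#' @param params A [generator_params()] object.
#' @param seed Integer seed; identical seeds give identical output.
#' @param tables If `FALSE`, skip building the daily observation tables
#'   (faster for simulation studies that only need fates).
#' @param horizon_days Optional observation horizon; eggs still alive then
#'   are censored.
#' @return A list with `fates` (per-egg ground truth, stage durations on
#'   hatched eggs) and `observations` (daily cluster tables, or `NULL` when
#'   `tables = FALSE`).
#' @export
#' @examples
#' sim <- simulate_experiment(design_conditions(c(16, 20), "medium"),
#'                            clusters_per_condition = 3, seed = 42)
#' head(sim$observations)
simulate_experiment <- function(design = design_conditions(),
                                clusters_per_condition = 20,
                                eggs_per_cluster = c(10L, 15L),
                                params = generator_params(),
                                seed = params$seed,
                                tables = TRUE,
                                horizon_days = NULL) {
  stopifnot(inherits(params, "generator_params"),
            clusters_per_condition >= 1,
            length(eggs_per_cluster) == 2,
            eggs_per_cluster[1] >= 1,
            eggs_per_cluster[1] <= eggs_per_cluster[2])
  design <- as_tibble(design) %>%
    mutate(rh_regime = as_rh_factor(.data$rh_regime))
  if (!"non_developing" %in% names(design)) design$non_developing <- FALSE

  t0 <- params$true_t0[as.character(design$rh_regime)]
  if (any(design$temperature_c <= t0 & !design$non_developing)) {
    bad <- which(design$temperature_c <= t0 & !design$non_developing)[1]
    abort(sprintf(
      "Condition %g degC / %s is at or below the regime threshold (%.2f degC); flag it non_developing.",
      design$temperature_c[bad], design$rh_regime[bad], t0[bad]
    ))
  }

  surface <- params$survival_surface
  design_p <- design %>%
    left_join(surface, by = c("temperature_c", "rh_regime"))
  if (any(is.na(design_p$p_hatch) & !design_p$non_developing)) {
    bad <- design_p %>% filter(is.na(.data$p_hatch), !.data$non_developing)
    abort(sprintf(
      "Survival surface has no entry for %g degC / %s.",
      bad$temperature_c[1], bad$rh_regime[1]
    ))
  }

  eggs <- with_seed(seed, {
    purrr::pmap(design_p, function(temperature_c, rh_regime, non_developing,
                                   p_hatch, ...) {
      regime <- as.character(rh_regime)
      sizes <- sample(seq(eggs_per_cluster[1], eggs_per_cluster[2]),
                      clusters_per_condition, replace = TRUE)
      n <- sum(sizes)
      cluster_id <- rep(sprintf("T%g_%s_c%02d", temperature_c, regime,
                                seq_len(clusters_per_condition)), sizes)
      if (non_developing) {
        hatched <- rep(FALSE, n)
        dur <- rep(1L, n)  # nominal span: death within the first day(s)
      } else {
        hatched <- runif(n) < p_hatch
        mu <- params$true_k[regime] /
          (temperature_c - params$true_t0[regime])
        if (temperature_c > params$supraoptimal_above_c) {
          mu <- mu * params$supraoptimal_inflation
        }
        dur <- draw_durations(n, mu, params$duration_cv)
      }
      death_age <- as.integer(ceiling(runif(n) * dur))
      stages <- stage_partition(dur, params$stage_fractions)
      tibble(
        cluster_id = cluster_id,
        temperature_c = temperature_c,
        rh_regime = rh_regime,
        outcome = if_else(hatched, "hatched", "died"),
        event_age_days = if_else(hatched, dur, death_age),
        d_yellow = stages[, "yellow"],
        d_brown = stages[, "brown"],
        d_blackhead = stages[, "blackhead"]
      )
    }) %>% bind_rows()
  })

  if (!is.null(horizon_days)) {
    stopifnot(horizon_days >= 1)
    eggs <- eggs %>%
      mutate(
        censor = .data$event_age_days > horizon_days,
        outcome = if_else(.data$censor, "censored", .data$outcome),
        event_age_days = if_else(.data$censor, as.integer(horizon_days),
                                 .data$event_age_days)
      ) %>%
      select(-"censor")
  }

  fates <- eggs %>%
    group_by(.data$cluster_id) %>%
    mutate(egg_id = sprintf("%s_e%03d", .data$cluster_id, row_number())) %>%
    ungroup() %>%
    mutate(
      d_yellow = if_else(.data$outcome == "hatched", .data$d_yellow, NA_integer_),
      d_brown = if_else(.data$outcome == "hatched", .data$d_brown, NA_integer_),
      d_blackhead = if_else(.data$outcome == "hatched", .data$d_blackhead,
                            NA_integer_)
    ) %>%
    select(all_of(fate_columns()))

  observations <- NULL
  if (tables) {
    observations <- tally_observations(eggs, horizon_days)
  }
  list(fates = fates, observations = observations)
}

# Exact daily tally of per-egg ground truth into cluster observation tables.
tally_observations <- function(eggs, horizon_days = NULL) {
  ages <- eggs %>%
    group_by(.data$cluster_id, .data$temperature_c, .data$rh_regime) %>%
    summarise(max_age = max(.data$event_age_days), .groups = "drop") %>%
    mutate(age_days = purrr::map(.data$max_age, ~seq(0L, .x))) %>%
    select(-"max_age") %>%
    tidyr::unnest("age_days")

  pairs <- ages %>%
    left_join(
      eggs %>% select("cluster_id", "outcome", "event_age_days",
                      "d_yellow", "d_brown", "d_blackhead"),
      by = "cluster_id", relationship = "many-to-many"
    ) %>%
    mutate(
      alive = if_else(.data$outcome == "censored",
                      .data$age_days <= .data$event_age_days,
                      .data$age_days < .data$event_age_days),
      stage = case_when(
        !.data$alive ~ NA_character_,
        .data$age_days < .data$d_yellow ~ "yellow",
        .data$age_days < .data$d_yellow + .data$d_brown ~ "brown",
        TRUE ~ "blackhead"
      )
    )

  pairs %>%
    group_by(.data$cluster_id, .data$temperature_c, .data$rh_regime,
             .data$age_days) %>%
    summarise(
      n_alive = sum(.data$alive),
      n_yellow = sum(.data$stage == "yellow", na.rm = TRUE),
      n_brown = sum(.data$stage == "brown", na.rm = TRUE),
      n_blackhead = sum(.data$stage == "blackhead", na.rm = TRUE),
      n_hatched_cum = sum(.data$outcome == "hatched" &
                            .data$event_age_days <= .data$age_days),
      n_dead_cum = sum(.data$outcome == "died" &
                         .data$event_age_days <= .data$age_days),
      .groups = "drop"
    ) %>%
    select(all_of(cohort_columns())) %>%
    validate_cohort()
}

#' Simulate a daily mean temperature series
#'
#' Seasonal sinusoid plus stationary AR(1) noise:
#' `tmean(d) = annual_mean - annual_amplitude * cos(2 * pi * (doy(d) -
#' coldest_doy) / 365.25) + e(d)`. Defaults emulate an Ebro-Valley-like
#' Mediterranean climate (January mean around 6 degC, July around 24 degC).
#'
#' @param area Area identifier.
#' @param start_date First date of the series (`Date` or ISO string).
#' @param n_days Number of daily records (>= 1).
#' @param annual_mean,annual_amplitude Mean and seasonal semi-amplitude
#'   (degC); amplitude must be non-negative.
#' @param noise_sd Stationary standard deviation of the AR(1) noise (>= 0).
#' @param ar1_rho AR(1) autocorrelation in `[0, 1)`.
#' @param coldest_doy Day of year of the seasonal minimum.
#' @param seed Integer seed.
#' @return A temperature series tibble: `area`, `date`, `tmean_c`.
#' @export
#' @examples
#' simulate_temperature_series("urgell", "2018-10-01", 7, seed = 1)
simulate_temperature_series <- function(area = "urgell",
                                        start_date = "2018-10-01",
                                        n_days = 180,
                                        annual_mean = 15,
                                        annual_amplitude = 9,
                                        noise_sd = 1.5,
                                        ar1_rho = 0.6,
                                        coldest_doy = 15,
                                        seed = 1L) {
  stopifnot(n_days >= 1, ar1_rho >= 0, ar1_rho < 1)
  if (annual_amplitude < 0 || noise_sd < 0) {
    abort("annual_amplitude and noise_sd must be non-negative.")
  }
  dates <- as.Date(start_date) + seq_len(n_days) - 1
  doy <- as.POSIXlt(dates)$yday + 1
  seasonal <- annual_mean -
    annual_amplitude * cos(2 * pi * (doy - coldest_doy) / 365.25)
  noise <- with_seed(seed, {
    if (noise_sd == 0) {
      rep(0, n_days)
    } else {
      innov_sd <- noise_sd * sqrt(1 - ar1_rho^2)
      e <- numeric(n_days)
      e[1] <- stats::rnorm(1, sd = noise_sd)
      if (n_days > 1) {
        z <- stats::rnorm(n_days - 1, sd = innov_sd)
        for (i in 2:n_days) e[i] <- ar1_rho * e[i - 1] + z[i - 1]
      }
      e
    }
  })
  validate_temperature_series(
    tibble(area = area, date = dates, tmean_c = seasonal + noise)
  )
}

#' Simulate field stage records over an oviposition window
#'
#' Egg cohorts are laid, one per day, uniformly over the true oviposition
#' window and progress deterministically through yellow, brown and
#' head-capsule (blackhead) stages to larvae at the reference-temperature
#' stage durations. Each sampling date reports the count of cohorts in each
#' stage; reproductive-adult records start at the window start (adults
#' sampled before it are non-reproductive).
#'
#' @param window_start,window_end Dates bounding the true oviposition window.
#' @param stage_durations Named numeric (days at the reference temperature):
#'   `yellow`, `brown`, `blackhead`.
#' @param sampling_dates Dates on which fields are sampled (non-empty).
#' @param area Area identifier.
#' @param adults_per_sample Count reported for adult records.
#' @return A field-record tibble: `date`, `area`, `record_kind`, `count`.
#' @export
#' @examples
#' simulate_field_records("2018-10-15", "2019-01-31",
#'                        c(yellow = 15, brown = 23, blackhead = 12),
#'                        sampling_dates = as.Date("2018-11-01"))
simulate_field_records <- function(window_start, window_end,
                                   stage_durations,
                                   sampling_dates,
                                   area = "urgell",
                                   adults_per_sample = 5L) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  stopifnot(window_start <= window_end,
            all(c("yellow", "brown", "blackhead") %in% names(stage_durations)),
            all(stage_durations > 0))
  if (length(sampling_dates) == 0) {
    abort("sampling_dates must be non-empty.")
  }
  sampling_dates <- sort(as.Date(sampling_dates))
  y <- stage_durations[["yellow"]]
  b <- stage_durations[["brown"]]
  bh <- stage_durations[["blackhead"]]
  lay_days <- seq(window_start, window_end, by = "day")

  records <- purrr::map(sampling_dates, function(d) {
    laid <- lay_days[lay_days <= d]
    adult_kind <- if (d >= window_start) "adult_reproductive" else "adult_nonreproductive"
    out <- tibble(date = d, area = area, record_kind = adult_kind,
                  count = as.integer(adults_per_sample))
    if (length(laid) > 0) {
      age <- as.numeric(d - laid)
      kind <- case_when(
        age < y ~ "egg_yellow",
        age < y + b ~ "egg_brown",
        age < y + b + bh ~ "egg_blackhead",
        TRUE ~ "larva"
      )
      out <- bind_rows(
        out,
        tibble(date = d, area = area, record_kind = kind) %>%
          count(.data$date, .data$area, .data$record_kind, name = "count")
      )
    }
    out
  }) %>% bind_rows()
  validate_field_records(records)
}
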