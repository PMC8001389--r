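# End-to-end orchestration: simulate (optional) -> survival -> development
# time -> thermal fit -> hatch forecast -> oviposition window, with
# fail-fast configuration validation and a machine-readable run manifest.

#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [run_pipeline()].
#' When `simulate = TRUE` the laboratory cohort, temperature series and
#' field records are generated; otherwise the corresponding CSV paths must
#' exist.
#'
#' @param out_dir Output directory (created if needed).
#' @param simulate Generate synthetic inputs instead of reading CSVs?
#' @param cohort_csv,temps_csv,field_csv Input CSV paths (required for the
#'   stages that consume them when `simulate = FALSE`).
#' @param seed Integer seed governing all randomness.
#' @param alpha Significance level for post-hoc groupings, in (0, 1).
#' @param exclude_supraoptimal Drop supraoptimal rate points before the
#'   linear fit?
#' @param reference_temperature_c Reference temperature (degC) whose stage
#'   durations back-date the field records.
#' @param stage_durations Named numeric (`yellow`, `brown`, `blackhead`)
#'   days at the reference temperature, or `NULL` to derive them from the
#'   fitted medium-regime thermal parameters and the generator's stage
#'   fractions.
#' @param forecast_lay_dates Lay dates to forecast (`NULL`: the four Mondays
#'   of the first simulated October).
#' @param run_forecast,run_window Enable the forecasting / window stages.
#' @param generator A [generator_params()] object used when simulating.
#' @param design Condition grid for simulation (see [design_conditions()]).
#' @param clusters_per_condition,eggs_per_cluster Simulated cohort sizes.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("eggtherm_run_"),
                            simulate = TRUE,
                            cohort_csv = NULL,
                            temps_csv = NULL,
                            field_csv = NULL,
                            seed = 1L,
                            alpha = 0.05,
                            exclude_supraoptimal = TRUE,
                            reference_temperature_c = 8,
                            stage_durations = NULL,
                            forecast_lay_dates = NULL,
                            run_forecast = TRUE,
                            run_window = TRUE,
                            generator = generator_params(seed = seed),
                            design = design_conditions(),
                            clusters_per_condition = 20,
                            eggs_per_cluster = c(10L, 15L)) {
  stopifnot(alpha > 0, alpha < 1, is.numeric(seed))
  config <- list(
    out_dir = out_dir, simulate = simulate,
    cohort_csv = cohort_csv, temps_csv = temps_csv, field_csv = field_csv,
    seed = as.integer(seed), alpha = alpha,
    exclude_supraoptimal = exclude_supraoptimal,
    reference_temperature_c = reference_temperature_c,
    stage_durations = stage_durations,
    forecast_lay_dates = forecast_lay_dates,
    run_forecast = run_forecast, run_window = run_window,
    generator = generator,
    design = design,
    clusters_per_condition = clusters_per_condition,
    eggs_per_cluster = eggs_per_cluster
  )
  class(config) <- "pipeline_config"
  validate_pipeline_config(config)
}

validate_pipeline_config <- function(config) {
  if (!config$simulate) {
    require_file <- function(path, label, needed) {
      if (!needed) return(invisible())
      if (is.null(path) || !file.exists(path)) {
        abort(sprintf(
          "Configuration invalid: %s (%s) is required but missing.",
          label, if (is.null(path)) "no path given" else path
        ), class = "eggtherm_config_error")
      }
    }
    require_file(config$cohort_csv, "cohort_csv", TRUE)
    require_file(config$temps_csv, "temps_csv", config$run_forecast)
    require_file(config$field_csv, "field_csv", config$run_window)
  }
  if (!is.null(config$stage_durations)) {
    stopifnot(all(c("yellow", "brown", "blackhead") %in%
                    names(config$stage_durations)))
  }
  config
}

#' Read a pipeline configuration from YAML
#'
#' Reads a nested key-value configuration file and builds a validated
#' [pipeline_config()]. Keys mirror the `pipeline_config()` arguments;
#' generator parameters may be overridden under a `generator:` block.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator %||% list()
  if (!is.null(gen_args$true_t0)) gen_args$true_t0 <- unlist(gen_args$true_t0)
  if (!is.null(gen_args$true_k)) gen_args$true_k <- unlist(gen_args$true_k)
  if (!is.null(gen_args$stage_fractions)) {
    gen_args$stage_fractions <- unlist(gen_args$stage_fractions)
  }
  seed <- raw$seed %||% 1L
  if (is.null(gen_args$seed)) gen_args$seed <- seed
  args <- raw[setdiff(names(raw), "generator")]
  if (!is.null(args$stage_durations)) {
    args$stage_durations <- unlist(args$stage_durations)
  }
  args$generator <- do.call(generator_params, gen_args)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or CSVs), Kaplan-Meier
#' survival curves and log-rank tables, development-time summary, Poisson
#' GLM analysis of deviance and post-hoc letters, linear thermal-model fit
#' (T0 and K per RH regime), degree-day hatch forecasts, and the
#' oviposition-window estimate. All outputs are written as CSVs to
#' `config$out_dir` together with `manifest.json` (package version, seed,
#' configuration hash, record counts). Identical configuration and seed
#' give identical outputs.
#'
#' @param config A [pipeline_config()] object (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the output directory, the manifest, and
#'   the in-memory results of each stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  config <- validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }

  # --- inputs ---------------------------------------------------------
  results <- list()
  if (config$simulate) {
    stage("simulate", {
      sim <- simulate_experiment(
        design = config$design,
        clusters_per_condition = config$clusters_per_condition,
        eggs_per_cluster = config$eggs_per_cluster,
        params = config$generator,
        seed = config$seed
      )
      areas <- c("urgell", "segria", "baja_cinca", "monegros")
      temps <- purrr::imap(areas, function(a, i) {
        simulate_temperature_series(area = a, seed = config$seed + i)
      }) %>% bind_rows()
      observations <- sim$observations
      fates <- sim$fates
      write_cohort_observations(observations, file.path(out, "cohort.csv"))
      write_temperature_series(temps, file.path(out, "temps.csv"))
      results$fates <- fates
      results$observations <- observations
      results$temps <- temps
      inform(sprintf("simulate: %d clusters, %d eggs, %d temperature days",
                     dplyr::n_distinct(observations$cluster_id),
                     nrow(fates), nrow(temps)))
    })
  } else {
    stage("load", {
      results$observations <- read_cohort_observations(config$cohort_csv)
      results$fates <- derive_fates(results$observations)
      if (config$run_forecast) {
        results$temps <- read_temperature_series(config$temps_csv)
      }
      if (config$run_window) {
        results$field <- read_field_records(config$field_csv)
      }
    })
  }
  fates <- results$fates

  # --- survival -------------------------------------------------------
  stage("survival", {
    results$curves <- kaplan_meier(fates)
    results$logrank_overall <- logrank_test(fates)
    results$logrank_table <- logrank_by_temperature(fates)
    readr::write_csv(results$curves, file.path(out, "survival_curves.csv"))
    readr::write_csv(
      bind_rows(
        results$logrank_overall %>%
          mutate(temperature_c = NA_real_,
                 comparison = sprintf("%d conditions", .data$n_groups)) %>%
          select("temperature_c", "comparison", "chi2", "df", "p_value"),
        results$logrank_table
      ),
      file.path(out, "logrank_tests.csv")
    )
  })

  # --- development time ----------------------------------------------
  stage("devtime", {
    results$devtime <- summarize_development(fates)
    results$glm <- fit_duration_glm(fates)
    results$letters <- posthoc_groups(results$glm, "rh_regime",
                                       alpha = config$alpha)
    readr::write_csv(results$devtime, file.path(out, "devtime_summary.csv"))
    readr::write_csv(tidy(results$glm), file.path(out, "devtime_anova.csv"))
    readr::write_csv(results$letters, file.path(out, "devtime_letters.csv"))
    stages_tbl <- colour_stage_durations(fates)
    if (nrow(stages_tbl) > 0) {
      readr::write_csv(stages_tbl, file.path(out, "stage_durations.csv"))
      results$stages <- stages_tbl
    }
  })

  # --- thermal model --------------------------------------------------
  stage("thermal-fit", {
    rates <- development_rates(results$devtime)
    results$rate_fit <- fit_rate_model(
      rates, exclude_supraoptimal = config$exclude_supraoptimal
    )
    readr::write_csv(results$rate_fit$summary,
                     file.path(out, "thermal_fit.csv"))
  })
  thermal <- results$rate_fit$summary

  # stage durations at the reference temperature, for field back-dating
  ref_stages <- config$stage_durations
  if (is.null(ref_stages)) {
    med <- thermal %>% filter(.data$rh_regime == "medium", .data$valid)
    if (nrow(med) == 1) {
      total_ref <- predict_duration(med$t0, med$k,
                                    config$reference_temperature_c)
      fr <- config$generator$stage_fractions
      ref_stages <- round(total_ref * fr / sum(fr))
      names(ref_stages) <- c("yellow", "brown", "blackhead")
    }
  }

  # --- forecast -------------------------------------------------------
  if (config$run_forecast) {
    stage("forecast", {
      med <- thermal %>% filter(.data$rh_regime == "medium", .data$valid)
      if (nrow(med) != 1) {
        abort("No valid medium-regime thermal fit to forecast from.")
      }
      lay_dates <- config$forecast_lay_dates
      if (is.null(lay_dates)) {
        oct <- results$temps %>%
          filter(format(.data$date, "%m") == "10") %>%
          pull("date")
        lay_dates <- sort(unique(oct))[c(1, 8, 15, 22)]
      }
      results$forecast <- results$temps %>%
        group_by(.data$area) %>%
        group_split() %>%
        purrr::map(forecast_hatch, lay_dates = lay_dates,
                   t0 = med$t0, k = med$k) %>%
        bind_rows()
      readr::write_csv(results$forecast, file.path(out, "forecast.csv"))
    })
  }

  # --- oviposition window --------------------------------------------
  if (config$run_window) {
    stage("window", {
      if (is.null(ref_stages)) {
        abort("Stage durations unavailable; cannot back-date field records.")
      }
      if (config$simulate) {
        true_start <- as.Date("2018-10-15")
        true_end <- as.Date("2019-01-31")
        sampling <- seq(as.Date("2018-10-08"), by = "7 days",
                        length.out = 22)
        results$field <- purrr::map(
          c("urgell", "segria", "baja_cinca", "monegros"),
          function(a) {
            simulate_field_records(true_start, true_end, ref_stages,
                                   sampling_dates = sampling, area = a)
          }
        ) %>% bind_rows()
        write_field_records(results$field, file.path(out, "field.csv"))
      }
      results$window <- estimate_oviposition_window(results$field,
                                                     ref_stages)
      readr::write_csv(
        results$window %>% select(-"evidence"),
        file.path(out, "window.csv")
      )
    })
  }

  manifest <- list(
    package = "eggtherm",
    version = as.character(utils::packageVersion("eggtherm")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    outputs = sort(list.files(out)),
    n_eggs = nrow(fates),
    n_clusters = dplyr::n_distinct(fates$cluster_id)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(list(out_dir = out, manifest = manifest), results))
}
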