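# ggplot2 helpers for the main result types.

#' Plot Kaplan-Meier survival curves
#'
#' Step curves of the age-specific survival rate lx per RH regime, faceted
#' by temperature.
#'
#' @param curves A `km_curves` tibble from [kaplan_meier()].
#' @return A ggplot object.
#' @export
plot_survival <- function(curves) {
  stopifnot(all(c("time", "estimate") %in% names(curves)))
  has_regime <- "rh_regime" %in% names(curves)
  has_temp <- "temperature_c" %in% names(curves)
  mapping <- if (has_regime) {
    ggplot2::aes(x = .data$time, y = .data$estimate,
                 colour = .data$rh_regime)
  } else {
    ggplot2::aes(x = .data$time, y = .data$estimate)
  }
  p <- ggplot2::ggplot(curves, mapping) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Age (days)", y = "Survival rate (lx)",
                  colour = "RH regime") +
    ggplot2::theme_minimal()
  if (has_temp) {
    p <- p + ggplot2::facet_wrap(~temperature_c,
                                 labeller = ggplot2::label_both)
  }
  p
}

#' @rdname plot_survival
#' @param object A `km_curves` tibble.
#' @param ... Unused.
#' @method autoplot km_curves
#' @export
autoplot.km_curves <- function(object, ...) plot_survival(object)

#' Plot the linear development-rate fit
#'
#' Rate points against temperature with the fitted line per RH regime;
#' points excluded as supraoptimal are hollow.
#'
#' @param fit A `rate_fit` object from [fit_rate_model()].
#' @return A ggplot object.
#' @export
plot_rate_fit <- function(fit) {
  stopifnot(inherits(fit, "rate_fit"))
  lines <- fit$summary %>%
    filter(.data$valid) %>%
    group_by(.data$rh_regime) %>%
    group_split() %>%
    purrr::map(function(row) {
      pts <- fit$points %>%
        filter(as.character(.data$rh_regime) == row$rh_regime, .data$used)
      tibble(
        rh_regime = row$rh_regime,
        temperature_c = range(pts$temperature_c),
        rate = row$intercept + row$slope * range(pts$temperature_c)
      )
    }) %>%
    bind_rows()
  ggplot2::ggplot(fit$points,
                  ggplot2::aes(x = .data$temperature_c, y = .data$rate,
                               colour = .data$rh_regime)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(group = .data$rh_regime)) +
    ggplot2::labs(x = "Temperature (degC)",
                  y = "Development rate (1/days)", colour = "RH regime") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rate_fit
#' @param object A `rate_fit` object.
#' @param ... Unused.
#' @method autoplot rate_fit
#' @export
autoplot.rate_fit <- function(object, ...) plot_rate_fit(object)

#' Plot development time against temperature
#'
#' Mean hatch age with standard-error bars per RH regime.
#'
#' @param summaries Output of [summarize_development()].
#' @return A ggplot object.
#' @export
plot_development_time <- function(summaries) {
  stopifnot(all(c("temperature_c", "mean_days") %in% names(summaries)))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$temperature_c, y = .data$mean_days,
                               colour = .data$rh_regime)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_days - .data$se_days,
                   ymax = .data$mean_days + .data$se_days),
      width = 0.5
    ) +
    ggplot2::labs(x = "Temperature (degC)", y = "Development time (days)",
                  colour = "RH regime") +
    ggplot2::theme_minimal()
}
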