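#' Relative-humidity regime definitions
#'
#' The three RH bands maintained during egg incubation. The bounds are fixed
#' experiment metadata: high 90-100%, medium 50-75%, low 10-35%.
#'
#' @return A tibble with columns `rh_regime`, `rh_min`, `rh_max`.
#' @export
#' @examples
#' rh_regimes()
rh_regimes <- function() {
  tibble::tibble(
    rh_regime = rh_levels(),
    rh_min = c(10, 50, 90),
    rh_max = c(35, 75, 100)
  )
}

# canonical ordering, coldest-tolerance band first
rh_levels <- function() c("low", "medium", "high")

as_rh_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), rh_levels())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown RH regime(s): %s. Expected one of: %s.",
      paste(bad, collapse = ", "), paste(rh_levels(), collapse = ", ")
    ))
  }
  factor(x, levels = rh_levels())
}

#' Factorial temperature x RH experimental design
#'
#' Builds the condition grid for an egg incubation experiment. The default
#' reproduces the 8 temperatures (8-36 degC in 4 degC steps) crossed with the
#' three RH regimes, i.e. 24 conditions.
#'
#' @param temperatures Numeric vector of constant incubation temperatures
#'   (degC).
#' @param regimes Character vector of RH regimes, a subset of
#'   `c("low", "medium", "high")`.
#' @return A tibble with one row per condition: `temperature_c`, `rh_regime`.
#' @export
#' @examples
#' design_conditions()           # the full 24-condition grid
#' design_conditions(c(8, 20))   # a 2 x 3 subset
design_conditions <- function(temperatures = seq(8, 36, by = 4),
                              regimes = rh_levels()) {
  stopifnot(is.numeric(temperatures), all(is.finite(temperatures)))
  tidyr::expand_grid(
    temperature_c = as.numeric(temperatures),
    rh_regime = as_rh_factor(regimes)
  ) %>%
    arrange(.data$temperature_c, .data$rh_regime)
}
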