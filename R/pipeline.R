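#' Regression 1: geographic categories only
#'
#' Fits the obesity outcome on the four geographic categorisations (urban-
#' rural class, census division, majority ethnicity, poverty quintile) and
#' their six first-order interactions as random effects, with the ICAR
#' spatial residual — no environmental indicators.
#'
#' @param data county data frame in graph node order.
#' @param graph a [county_graph()].
#' @param config an [mcmc_config()].
#' @param outcome outcome column name.
#' @returns A `car_fit`.
#' @export
run_regression1 <- function(data, graph, config = mcmc_config(),
                            outcome = "obesity_persons") {
  fit_car(data, graph, county_model_spec(outcome, indicators = FALSE),
          config = config)
}

#' Regression 2: geographic categories plus environmental indicators
#'
#' Adds the seven unit-scaled environmental indicators (inactivity, exercise
#' access, fast-food/grocery ratio, groceries per head, food environment
#' index, percent fast-food restaurants, concentration score) to the
#' Regression 1 structure.
#'
#' @inheritParams run_regression1
#' @returns A `car_fit`.
#' @export
run_regression2 <- function(data, graph, config = mcmc_config(),
                            outcome = "obesity_persons") {
  fit_car(data, graph, county_model_spec(outcome, indicators = TRUE),
          config = config)
}

#' Compare the two regressions
#'
#' Summarises how the extended regression changes the picture relative to
#' the categories-only one: the gain in percent variation explained, the
#' change in the spatial fraction Lambda, and the shrinkage of the poverty-
#' quintile coefficients once environment is controlled for.
#'
#' @param fit1 `car_fit` from [run_regression1()].
#' @param fit2 `car_fit` from [run_regression2()].
#' @returns one-row tibble: `pct_explained_1`, `pct_explained_2`,
#'   `delta_pct_explained`, `lambda_1`, `lambda_2`, `delta_lambda`,
#'   `poverty_mean_abs_1`, `poverty_mean_abs_2`, `poverty_shrinkage`
#'   (1 - ratio of mean absolute poverty coefficients).
#' @export
compare_regressions <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "car_fit"), inherits(fit2, "car_fit"))
  p1 <- pct_variation_explained(fit1)$estimate
  p2 <- pct_variation_explained(fit2)$estimate
  l1 <- lambda_stat(fit1)$estimate
  l2 <- lambda_stat(fit2)$estimate
  pov <- function(fit) {
    td <- tidy(fit)
    mean(abs(td$estimate[grepl("^poverty_q:", td$term)]))
  }
  pv1 <- pov(fit1); pv2 <- pov(fit2)
  tibble::tibble(
    pct_explained_1 = p1, pct_explained_2 = p2,
    delta_pct_explained = p2 - p1,
    lambda_1 = l1, lambda_2 = l2, delta_lambda = l2 - l1,
    poverty_mean_abs_1 = pv1, poverty_mean_abs_2 = pv2,
    poverty_shrinkage = 1 - pv2 / pv1)
}

#' Coefficient interval plot for a fitted model
#'
#' @param object a `car_fit`.
#' @param ... unused.
#' @returns ggplot dot-and-interval chart of the fixed-effect posteriors
#'   (intercept omitted).
#' @importFrom ggplot2 autoplot
#' @export
autoplot.car_fit <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Posterior mean (95% credible interval)", y = NULL) +
    ggplot2::theme_minimal()
}
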