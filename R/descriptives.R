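#' Cross-tabulated mean rates by two county categorisations
#'
#' The descriptive geography tables: unweighted mean of county rates in each
#' cell of a two-way layout (e.g. poverty quintile by urban-rural class),
#' with "All" margins. Each county contributes to exactly one interior cell;
#' margins are count-weighted averages of their row/column cells, i.e. plain
#' means over the counties involved. Cell statistics are unweighted means of
#' county rates; pass `weight` to population-weight them instead.
#'
#' @param data data frame of county rows.
#' @param outcome name of the numeric outcome column (a rate, %).
#' @param rows,cols names of the two categorical columns.
#' @param weight optional name of a weight column (e.g. population); the
#'   default `NULL` gives unweighted county means.
#' @returns A `crosstab` tibble: `row`, `col`, `mean`, `n`, where the margins
#'   carry level `"All"`. Counties with a missing outcome are dropped with a
#'   message. Empty interior cells are reported with `mean = NA`, not zero.
#' @export
crosstab_rates <- function(data, outcome, rows, cols, weight = NULL) {
  stopifnot(is.data.frame(data))
  for (v in c(outcome, rows, cols, weight))
    if (!v %in% names(data)) stop("column not found: ", v)
  if (anyNA(data[[rows]]) || anyNA(data[[cols]]))
    stop("factors must be fully observed for all counties")
  drop <- is.na(data[[outcome]])
  if (any(drop)) {
    message(sum(drop), " counties dropped for missing outcome")
    data <- data[!drop, , drop = FALSE]
  }
  w <- if (is.null(weight)) rep(1, nrow(data)) else data[[weight]]
  d <- tibble::tibble(row = as.character(data[[rows]]),
                      col = as.character(data[[cols]]),
                      y = data[[outcome]], w = w)
  wmean <- function(y, w) sum(y * w) / sum(w)
  cell <- d |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(mean = wmean(.data$y, .data$w), n = dplyr::n(),
                     .groups = "drop")
  row_lv <- level_order(data[[rows]])
  col_lv <- level_order(data[[cols]])
  full <- tidyr::expand_grid(row = row_lv, col = col_lv) |>
    dplyr::left_join(cell, by = c("row", "col")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  row_m <- d |>
    dplyr::group_by(.data$row) |>
    dplyr::summarise(mean = wmean(.data$y, .data$w), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(col = "All")
  col_m <- d |>
    dplyr::group_by(.data$col) |>
    dplyr::summarise(mean = wmean(.data$y, .data$w), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(row = "All")
  grand <- tibble::tibble(row = "All", col = "All",
                          mean = wmean(d$y, d$w), n = nrow(d))
  out <- dplyr::bind_rows(full, row_m, col_m, grand) |>
    dplyr::select("row", "col", "mean", "n")
  structure(out, class = c("crosstab", class(out)),
            row_factor = rows, col_factor = cols, outcome = outcome)
}

level_order <- function(x) {
  if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
}

#' Spread a crosstab into the published wide layout
#' @param x a `crosstab` from [crosstab_rates()].
#' @param digits rounding for display.
#' @returns tibble with one row per row-factor level and one column per
#'   column-factor level, margins last.
#' @export
crosstab_wide <- function(x, digits = 1) {
  stopifnot(inherits(x, "crosstab"))
  tibble::as_tibble(x) |>
    dplyr::mutate(mean = round(.data$mean, digits)) |>
    dplyr::select("row", "col", "mean") |>
    tidyr::pivot_wider(names_from = "col", values_from = "mean")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("Mean", attr(x, "outcome"), "by", attr(x, "row_factor"), "x",
      attr(x, "col_factor"), "\n")
  print(crosstab_wide(x), ...)
  invisible(x)
}

#' Top-to-bottom gradient ratio
#'
#' Ratio of the mean outcome in the highest level of an ordered factor to the
#' mean in the lowest level — e.g. the high- vs low-poverty obesity ratio
#' used to compare the steepness of the female and male poverty gradients.
#'
#' @param data data frame of county rows.
#' @param outcome name of the numeric outcome column.
#' @param factor name of an ordered categorical column (ordered factor, or a
#'   column whose sorted unique values give the order).
#' @returns scalar ratio `mean(top) / mean(bottom)`.
#' @export
gradient_ratio <- function(data, outcome, factor) {
  stopifnot(is.data.frame(data))
  for (v in c(outcome, factor))
    if (!v %in% names(data)) stop("column not found: ", v)
  lv <- level_order(data[[factor]])
  if (length(lv) < 2) stop("factor needs at least 2 ordered levels")
  f <- as.character(data[[factor]])
  top <- data[[outcome]][f == lv[length(lv)]]
  bot <- data[[outcome]][f == lv[1]]
  if (!length(top) || !length(bot)) stop("extreme levels must be non-empty")
  mb <- mean(bot, na.rm = TRUE)
  if (mb == 0) stop("bottom-level mean is zero")
  mean(top, na.rm = TRUE) / mb
}

#' Mean outcome by indicator quintile
#'
#' Quintile profile of an outcome against an indicator: counties are assigned
#' to indicator quintiles ([quintile_assign()]) and the unweighted mean
#' outcome per quintile is returned — the bar-profile summaries relating
#' obesity to exercise access, the food environment index, the concentration
#' score, and poverty.
#'
#' @param data data frame of county rows.
#' @param outcome name of the numeric outcome column.
#' @param indicator name of the numeric indicator column (>= 5 distinct
#'   values).
#' @param breaks optional fixed cutpoints forwarded to [quintile_assign()].
#' @returns tibble with `quintile` (1-5), `mean`, `n`, and attribute
#'   `cutpoints`.
#' @export
quintile_profile <- function(data, outcome, indicator, breaks = NULL) {
  stopifnot(is.data.frame(data))
  for (v in c(outcome, indicator))
    if (!v %in% names(data)) stop("column not found: ", v)
  x <- data[[indicator]]
  if (length(unique(x)) < 5)
    stop("indicator needs at least 5 distinct values")
  q <- quintile_assign(x, breaks = breaks)
  out <- tibble::tibble(quintile = as.integer(q), y = data[[outcome]]) |>
    dplyr::group_by(.data$quintile) |>
    dplyr::summarise(mean = mean(.data$y, na.rm = TRUE), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$quintile)
  attr(out, "cutpoints") <- attr(q, "cutpoints")
  out
}

#' Plot a quintile profile
#' @param profile tibble from [quintile_profile()].
#' @param xlab,ylab axis labels.
#' @returns a ggplot bar chart.
#' @export
plot_quintile_profile <- function(profile, xlab = "Quintile",
                                  ylab = "Mean rate (%)") {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$quintile), y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
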