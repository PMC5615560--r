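#' Rescale a vector to the unit interval
#'
#' The covariate rescaling used before regression so coefficient magnitudes
#' are comparable: `(x - min(x)) / (max(x) - min(x))`. The observed minimum
#' maps to 0 and the maximum to 1; the map is order-preserving and idempotent.
#'
#' @param x numeric vector, length >= 2, non-constant, no missing values.
#' @returns numeric vector in `[0, 1]`.
#' @examples
#' scale_unit(c(2, 4, 6))
#' @export
scale_unit <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to rescale")
  if (anyNA(x)) stop("missing values in covariate")
  rng <- range(x)
  if (rng[2] - rng[1] <= 0)
    stop("constant vector: zero range, cannot rescale to [0, 1]")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Concentration score: leading principal component of settlement indices
#'
#' Summarises dispersed, car-dependent settlement in a single standardised
#' score: the leading principal component (correlation-matrix PCA) of five
#' county indices — percent car commuting, percent public-transport
#' commuting, percent walking/cycling commuting, percent post-1950 housing,
#' and population density. The sign is fixed so the loading on car commuting
#' is negative: highly negative scores mark the most dispersed, car-dependent
#' counties, positive scores the most concentrated. Scores are standardised
#' to unit variance.
#'
#' @param data data frame of county rows.
#' @param cols names of the five columns, in the order car commuting,
#'   public-transport commuting, walking/cycling commuting, post-1950
#'   housing, population density.
#' @returns numeric score vector (one per row) with attributes `loadings`
#'   (named 5-vector) and `eigenvalues`.
#' @export
concentration_score <- function(data,
                                cols = c("car_commute",
                                         "public_transport_commute",
                                         "walk_cycle_commute",
                                         "post1950_housing",
                                         "pop_density")) {
  stopifnot(is.data.frame(data), length(cols) == 5)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  M <- as.matrix(data[cols])
  if (nrow(M) < 6) stop("need at least 6 counties for the component score")
  if (anyNA(M)) stop("missing values in settlement indices")
  sds <- apply(M, 2, stats::sd)
  if (any(sds <= 0))
    stop("zero-variance column(s): ", paste(cols[sds <= 0], collapse = ", "))
  pc <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  if ((ev[1] - ev[2]) / ev[1] < 1e-10)
    stop("degenerate leading eigenvalue gap; eigenvalues: ",
         paste(signif(ev, 6), collapse = ", "))
  load1 <- pc$rotation[, 1]
  if (load1[1] > 0) load1 <- -load1  # car commuting must load negatively
  score <- as.vector(scale(M) %*% load1)
  score <- score / stats::sd(score)
  attr(score, "loadings") <- stats::setNames(load1, cols)
  attr(score, "eigenvalues") <- ev
  score
}

#' Food environment index from its two components
#'
#' Reconstructs a 0-10 food-environment score that equally weights two
#' county measures: percent of the population with limited access to healthy
#' foods, and percent food insecure. Each component is min-max scaled over
#' the cohort to a 0-10 "badness" scale, the two are averaged with equal
#' weight, and the result is reversed so 10 marks the best food environments
#' and 0 the worst. The exact normalisation behind published versions of the
#' index is not specified; this is a documented reconstruction, and a
#' precomputed index column can be used instead throughout the package.
#'
#' @param limited_access percent of population with limited healthy-food
#'   access, in `[0, 100]`.
#' @param food_insecurity percent food insecure, in `[0, 100]`.
#' @returns numeric vector in `[0, 10]`; 10 = best environment.
#' @export
food_environment_index <- function(limited_access, food_insecurity) {
  stopifnot(length(limited_access) == length(food_insecurity))
  for (v in list(limited_access, food_insecurity)) {
    if (anyNA(v) || any(v < 0 | v > 100))
      stop("components must be percentages in [0, 100]")
  }
  bad1 <- 10 * scale_unit(limited_access)
  bad2 <- 10 * scale_unit(food_insecurity)
  10 - (bad1 + bad2) / 2
}

#' Assign counties to quintiles
#'
#' Labels each value 1-5 by the empirical 20/40/60/80 percentiles of the
#' cohort (or by supplied fixed cutpoints, e.g. published poverty breaks).
#' Intervals are half-open and lower-closed: a value equal to a cutpoint
#' belongs to the higher quintile. Quintile 1 holds the lowest values.
#'
#' @param x numeric vector, length >= 5.
#' @param breaks optional numeric vector of 4 increasing interior cutpoints;
#'   default uses empirical quantiles of `x`.
#' @returns integer vector of labels 1-5 with attribute `cutpoints`
#'   (the 4 interior cutpoints used).
#' @examples
#' quintile_assign(c(10, 25), breaks = c(11.8, 14.7, 18, 22.1))
#' @export
quintile_assign <- function(x, breaks = NULL) {
  if (anyNA(x)) stop("missing values in x")
  empirical <- is.null(breaks)
  if (empirical) {
    if (length(x) < 5) stop("need at least 5 values for empirical quintiles")
    breaks <- unname(stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 7))
  } else {
    if (length(breaks) != 4 || is.unsorted(breaks, strictly = FALSE))
      stop("breaks must be 4 non-decreasing cutpoints")
  }
  if (anyDuplicated(breaks))
    stop("tied cutpoints leave empty quintile(s): ",
         paste(unique(breaks[duplicated(breaks)]), collapse = ", "))
  q <- findInterval(x, breaks) + 1L  # lower-closed: x == cutpoint -> higher
  if (empirical && !all(seq_len(5L) %in% q))
    stop("heavy ties leave empty quintile(s) at cutpoints: ",
         paste(signif(breaks, 6), collapse = ", "))
  attr(q, "cutpoints") <- breaks
  q
}
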