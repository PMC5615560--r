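#' Posterior draws of the spatial fraction Lambda
#'
#' For each retained draw, `Lambda = var(s) / (var(s) + sigma2_u)`, where
#' `var(s)` is the empirical marginal variance of the spatial-effect vector
#' across counties at that draw. Values near 1 indicate residual variation
#' dominated by the spatially clustered component.
#'
#' @param fit a `car_fit` (or a list with numeric vectors `var_s` and
#'   `sigma2_u` of equal length).
#' @returns numeric vector of Lambda draws in `[0, 1]`.
#' @export
lambda_draws <- function(fit) {
  if (inherits(fit, "car_fit")) {
    vs <- pool_draws(fit, "var_s")[, 1]
    su <- pool_draws(fit, "sigma2_u")[, 1]
  } else {
    vs <- fit$var_s
    su <- fit$sigma2_u
  }
  stopifnot(length(vs) == length(su))
  tot <- vs + su
  if (any(tot <= 0)) stop("var(s) + sigma2_u is zero at some draw")
  vs / tot
}

#' Summarise the spatial fraction Lambda
#'
#' @inheritParams lambda_draws
#' @param prob credible-interval probability (equal-tailed).
#' @returns one-row tibble: `estimate` (posterior mean), `conf.low`,
#'   `conf.high`.
#' @export
lambda_stat <- function(fit, prob = 0.95) {
  d <- lambda_draws(fit)
  a <- (1 - prob) / 2
  tibble::tibble(estimate = mean(d),
                 conf.low = unname(stats::quantile(d, a)),
                 conf.high = unname(stats::quantile(d, 1 - a)))
}

#' Posterior percent of outcome variation explained
#'
#' `100 * (1 - Total Residual Variation / Total Variation)` per draw, where
#' total variation is the empirical variance of the outcome and total
#' residual variation is `var(s) + sigma2_u` at that draw (the model-based
#' residual partition). Set `realised = TRUE` to use the realised residuals
#' `y - X beta - s - interactions` instead.
#'
#' @param fit a `car_fit`, or a list with numeric vectors `var_s` and
#'   `sigma2_u` (in which case `y` is required and `realised` unavailable).
#' @param y outcome vector; defaults to the outcome stored in the fit.
#' @param realised use realised squared residuals rather than the
#'   model-based `var(s) + sigma2_u` partition.
#' @param prob credible-interval probability.
#' @returns one-row tibble: `estimate`, `conf.low`, `conf.high` (percent).
#' @export
pct_variation_explained <- function(fit, y = NULL, realised = FALSE,
                                    prob = 0.95) {
  if (!inherits(fit, "car_fit")) {
    stopifnot(is.list(fit), !realised, !is.null(y))
    tot <- stats::var(y)
    if (tot == 0) stop("outcome has zero variance")
    d <- 100 * (1 - (fit$var_s + fit$sigma2_u) / tot)
    a <- (1 - prob) / 2
    return(tibble::tibble(estimate = mean(d),
                          conf.low = unname(stats::quantile(d, a)),
                          conf.high = unname(stats::quantile(d, 1 - a))))
  }
  y <- y %||% fit$y
  tot <- stats::var(y)
  if (tot == 0) stop("outcome has zero variance")
  if (!realised) {
    resid_var <- pool_draws(fit, "var_s")[, 1] + pool_draws(fit, "sigma2_u")[, 1]
  } else {
    beta <- pool_draws(fit, "beta")
    xb <- fit$design$X %*% t(beta)  # n x draws
    sdr <- if (fit$design$spec$spatial) t(pool_draws(fit, "s")) else 0
    resid_var <- apply(y - xb - sdr, 2, stats::var)
  }
  d <- 100 * (1 - resid_var / tot)
  a <- (1 - prob) / 2
  tibble::tibble(estimate = mean(d),
                 conf.low = unname(stats::quantile(d, a)),
                 conf.high = unname(stats::quantile(d, 1 - a)))
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Split-chain PSRF: each chain is halved, and the factor is
#' `sqrt(((n - 1)/n * W + B/n) / W)` over the resulting half-chains, with
#' `W` the mean within-chain variance and `B/n` the between-chain variance
#' of the half-chain means. Values near 1 indicate convergence; the package
#' flags parameters above 1.1.
#'
#' @param chains numeric matrix of draws, iterations x chains (>= 2 chains
#'   before splitting, >= 10 draws each), or a list of equal-length numeric
#'   vectors.
#' @param split halve each chain before computing (default `TRUE`).
#' @returns scalar PSRF (>= 1 up to numerical tolerance).
#' @export
bgr_diagnostic <- function(chains, split = TRUE) {
  if (is.list(chains) && !is.data.frame(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1) stop("chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2) stop("need at least 2 chains")
  if (nrow(chains) < 10) stop("need at least 10 draws per chain")
  if (split) {
    h <- nrow(chains) %/% 2
    chains <- cbind(chains[seq_len(h), , drop = FALSE],
                    chains[(nrow(chains) - h + 1):nrow(chains), , drop = FALSE])
  }
  n <- nrow(chains); m <- ncol(chains)
  W <- mean(apply(chains, 2, stats::var))
  if (W == 0) stop("zero within-chain variance in all chains")
  B_over_n <- stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Metric report for a fitted model
#'
#' Bundles the derived inference metrics: posterior mean and 95% interval of
#' the spatial fraction Lambda, percent variation explained, and the
#' per-parameter BGR factors with a convergence flag at 1.1.
#'
#' @param fit a `car_fit`.
#' @returns list of class `metric_report`: `lambda` and `pct_explained`
#'   one-row tibbles, `bgr` tibble (`term`, `rhat`, `converged`).
#' @export
metric_report <- function(fit) {
  stopifnot(inherits(fit, "car_fit"))
  ps <- posterior_summary(fit)
  bgr <- ps |>
    dplyr::filter(!is.na(.data$rhat)) |>
    dplyr::transmute(term = .data$term, rhat = .data$rhat,
                     converged = .data$rhat < 1.1)
  structure(list(
    lambda = if (fit$design$spec$spatial) lambda_stat(fit) else NULL,
    pct_explained = pct_variation_explained(fit),
    bgr = bgr), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  if (!is.null(x$lambda))
    cat(sprintf("Spatial fraction Lambda: %.3f (%.3f, %.3f)\n",
                x$lambda$estimate, x$lambda$conf.low, x$lambda$conf.high))
  cat(sprintf("%% variation explained:   %.1f (%.1f, %.1f)\n",
              x$pct_explained$estimate, x$pct_explained$conf.low,
              x$pct_explained$conf.high))
  cat(sprintf("BGR: %d/%d parameters converged (max %.3f)\n",
              sum(x$bgr$converged), nrow(x$bgr), max(x$bgr$rhat)))
  invisible(x)
}
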