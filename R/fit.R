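#' MCMC settings for the Gibbs sampler
#'
#' Defaults follow the analysis protocol: inference from the second half of a
#' two-chain run of 10,000 iterations, no thinning. Priors: Gaussian
#' `N(0, beta_prior_var)` on fixed effects and `Gamma(shape, rate)` on every
#' precision (IID, spatial, and each interaction block) — the vague
#' disease-mapping defaults `Gamma(0.5, 0.0005)`.
#'
#' @param n_chains number of chains (>= 2 so the Brooks-Gelman-Rubin
#'   diagnostic is defined).
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations per chain (default first half).
#' @param seed integer seed governing all chains (chain c uses `seed + c`).
#' @param beta_prior_var prior variance of fixed effects.
#' @param prec_shape,prec_rate Gamma prior on precisions.
#' @returns An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 10000,
                        burn_in = n_iter %/% 2, seed = 1,
                        beta_prior_var = 1e6,
                        prec_shape = 0.5, prec_rate = 5e-4) {
  stopifnot(n_chains >= 1, n_iter >= 2, burn_in >= 0, burn_in < n_iter,
            beta_prior_var > 0, prec_shape > 0, prec_rate > 0)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 beta_prior_var = beta_prior_var,
                 prec_shape = prec_shape, prec_rate = prec_rate),
            class = "mcmc_config")
}

#' Fit the spatial county regression by Gibbs sampling
#'
#' Samples the hierarchically centred model
#' `y_i ~ N(X_i beta + s_i + sum_k gamma_k[cell], sigma2_u)` with an
#' intrinsic CAR prior on `s` (conditional variance `sigma2_s / L_i`,
#' sum-to-zero recentring each sweep) and exchangeable Gaussian interaction
#' cells. Full conditionals are conjugate throughout; chains start
#' overdispersed around the OLS fit (`beta = OLS +/- 2c SE`, variances at
#' 0.5x / 2x the method-of-moments residual variance).
#'
#' @param y numeric outcome vector, aligned with `design` rows and
#'   `graph$node_ids`.
#' @param design a `car_design` from [build_design()].
#' @param graph a [county_graph()] (required when the spec includes the
#'   spatial term; pass `NULL` otherwise).
#' @param config an [mcmc_config()].
#' @param fix_sigma2_u fix the IID residual variance at this value instead of
#'   sampling it (used by conjugate-oracle checks). `NULL` to sample.
#' @param fix_sigma2_s fix the spatial conditional variance (e.g. at a value
#'   near zero to force the IID submodel). `NULL` to sample.
#' @returns A `car_fit` object holding per-chain posterior draws (`beta`,
#'   `s`, `sigma2_u`, `sigma2_s`, `var_s`, interaction variances and
#'   effects), the design, outcome, graph and config.
#' @export
fit_gibbs <- function(y, design, graph = NULL, config = mcmc_config(),
                      fix_sigma2_u = NULL, fix_sigma2_s = NULL) {
  stopifnot(inherits(design, "car_design"), inherits(config, "mcmc_config"))
  X <- design$X
  n <- nrow(X)
  if (length(y) != n) stop("outcome length does not match design rows")
  if (anyNA(y)) stop("missing outcome values")
  spatial <- design$spec$spatial
  if (spatial) {
    if (is.null(graph)) stop("spatial model requires an adjacency graph")
    stopifnot(inherits(graph, "county_graph"))
    if (n_nodes(graph) != n)
      stop("graph has ", n_nodes(graph), " nodes but data has ", n, " counties")
    if (!graph_connected(graph, ignore_islands = TRUE))
      stop("graph must be connected (islands aside)")
    csr <- graph_csr(graph)
  } else {
    csr <- list(adj = integer(0), adj_start = rep(0L, n), nnbr = rep(0L, n))
  }
  K <- length(design$interaction)
  zcell <- if (K) do.call(cbind, lapply(design$interaction,
                                        function(b) b$cell - 1L))
  else matrix(0L, n, 0)
  ncell <- vapply(design$interaction, function(b) b$n_cells, integer(1))

  # overdispersed chain starts around OLS
  ols <- stats::lm.fit(X, y)
  bhat <- ols$coefficients
  res_var <- sum(ols$residuals^2) / max(1, n - ncol(X))
  se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * res_var)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    sign_ch <- if (ch %% 2 == 1) 1 else -1
    beta_init <- bhat + sign_ch * 2 * ch * se
    vf <- if (ch %% 2 == 1) 0.5 else 2
    chains[[ch]] <- gibbs_car_chain(
      y = y, X = X,
      adj = csr$adj, adj_start = csr$adj_start, nnbr = csr$nnbr,
      zcell = zcell, ncell = as.integer(ncell),
      n_iter = config$n_iter, n_burn = config$burn_in,
      beta_prior_var = config$beta_prior_var,
      prec_shape = config$prec_shape, prec_rate = config$prec_rate,
      beta_init = beta_init,
      s2u_init = if (is.null(fix_sigma2_u)) vf * res_var else fix_sigma2_u,
      s2s_init = if (is.null(fix_sigma2_s)) vf * res_var else fix_sigma2_s,
      gvar_init = vf * res_var / 4,
      spatial = spatial,
      fix_s2u = !is.null(fix_sigma2_u), fix_s2s = !is.null(fix_sigma2_s))
    colnames(chains[[ch]]$beta) <- colnames(X)
    if (K) {
      colnames(chains[[ch]]$interaction_var) <- names(design$interaction)
      colnames(chains[[ch]]$interaction_effects) <-
        unlist(lapply(seq_len(K), function(k)
          paste0(names(design$interaction)[k], ": ",
                 design$interaction[[k]]$labels)))
    }
    n_fl <- chains[[ch]]$n_floored
    if (n_fl > 0)
      message("chain ", ch, ": variance floor applied ", n_fl, " time(s)")
  }
  structure(list(chains = chains, design = design, y = y, graph = graph,
                 config = config, terms = colnames(X),
                 interaction_names = names(design$interaction)),
            class = "car_fit")
}

#' Fit the county model from a data frame
#'
#' Data-frame-first wrapper: builds the design from `spec`, extracts the
#' outcome, and runs [fit_gibbs()].
#'
#' @param data data frame of county rows (one per graph node, in node order).
#' @param graph a [county_graph()] aligned with `data` rows.
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()].
#' @param ... passed to [fit_gibbs()].
#' @returns A `car_fit`.
#' @export
fit_car <- function(data, graph, spec, config = mcmc_config(), ...) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$outcome %in% names(data))
    stop("outcome column not found: ", spec$outcome)
  design <- build_design(data, spec)
  fit_gibbs(data[[spec$outcome]], design, graph = graph, config = config, ...)
}

# pooled post-burn-in draws of one quantity, stacked across chains
pool_draws <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, function(ch) as.matrix(ch[[what]])))
}

# per-chain draws of scalar series as a matrix (iterations x chains)
chain_matrix <- function(fit, what, column = 1) {
  vapply(fit$chains, function(ch) as.matrix(ch[[what]])[, column],
         numeric(nrow(as.matrix(fit$chains[[1]][[what]]))))
}

#' Posterior summary table
#'
#' Pooled posterior means and equal-tailed 95% credible intervals for every
#' fixed effect, the variance components, the interaction-block variances,
#' and the derived statistics (spatial fraction Lambda and percent variation
#' explained), plus split-chain Brooks-Gelman-Rubin factors.
#'
#' @param fit a `car_fit`.
#' @param prob interval probability (default 0.95, equal-tailed).
#' @returns tibble with `term`, `type`, `estimate`, `conf.low`, `conf.high`,
#'   `rhat`, rows ordered as the published tables (metrics, intercept and
#'   fixed effects, interaction variances, variance components).
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "car_fit"))
  a <- (1 - prob) / 2
  one <- function(draws, term, type, chains_mat = NULL) {
    if (!length(draws)) stop("empty posterior sample for ", term)
    tibble::tibble(
      term = term, type = type, estimate = mean(draws),
      conf.low = unname(stats::quantile(draws, a, type = 7)),
      conf.high = unname(stats::quantile(draws, 1 - a, type = 7)),
      rhat = if (is.null(chains_mat)) NA_real_ else
        tryCatch(bgr_diagnostic(chains_mat), error = function(e) NA_real_))
  }
  if (nrow(as.matrix(fit$chains[[1]]$beta)) *
      length(fit$chains) < 100)
    stop("need at least 100 retained draws for a posterior summary")
  beta <- pool_draws(fit, "beta")
  rows <- purrr::map(seq_along(fit$terms), function(j)
    one(beta[, j], fit$terms[j], "fixed",
        chain_matrix(fit, "beta", j)))
  out <- dplyr::bind_rows(rows)
  spatial <- fit$design$spec$spatial
  metric_rows <- dplyr::bind_rows(
    one(100 * (1 - (pool_draws(fit, "var_s")[, 1] +
                      pool_draws(fit, "sigma2_u")[, 1]) / stats::var(fit$y)),
        "% variation explained", "metric"),
    if (spatial)
      one(100 * lambda_draws(fit), "% of residual variation spatially structured",
          "metric"))
  var_rows <- dplyr::bind_rows(
    one(pool_draws(fit, "sigma2_u")[, 1], "sigma2_u", "variance",
        chain_matrix(fit, "sigma2_u")),
    if (spatial)
      one(pool_draws(fit, "sigma2_s")[, 1], "sigma2_s", "variance",
          chain_matrix(fit, "sigma2_s")))
  int_rows <- if (length(fit$interaction_names)) {
    iv <- pool_draws(fit, "interaction_var")
    dplyr::bind_rows(purrr::map(seq_along(fit$interaction_names), function(k)
      one(iv[, k], fit$interaction_names[k], "interaction variance",
          chain_matrix(fit, "interaction_var", k))))
  }
  dplyr::bind_rows(metric_rows, out, int_rows, var_rows)
}

#' @export
print.car_fit <- function(x, ...) {
  cat("<car_fit> ", length(x$y), " counties, ", length(x$terms),
      " fixed effects, ", length(x$interaction_names),
      " interaction block(s), ",
      length(x$chains), " chain(s) x ",
      x$config$n_iter - x$config$burn_in, " retained draws\n", sep = "")
  print(posterior_summary(x), n = 15)
  invisible(x)
}

#' Tidy method for `car_fit`
#'
#' @param x a `car_fit`.
#' @param ... unused.
#' @returns tibble of fixed-effect posterior summaries in broom layout
#'   (`term`, `estimate`, `conf.low`, `conf.high`, `rhat`).
#' @export
tidy.car_fit <- function(x, ...) {
  posterior_summary(x) |>
    dplyr::filter(.data$type == "fixed") |>
    dplyr::select("term", "estimate", "conf.low", "conf.high", "rhat")
}

#' Glance method for `car_fit`
#'
#' @param x a `car_fit`.
#' @param ... unused.
#' @returns one-row tibble: counties, chains, retained draws, posterior mean
#'   `sigma2_u`, `sigma2_s`, `lambda`, `pct_explained`, and the largest
#'   fixed-effect BGR factor.
#' @export
glance.car_fit <- function(x, ...) {
  ps <- posterior_summary(x)
  spatial <- x$design$spec$spatial
  tibble::tibble(
    n = length(x$y),
    n_chains = length(x$chains),
    n_draws = nrow(pool_draws(x, "sigma2_u")),
    sigma2_u = ps$estimate[ps$term == "sigma2_u"],
    sigma2_s = if (spatial) ps$estimate[ps$term == "sigma2_s"] else NA_real_,
    lambda = if (spatial) mean(lambda_draws(x)) else NA_real_,
    pct_explained = ps$estimate[ps$term == "% variation explained"],
    max_rhat = max(ps$rhat, na.rm = TRUE))
}

#' Generic tidy (broom-style)
#' @param x object to tidy.
#' @param ... method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic glance (broom-style)
#' @param x object to summarise.
#' @param ... method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
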