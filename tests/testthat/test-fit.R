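# small helper: IID-model data frame with a few covariates
iid_testdata <- function(n, p = 3, beta = NULL, sd = 1) {
  X <- matrix(runif(n * p), n)
  colnames(X) <- paste0("x", seq_len(p))
  beta <- beta %||% rep(0, p)
  y <- 5 + X %*% beta + rnorm(n, sd = sd)
  d <- tibble::as_tibble(as.data.frame(X))
  d$y <- as.vector(y)
  d
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("with spatial and interactions off the beta posterior is conjugate", {
  set.seed(17)
  d <- iid_testdata(150, p = 3, beta = c(2, -1, 0.5))
  spec <- model_spec("y", factors = c(), covariates = paste0("x", 1:3),
                     spatial = FALSE)
  ds <- build_design(d, spec)
  s2u <- 1.3
  fit <- fit_gibbs(d$y, ds, config = mcmc_config(n_iter = 6000, seed = 4),
                   fix_sigma2_u = s2u)
  draws <- do.call(rbind, lapply(fit$chains, function(ch) ch$beta))
  # closed-form Gaussian posterior
  tau <- 1e6
  V <- solve(crossprod(ds$X) / s2u + diag(ncol(ds$X)) / tau)
  m <- V %*% crossprod(ds$X, d$y) / s2u
  nd <- nrow(draws)
  for (j in seq_len(ncol(draws))) {
    mc_se <- sd(draws[, j]) / sqrt(nd)
    expect_lt(abs(mean(draws[, j]) - m[j]), 4 * mc_se)
    expect_equal(var(draws[, j]), V[j, j], tolerance = 0.1)
  }
  cov_emp <- cov(draws)
  expect_equal(cov_emp, V, tolerance = 0.15, ignore_attr = TRUE)
})

test_that("null slopes are covered by 95% intervals at near-nominal rate", {
  set.seed(23)
  hits <- matrix(NA, 20, 2)
  for (r in 1:20) {
    d <- iid_testdata(120, p = 2)
    spec <- model_spec("y", factors = c(), covariates = c("x1", "x2"),
                       spatial = FALSE)
    fit <- fit_car(d, graph = NULL, spec,
                   mcmc_config(n_iter = 1200, seed = 1000 + r))
    td <- tidy(fit)
    sl <- td[td$term != "(Intercept)", ]
    hits[r, ] <- sl$conf.low <= 0 & sl$conf.high >= 0
  }
  expect_gte(sum(hits[, 1]), 18)
  expect_gte(sum(hits[, 2]), 18)
})

test_that("adding a constant to y shifts only the intercept", {
  set.seed(12)
  sim <- simulate_county_data(sim_config(rows = 6, cols = 9, seed = 6))
  cfg <- mcmc_config(n_iter = 1500, seed = 77)
  f1 <- run_regression2(sim$data, sim$graph, cfg)
  d2 <- sim$data
  d2$obesity_persons <- d2$obesity_persons + 10
  f2 <- run_regression2(d2, sim$graph, cfg)
  t1 <- tidy(f1); t2 <- tidy(f2)
  shift <- t2$estimate - t1$estimate
  expect_equal(shift[t1$term == "(Intercept)"], 10, tolerance = 1e-2)
  expect_lt(max(abs(shift[t1$term != "(Intercept)"])), 1e-2)
})

test_that("county relabelling with the graph permuted leaves summaries alike", {
  set.seed(3)
  sim <- simulate_county_data(sim_config(rows = 10, cols = 10, seed = 9))
  cfg <- mcmc_config(n_iter = 2500, seed = 31)
  f1 <- run_regression2(sim$data, sim$graph, cfg)
  perm <- sample(nrow(sim$data))
  d2 <- sim$data[perm, ]
  g <- sim$graph
  g2 <- county_graph(g$node_ids[perm],
                     lapply(g$node_ids[perm], function(i) g$neighbours[[i]]))
  f2 <- run_regression2(d2, g2, cfg)
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t2$term, t1$term)
  sd1 <- (t1$conf.high - t1$conf.low) / 4
  expect_true(all(abs(t2$estimate - t1$estimate) < 0.35 * sd1 + 0.02))
})

test_that("forcing sigma2_s to zero reproduces the IID-model fit", {
  set.seed(44)
  d <- iid_testdata(150, p = 2, beta = c(3, -2))
  g <- grid_graph(10, 15)
  spec_sp <- model_spec("y", factors = c(), covariates = c("x1", "x2"),
                        spatial = TRUE)
  spec_iid <- model_spec("y", factors = c(), covariates = c("x1", "x2"),
                         spatial = FALSE)
  dsp <- build_design(d, spec_sp)
  dii <- build_design(d, spec_iid)
  f_sp <- fit_gibbs(d$y, dsp, g, mcmc_config(n_iter = 3000, seed = 2),
                    fix_sigma2_s = 1e-10)
  f_iid <- fit_gibbs(d$y, dii, NULL, mcmc_config(n_iter = 3000, seed = 8))
  t1 <- tidy(f_sp); t2 <- tidy(f_iid)
  sd1 <- (t1$conf.high - t1$conf.low) / 4
  expect_true(all(abs(t1$estimate - t2$estimate) < 0.2 * sd1 + 0.01))
})

test_that("summaries are stable across chain seeds within Monte Carlo error", {
  set.seed(10)
  sim <- simulate_county_data(sim_config(rows = 20, cols = 20, seed = 20))
  fA <- run_regression2(sim$data, sim$graph, mcmc_config(n_iter = 4000, seed = 1))
  fB <- run_regression2(sim$data, sim$graph, mcmc_config(n_iter = 4000, seed = 3))
  tA <- tidy(fA); tB <- tidy(fB)
  batch_se <- function(fit, n_batch = 20) {
    # batch means over the retained draws of each chain, pooled
    draws <- do.call(rbind, lapply(fit$chains, function(ch) ch$beta))
    nb <- nrow(draws) %/% n_batch
    bm <- sapply(seq_len(n_batch), function(b)
      colMeans(draws[((b - 1) * nb + 1):(b * nb), , drop = FALSE]))
    apply(bm, 1, sd) / sqrt(n_batch)
  }
  se <- sqrt(batch_se(fA)^2 + batch_se(fB)^2)
  expect_true(all(abs(tA$estimate - tB$estimate) < 3 * se + 0.02))
})

test_that("summary intervals match an independent sort-based quantile", {
  set.seed(2)
  sim <- simulate_county_data(sim_config(rows = 6, cols = 9, seed = 13))
  fit <- run_regression1(sim$data, sim$graph, mcmc_config(n_iter = 600, seed = 5))
  td <- tidy(fit)
  draws <- do.call(rbind, lapply(fit$chains, function(ch) ch$beta))
  sort_quantile <- function(v, p) {
    # type-7 interpolation written out directly
    v <- sort(v); h <- (length(v) - 1) * p
    lo <- floor(h) + 1
    v[lo] + (h - floor(h)) * (v[min(lo + 1, length(v))] - v[lo])
  }
  for (j in c(1, 5, ncol(draws))) {
    expect_equal(td$conf.low[j], sort_quantile(draws[, j], 0.025),
                 tolerance = 1e-12)
    expect_equal(td$conf.high[j], sort_quantile(draws[, j], 0.975),
                 tolerance = 1e-12)
    expect_equal(td$estimate[j], mean(draws[, j]), tolerance = 1e-12)
  }
})

test_that("retained spatial draws respect the sum-to-zero identification", {
  sim <- simulate_county_data(sim_config(rows = 6, cols = 9, seed = 3))
  fit <- run_regression1(sim$data, sim$graph, mcmc_config(n_iter = 400, seed = 2))
  for (ch in fit$chains) {
    expect_lt(max(abs(rowSums(ch$s))), 1e-8)
    expect_true(all(ch$sigma2_u > 0))
    expect_true(all(ch$sigma2_s > 0))
    expect_true(all(ch$interaction_var > 0))
  }
})

test_that("misaligned inputs are rejected", {
  sim <- simulate_county_data(sim_config(rows = 6, cols = 9, seed = 3))
  small <- grid_graph(3, 3)
  expect_error(run_regression1(sim$data, small, mcmc_config(n_iter = 100)),
               "54 counties")
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
})
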