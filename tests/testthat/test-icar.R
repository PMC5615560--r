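test_that("conditional moments follow the neighbour-average / sigma2/L rule", {
  g <- path_graph(3)
  # middle node: neighbours' effects 1 and 3, sigma2 = 2 -> N(2, 1)
  out <- icar_conditional_params("2", c(1, 0, 3), g, sigma2_s = 2)
  expect_equal(out$mean, 2)
  expect_equal(out$variance, 1)
  # end node: single neighbour -4, sigma2 = 5 -> N(-4, 5)
  out <- icar_conditional_params("1", c(0, -4, 7), g, sigma2_s = 5)
  expect_equal(out$mean, -4)
  expect_equal(out$variance, 5)
})

test_that("island nodes have no conditional and the error says why", {
  g <- county_graph(c("a", "b", "c"), list(a = "b", b = "a", c = character(0)))
  expect_error(icar_conditional_params("c", c(0, 0, 0), g, 1), "island")
})

test_that("log density is the pairwise-difference quadratic form", {
  g <- path_graph(4)
  expect_equal(icar_log_density(rep(2, 4), g, 1), 0)  # constants are free
  g2 <- path_graph(2)
  expect_equal(icar_log_density(c(1, -1), g2, 1), -2)  # (1-(-1))^2 / 2
  # shift invariance through the sum-to-zero projection
  s <- c(0.3, -0.8, 0.1, 0.4)
  expect_equal(icar_log_density(s + 5, g, 1.7), icar_log_density(s, g, 1.7))
  # disconnected graphs are rank-deficient beyond the single constraint
  gd <- county_graph(c("a", "b", "c", "d"),
                     list(a = "b", b = "a", c = "d", d = "c"))
  expect_error(icar_log_density(c(1, -1, 2, -2), gd, 1), "disconnected")
})

test_that("log-density gradient matches finite differences on random graphs", {
  set.seed(41)
  for (rep in 1:5) {
    g <- random_connected_graph(6, extra = 3)
    Q <- graph_laplacian(g)
    s <- rnorm(6); s <- s - mean(s)
    s2 <- runif(1, 0.5, 3)
    grad_analytic <- -as.vector(Q %*% s) / s2
    eps <- 1e-6
    grad_fd <- vapply(1:6, function(i) {
      sp <- s; sm <- s
      sp[i] <- sp[i] + eps; sm[i] <- sm[i] - eps
      (icar_log_density(sp, g, s2) - icar_log_density(sm, g, s2)) / (2 * eps)
    }, numeric(1))
    expect_equal(grad_fd, grad_analytic, tolerance = 1e-5)
  }
})

test_that("conditional moments agree with 1-D normalisation of the joint", {
  # numerically normalise exp(log joint) over one coordinate and compare the
  # resulting mean/variance with the closed-form conditional
  set.seed(7)
  for (n in 3:6) {
    g <- random_connected_graph(n, extra = 2)
    s <- rnorm(n); s <- s - mean(s)
    s2 <- 1.3
    i <- sample.int(n, 1)
    cp <- icar_conditional_params(i, s, g, s2)
    grid <- seq(cp$mean - 7 * sqrt(cp$variance),
                cp$mean + 7 * sqrt(cp$variance), length.out = 4001)
    logf <- vapply(grid, function(t) {
      st <- s; st[i] <- t
      icar_log_density(st, g, s2)
    }, numeric(1))
    w <- exp(logf - max(logf))
    m <- sum(w * grid) / sum(w)
    v <- sum(w * (grid - m)^2) / sum(w)
    expect_equal(m, cp$mean, tolerance = 1e-6)
    expect_equal(v, cp$variance, tolerance = 1e-4)
  }
})

test_that("prior draws satisfy the constraint and the quadratic-form moment", {
  g <- grid_graph(6, 9)
  n <- n_nodes(g)
  Q <- graph_laplacian(g)
  set.seed(99)
  s2 <- 2.5
  qf <- replicate(400, {
    s <- simulate_spatial_effects(g, s2)
    expect_lt(abs(sum(s)), 1e-10)
    as.numeric(t(s) %*% Q %*% s)
  })
  # E[s' Q s] = (n - 1) * sigma2_s for the constrained intrinsic draw
  expect_equal(mean(qf), (n - 1) * s2, tolerance = 0.1)
})

test_that("lattice fast path matches the dense spectral construction", {
  g <- grid_graph(5, 9)
  Q <- graph_laplacian(g)
  eg <- eigen(Q, symmetric = TRUE)
  n <- n_nodes(g)
  marg <- diag(eg$vectors[, 1:(n - 1)] %*%
                 diag(1 / eg$values[1:(n - 1)]) %*% t(eg$vectors[, 1:(n - 1)]))
  set.seed(11)
  draws <- replicate(3000, simulate_spatial_effects(g, 1))
  emp <- apply(draws, 1, var)
  # theoretical marginal variances from the Laplacian pseudo-inverse include
  # the mean-centred correction; draws are recentred, so compare to the
  # centred covariance diagonal
  P <- diag(n) - matrix(1 / n, n, n)
  margC <- diag(P %*% eg$vectors[, 1:(n - 1)] %*%
                  diag(1 / eg$values[1:(n - 1)]) %*%
                  t(eg$vectors[, 1:(n - 1)]) %*% t(P))
  expect_equal(unname(emp), unname(margC), tolerance = 0.12)
  expect_gt(cor(emp, marg), 0.95)
})
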