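test_that("unit rescaling is the min-max map and is idempotent", {
  expect_equal(scale_unit(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.25, 0.9, 1)
  expect_equal(scale_unit(v), v)          # already spans [0, 1]
  x <- sort(runif(50))
  expect_true(all(diff(scale_unit(x)) > 0))  # order preserved
  expect_equal(scale_unit(scale_unit(x)), scale_unit(x))
  expect_error(scale_unit(rep(3, 10)), "constant")
  expect_error(scale_unit(2), "at least 2")
})

test_that("concentration score orders car-dependent counties most negative", {
  set.seed(21)
  n <- 500
  u <- rnorm(n)  # latent dispersal axis
  d <- tibble::tibble(
    car_commute = 70 + 10 * u + rnorm(n),
    public_transport_commute = 5 - 2 * u + rnorm(n),
    walk_cycle_commute = 6 - 2 * u + rnorm(n),
    post1950_housing = 60 + 8 * u + rnorm(n),
    pop_density = 300 - 100 * u + rnorm(n, sd = 10))
  sc <- concentration_score(d)
  expect_lt(cor(sc, d$car_commute), -0.9)
  hi_car <- d$car_commute >= quantile(d$car_commute, 0.9)
  lo_car <- d$car_commute <= quantile(d$car_commute, 0.1)
  expect_lt(mean(sc[hi_car]), mean(sc[lo_car]))
  expect_equal(sd(sc), 1)
  expect_lt(attr(sc, "loadings")[["car_commute"]], 0)
})

test_that("anti-correlated pair dominates the leading component", {
  set.seed(33)
  n <- 2000
  z <- rnorm(n)
  d <- tibble::tibble(
    car_commute = z,
    public_transport_commute = -z,
    walk_cycle_commute = rnorm(n),
    post1950_housing = rnorm(n),
    pop_density = rnorm(n))
  sc <- concentration_score(d)
  ld <- attr(sc, "loadings")
  # analytic leading eigenvector of the 2-block correlation matrix is
  # (1, -1, 0, 0, 0)/sqrt(2) with eigenvalue 2
  expect_equal(abs(unname(ld[1:2])), rep(1 / sqrt(2), 2), tolerance = 0.02)
  expect_lt(max(abs(ld[3:5])), 0.1)
  expect_equal(attr(sc, "eigenvalues")[1], 2, tolerance = 0.1)
})

test_that("concentration score is invariant to affine rescaling of columns", {
  set.seed(5)
  n <- 300
  u <- rnorm(n)
  d <- tibble::tibble(
    car_commute = 70 + 10 * u + rnorm(n),
    public_transport_commute = 5 - 2 * u + rnorm(n),
    walk_cycle_commute = 6 - 2 * u + rnorm(n),
    post1950_housing = 60 + 8 * u + rnorm(n),
    pop_density = 300 - 100 * u + rnorm(n, sd = 10))
  sc <- concentration_score(d)
  d2 <- dplyr::mutate(d, pop_density = 1000 * .data$pop_density + 5,
                      walk_cycle_commute = 0.01 * .data$walk_cycle_commute)
  sc2 <- concentration_score(d2)
  expect_equal(as.vector(sc2), as.vector(sc), tolerance = 1e-8)
})

test_that("degenerate leading eigen-gap is rejected with the spectrum", {
  set.seed(9)
  # exactly orthogonal in-sample axes a, b, c; two perfect +/- pairs give
  # the correlation matrix eigenvalues {2, 2, 1, 0, 0}: tied leading pair
  M <- qr.Q(qr(scale(matrix(rnorm(30), 10), scale = FALSE)))[, 1:3]
  dd <- tibble::tibble(car_commute = M[, 1],
                       public_transport_commute = -M[, 1],
                       walk_cycle_commute = M[, 2],
                       post1950_housing = -M[, 2],
                       pop_density = M[, 3])
  expect_error(concentration_score(dd), "eigenvalue")
})

test_that("food environment index hits its anchor points", {
  la <- c(2, 16, 30)   # min, midpoint, max
  fi <- c(5, 15, 25)
  fei <- food_environment_index(la, fi)
  expect_equal(fei, c(10, 5, 0))
  expect_error(food_environment_index(c(-1, 5, 7), fi), "\\[0, 100\\]")
})

test_that("quintile assignment respects published breaks and balance", {
  q <- quintile_assign(c(10, 25, 13, 16, 20),
                       breaks = c(11.8, 14.7, 18, 22.1))
  expect_equal(as.integer(q), c(1L, 5L, 2L, 3L, 4L))
  expect_equal(attr(q, "cutpoints"), c(11.8, 14.7, 18, 22.1))
  q2 <- quintile_assign(1:100)
  expect_equal(unname(table(as.integer(q2))), rep(20L, 5), ignore_attr = TRUE)
})

test_that("quintile labels are invariant to monotone transforms", {
  set.seed(3)
  x <- rlnorm(257)
  for (f in list(function(z) z^3, log, function(z) 5 * z - 2)) {
    expect_equal(as.integer(quintile_assign(f(x))),
                 as.integer(quintile_assign(x)))
  }
})

test_that("heavy ties produce an informative error", {
  expect_error(quintile_assign(rep(c(1, 2), 50)), "tie")
  expect_error(quintile_assign(c(1, 2, 3), breaks = c(1, 1, 2, 3)), "tied")
})
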