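toy_counties <- function() {
  tibble::tibble(
    pov = rep(c("low", "high"), each = 2),
    urb = rep(c("metro", "rural"), 2),
    rate = c(20, 30, 40, 50))
}

test_that("one county per cell reproduces the rates and pairwise margins", {
  ct <- crosstab_rates(toy_counties(), "rate", rows = "pov", cols = "urb")
  cell <- function(r, c) ct$mean[ct$row == r & ct$col == c]
  expect_equal(cell("low", "metro"), 20)
  expect_equal(cell("high", "rural"), 50)
  expect_equal(cell("low", "All"), 25)
  expect_equal(cell("All", "metro"), 30)
  expect_equal(cell("All", "All"), 35)
})

test_that("margins reconstruct the grand mean to near machine precision", {
  set.seed(14)
  d <- tibble::tibble(
    f1 = sample(letters[1:5], 400, replace = TRUE),
    f2 = sample(LETTERS[1:4], 400, replace = TRUE),
    y = rnorm(400, 30, 4))
  ct <- crosstab_rates(d, "y", rows = "f1", cols = "f2")
  grand <- ct$mean[ct$row == "All" & ct$col == "All"]
  expect_equal(grand, mean(d$y), tolerance = 1e-10)
  # margin = count-weighted average of its interior cells
  for (lv in letters[1:5]) {
    cells <- ct[ct$row == lv & ct$col != "All", ]
    m <- ct$mean[ct$row == lv & ct$col == "All"]
    expect_equal(sum(cells$mean * cells$n, na.rm = TRUE) / sum(cells$n), m,
                 tolerance = 1e-10)
  }
})

test_that("empty cells are missing, not zero, and one-cell data degenerates", {
  d <- tibble::tibble(f1 = rep("a", 4), f2 = rep("x", 4), y = c(1, 2, 3, 4))
  d2 <- dplyr::bind_rows(d, tibble::tibble(f1 = "b", f2 = "y", y = 10))
  ct <- crosstab_rates(d2, "y", rows = "f1", cols = "f2")
  expect_true(is.na(ct$mean[ct$row == "a" & ct$col == "y"]))
  expect_equal(ct$n[ct$row == "a" & ct$col == "y"], 0L)
  expect_equal(ct$mean[ct$row == "a" & ct$col == "x"], 2.5)
})

test_that("cell means converge to generating truth as counties grow", {
  set.seed(31)
  n <- 5000
  f1 <- sample(c("p1", "p2"), n, replace = TRUE)
  f2 <- sample(c("u1", "u2"), n, replace = TRUE)
  truth <- c(p1.u1 = 25, p1.u2 = 28, p2.u1 = 31, p2.u2 = 36)
  y <- truth[paste(f1, f2, sep = ".")] + rnorm(n, sd = 3)
  ct <- crosstab_rates(tibble::tibble(f1, f2, y = unname(y)),
                       "y", rows = "f1", cols = "f2")
  for (nm in names(truth)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    expect_equal(ct$mean[ct$row == parts[1] & ct$col == parts[2]],
                 unname(truth[nm]), tolerance = 0.01)  # ~3 se at n/4 per cell
  }
})

test_that("gradient ratio matches the published female poverty contrast", {
  # female "All" means in the lowest and highest poverty quintiles
  d <- tibble::tibble(q = c("1", "5"), rate = c(27.4, 34.5))
  expect_equal(gradient_ratio(d, "rate", "q"), 34.5 / 27.4)
  expect_equal(round(gradient_ratio(d, "rate", "q"), 2), 1.26)
  # equal means give exactly 1; monotone gradients exceed 1
  d2 <- tibble::tibble(q = rep(c("1", "2", "3"), each = 10),
                       rate = rep(c(20, 25, 30), each = 10))
  expect_gt(gradient_ratio(d2, "rate", "q"), 1)
  d3 <- tibble::tibble(q = rep(c("1", "2"), each = 5), rate = rep(20, 10))
  expect_equal(gradient_ratio(d3, "rate", "q"), 1)
  expect_error(gradient_ratio(tibble::tibble(q = c("1", "2"), rate = c(0, 1)),
                              "rate", "q"), "zero")
})

test_that("quintile profile is flat under independence, monotone under identity", {
  set.seed(8)
  n <- 4000
  d <- tibble::tibble(x = runif(n), y = rnorm(n, 30, 2))
  pr <- quintile_profile(d, "y", "x")
  expect_equal(pr$quintile, 1:5)
  expect_lt(max(abs(pr$mean - mean(d$y))), 4 * 2 / sqrt(n / 5))
  d2 <- tibble::tibble(x = runif(50), y = NA_real_)
  d2$y <- d2$x
  expect_true(all(diff(quintile_profile(d2, "y", "x")$mean) > 0))
})

test_that("profile slope recovers a generating linear effect", {
  set.seed(62)
  b <- 6
  for (rep in 1:10) {
    n <- 3000
    x <- runif(n)
    y <- 25 + b * x + rnorm(n, sd = 2)
    pr <- quintile_profile(tibble::tibble(x, y), "y", "x")
    qmid <- tapply(x, as.integer(quintile_assign(x)), mean)
    obs <- pr$mean[5] - pr$mean[1]
    exp_diff <- b * (qmid[[5]] - qmid[[1]])
    se_diff <- sqrt(2) * 2 / sqrt(n / 5)   # two cell means, sd = 2 each
    expect_lt(abs(obs - exp_diff), 3 * se_diff)
  }
})
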