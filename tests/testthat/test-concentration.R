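# Independent oracle: Gini as twice the area between the Lorenz curve
# and the diagonal, by trapezoid integration over the cumulative shares.
gini_lorenz_oracle <- function(counts) {
  x <- sort(counts)
  cum <- c(0, cumsum(x) / sum(x))
  p <- seq(0, 1, length.out = length(cum))
  area_under <- sum(diff(p) * (utils::head(cum, -1) + utils::tail(cum, -1)) / 2)
  2 * (0.5 - area_under)
}

test_that("gini hits closed forms and errors on all-zero input", {
  expect_equal(gini(c(5, 5, 5, 5)), 0)
  expect_equal(gini(c(0, 0, 0, 10)), 0.75)
  for (n in c(2, 7, 100)) {
    expect_equal(gini(c(rep(0, n - 1), 3)), (n - 1) / n)
    expect_equal(gini(rep(2, n)), 0)
  }
  expect_error(gini(c(0, 0)), "all-zero")
  expect_error(gini(numeric()), "non-empty")
  expect_error(gini(c(1, -1)), "non-negative")
})

test_that("the formula agrees with the Lorenz-area oracle on 200 random vectors", {
  set.seed(4021)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    x <- rpois(n, lambda = sample(c(1, 5, 50), 1)) +
      ifelse(runif(n) < 0.2, 0, rbinom(n, 200, 0.05))
    if (all(x == 0)) x[1] <- 1
    expect_lt(abs(gini(x) - gini_lorenz_oracle(x)), 1e-12)
  }
})

test_that("gini is scale- and permutation-invariant and respects transfers", {
  set.seed(77)
  x <- rpois(25, 8) + 1
  expect_equal(gini(x), gini(7.3 * x))
  expect_equal(gini(x), gini(sample(x)))
  # Pigou-Dalton: a rich-to-poor transfer without rank crossing lowers G
  y <- sort(x)
  y[1] <- y[1] + 0.5
  y[25] <- y[25] - 0.5
  expect_lt(gini(y), gini(x))
  # adding an entity at the mean never increases G
  expect_lte(gini(c(x, mean(x))), gini(x) + 1e-12)
})

test_that("lorenz curves are anchored, monotone, convex and consistent with gini", {
  eq <- lorenz_curve(rep(3, 5))
  expect_equal(eq$share, eq$p)  # line of equality
  conc <- lorenz_curve(c(0, 0, 0, 10))
  expect_equal(conc$share[conc$p == 0.75], 0)
  expect_equal(conc$share[conc$p == 1], 1)

  set.seed(8)
  x <- rpois(40, 5) + 1
  lc <- lorenz_curve(x)
  expect_equal(lc$p[1], 0); expect_equal(lc$share[1], 0)
  expect_equal(lc$p[nrow(lc)], 1); expect_equal(lc$share[nrow(lc)], 1)
  expect_true(all(diff(lc$share) >= 0))
  expect_true(all(diff(diff(lc$share)) >= -1e-12))  # convex
  expect_lt(abs(gini(x) - gini_lorenz_oracle(x)), 1e-12)
})

test_that("top_share matches the ceiling contract and a brute-force oracle", {
  eq100 <- setNames(rep(1, 100), sprintf("e%03d", 1:100))
  expect_equal(top_share(eq100, 0.01), 0.01)
  expect_equal(top_share(c(a = 9, b = 0, c = 0), 0.5), 1.0)
  set.seed(12)
  zipf <- setNames(round(1000 / (1:80)^1.2), sprintf("z%02d", 1:80))
  for (f in c(0.01, 0.05, 0.25, 1)) {
    k <- ceiling(f * 80)
    brute <- sum(sort(zipf, decreasing = TRUE)[1:k]) / sum(zipf)
    expect_equal(top_share(zipf, f), brute)
  }
  expect_equal(top_share(zipf, 1), 1)
})

test_that("annual Gini trends recover slopes and match closed-form OLS", {
  years <- 1996:2013
  flat <- dplyr::bind_rows(lapply(years, function(y) {
    tibble::tibble(year = y, entity = paste0("e", 1:30),
                   n = rep(c(1, 2, 8), 10))
  }))
  tr <- suppressWarnings(annual_gini_trend(flat))  # perfect fit: slope 0
  expect_equal(tr$slope, 0, tolerance = 1e-12)

  # injected drift of +0.012/yr in the annual Gini
  set.seed(90)
  drift <- dplyr::bind_rows(lapply(seq_along(years), function(i) {
    g_target <- 0.4 + 0.012 * (i - 1) + rnorm(1, 0, 0.004)
    tibble::tibble(year = years[i], entity = paste0("e", 1:50),
                   n = concentration_calibrator(50, g_target))
  }))
  tr2 <- annual_gini_trend(drift)
  se <- summary(tr2$fit)$coefficients["year", "Std. Error"]
  expect_lt(abs(tr2$slope - 0.012), 2 * se)

  # closed-form OLS oracle on the (year, gini) pairs
  py <- tr2$per_year
  slope_cf <- sum((py$year - mean(py$year)) * (py$gini - mean(py$gini))) /
    sum((py$year - mean(py$year))^2)
  expect_equal(tr2$slope, slope_cf, tolerance = 1e-12)

  # a year with all-zero counts is dropped with a warning
  withzero <- dplyr::bind_rows(
    drift, tibble::tibble(year = 2014, entity = paste0("e", 1:30), n = 0))
  expect_warning(tr3 <- annual_gini_trend(withzero), "no active entities")
  expect_equal(nrow(tr3$per_year), length(years))
})

test_that("concentration objects expose tidy, glance and autoplot surfaces", {
  cc <- concentration(c(a = 50, b = 30, c = 15, d = 5))
  expect_s3_class(tidy(cc), "tbl_df")
  g <- glance(cc)
  expect_equal(g$gini, gini(c(50, 30, 15, 5)))
  expect_equal(g$top_0.01, top_share(c(a = 50, b = 30, c = 15, d = 5), 0.01))
  expect_s3_class(autoplot(cc), "ggplot")
})
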