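test_that("winter rainfall sums November through April, labelled by spring year", {
  p <- data.frame(date = c("1993-11-15", "1993-12-01", "1994-01-20",
                           "1994-02-10", "1994-03-05", "1994-04-28"),
                  mm = c(10, 0, 25, 0, 5, 0))
  w <- winter_rain(p)
  expect_equal(w$year, 1994)
  expect_equal(w$rain_mm, 40)
  expect_true(w$complete)

  # all-zero months are a valid zero winter, not missing
  p$mm <- 0
  w0 <- winter_rain(p)
  expect_equal(w0$rain_mm, 0)
  expect_true(w0$complete)

  # a missing month flags the winter and yields NA
  p2 <- p[-3, ]  # drop the January record
  w2 <- winter_rain(p2)
  expect_false(w2$complete)
  expect_true(is.na(w2$rain_mm))

  # out-of-window months are ignored
  p3 <- rbind(p, data.frame(date = "1994-07-01", mm = 100))
  expect_equal(winter_rain(p3)$rain_mm, 0)
})

test_that("lagged correlation matches a direct covariance computation", {
  a <- data.frame(year = 1991:1995, value = c(1, 2, 3, 4, 5))
  b <- data.frame(year = 1991:1995, value = c(2, 1, 4, 3, 6))
  lc <- lagged_correlation(a, b, lag = 0)
  # brute-force formula oracle
  va <- a$value; vb <- b$value
  r_direct <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(lc$r, r_direct, tolerance = 1e-12)
  expect_equal(lc$n, 5)
  # Fisher z interval with the n - 3 denominator
  z <- atanh(r_direct)
  expect_equal(lc$ci, tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(5 - 3)),
               tolerance = 1e-12)
  expect_true(lc$ci[1] <= lc$r && lc$r <= lc$ci[2])
})

test_that("perfect correlation collapses the interval to the boundary", {
  a <- data.frame(year = 1991:1995, value = c(1, 2, 3, 4, 5))
  up <- lagged_correlation(a, transform(a, value = 2 * value + 3), lag = 0)
  expect_equal(up$r, 1)
  expect_equal(up$ci, c(1, 1))
  expect_true(up$boundary)
  down <- lagged_correlation(a, transform(a, value = -value), lag = 0)
  expect_equal(down$r, -1)
  expect_equal(down$ci, c(-1, -1))
})

test_that("lag symmetry and affine invariance hold", {
  set.seed(81)
  a <- data.frame(year = 1991:1999, value = rnorm(9))
  b <- data.frame(year = 1991:1999, value = rnorm(9))
  for (k in -2:2) {
    ab <- lagged_correlation(a, b, lag = k)
    ba <- lagged_correlation(b, a, lag = -k)
    expect_equal(ab$r, ba$r, tolerance = 1e-12)
    expect_equal(ab$n, ba$n)
  }
  scaled <- transform(b, value = 5 * value + 100)
  expect_equal(lagged_correlation(a, scaled, lag = 1)$r,
               lagged_correlation(a, b, lag = 1)$r, tolerance = 1e-12)
})

test_that("degenerate correlation inputs are refused", {
  a <- data.frame(year = 1991:1999, value = rnorm(9))
  short <- data.frame(year = 1991:1992, value = c(1, 2))
  expect_error(lagged_correlation(short, short, lag = 0), "3 overlapping")
  expect_error(lagged_correlation(a, a, lag = 8), "3 overlapping")
  flat <- data.frame(year = 1991:1999, value = 7)
  expect_error(lagged_correlation(a, flat, lag = 0), "zero variance")
})

test_that("the stylised synthetic series reproduces the chain's correlation signs", {
  s <- simulate_population_series(sim_config(seed = 12, years = 1991:1999))
  cors <- trophic_correlations(s)
  expect_gt(cors$reindeer_fox_lag2$r, 0)   # carrion feeds fox reproduction
  expect_equal(cors$reindeer_fox_lag2$lag, 2L)
  expect_equal(cors$reindeer_fox_lag2$n, 7)
})
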