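test_that("condition index is the OLS residual of mass on tarsus", {
  # hand-computed three-point regression: slope 25, intercept 100
  d <- data.frame(tarsus_mm = c(70, 80, 90), mass_g = c(1900, 2000, 2400))
  out <- compute_condition_index(d)
  fit <- attr(out, "condition_fit")
  expect_equal(unname(fit["tarsus_mm"]), 25)
  expect_equal(unname(fit["(Intercept)"]), 100)
  expect_equal(out$condition, c(50, -100, 50))
  expect_lt(abs(sum(out$condition)), 1e-8 * nrow(out))
})

test_that("a perfectly linear mass-tarsus relation gives zero condition", {
  d <- data.frame(tarsus_mm = c(60, 70, 75, 90), mass_g = 50 + 20 * c(60, 70, 75, 90))
  expect_equal(compute_condition_index(d)$condition, rep(0, 4), tolerance = 1e-10)
})

test_that("rows with missing tarsus get NA condition and are excluded from the fit", {
  d <- data.frame(tarsus_mm = c(70, 80, 90, NA), mass_g = c(1900, 2000, 2400, 2100))
  out <- compute_condition_index(d)
  expect_true(is.na(out$condition[4]))
  expect_equal(out$condition[1:3], c(50, -100, 50))
})

test_that("degenerate condition regressions are rejected", {
  expect_error(compute_condition_index(
    data.frame(tarsus_mm = c(70, 80), mass_g = c(1900, 2000))), "at least 3")
  expect_error(compute_condition_index(
    data.frame(tarsus_mm = rep(80, 5), mass_g = rnorm(5, 2000, 10))), "constant")
})

test_that("condition values are invariant to a constant mass shift", {
  set.seed(4)
  d <- data.frame(tarsus_mm = rnorm(50, 75, 3), mass_g = rnorm(50, 2000, 100))
  base <- compute_condition_index(d)$condition
  d$mass_g <- d$mass_g + 250
  expect_equal(compute_condition_index(d)$condition, base, tolerance = 1e-9)
})

test_that("trait normalisation centres, scales, and is idempotent", {
  expect_equal(normalize_trait(c(2, 4, 6)), c(-1, 0, 1))
  set.seed(2)
  v <- rnorm(200, 10, 4)
  z <- normalize_trait(v)
  expect_lt(abs(mean(z)), 1e-8)
  expect_lt(abs(sd(z) - 1), 1e-8)
  expect_equal(normalize_trait(z), z, tolerance = 1e-12)
  expect_equal(cor(v, z), 1, tolerance = 1e-12)
  expect_error(normalize_trait(rep(3, 10)), "constant")
})

test_that("trend test recovers a perfect trend and a null trend", {
  d <- data.frame(year = rep(1991:1999, each = 5))
  d$value <- d$year  # trait equals year exactly
  tr <- annual_trend_test(d)
  expect_equal(tr$slope, 1, tolerance = 1e-10)
  expect_lt(tr$p_value, 1e-10)
  expect_identical(tr$unit, "annual_means")

  d$value <- 7  # constant trait
  tr0 <- annual_trend_test(d)
  expect_equal(tr0$slope, 0, tolerance = 1e-12)
  expect_equal(tr0$p_value, 1)

  expect_error(annual_trend_test(data.frame(year = c(1, 2), value = c(1, 2))),
               "3 distinct years")
  tro <- annual_trend_test(d, unit = "observations")
  expect_identical(tro$unit, "observations")
})

test_that("fitness combines survival and recruitment as W = I + B/2", {
  f <- compute_fitness(c(1, 0, 1), c(2, 0, 3))
  expect_equal(f$W, c(2, 0, 2.5))
  expect_equal(f$twoW, c(4L, 0L, 5L))
  expect_error(compute_fitness(2, 0), "0 or 1")
  expect_error(compute_fitness(1, -1), "non-negative")
  expect_error(compute_fitness(1, 1.5), "non-negative integer")
})
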