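test_that("AICc arithmetic and support rule match the definition", {
  tab <- model_selection_aicc(list(m = list(logLik = -100, k = 3)), n = 50)
  expect_equal(tab$AICc, 206 + 24 / 46, tolerance = 1e-4)

  # two models within 2 units: both supported, sparser preferred
  tab2 <- model_selection_aicc(list(bigger = list(logLik = -99.25, k = 4),
                                    smaller = list(logLik = -100, k = 3)),
                               n = 50)
  expect_true(all(tab2$supported))
  expect_lt(max(tab2$delta_AICc), 2)
  expect_identical(attr(tab2, "preferred"), "smaller")

  # duplicated model: delta 0 for both, tie broken by k then label order
  tab3 <- model_selection_aicc(list(b = list(logLik = -100, k = 3),
                                    a = list(logLik = -100, k = 3)), n = 50)
  expect_equal(tab3$delta_AICc, c(0, 0))
  expect_identical(attr(tab3, "preferred"), "a")

  expect_error(model_selection_aicc(list(m = list(logLik = -10, k = 10)), n = 11),
               "AICc undefined")
})

test_that("AICc converges to AIC for large samples", {
  k <- 4
  n <- 2000 * k + 1
  tab <- model_selection_aicc(list(m = list(logLik = -500, k = k)), n = n)
  aic <- 1000 + 2 * k
  expect_lt(tab$AICc - aic, 1e-2)
  expect_gt(tab$AICc, aic)  # the correction is strictly positive
})

make_repro_data <- function(seed, n_id = 300, years = 1991:1999,
                            slope = 0.4, year_sd = 0.3) {
  set.seed(seed)
  id <- rep(seq_len(n_id), each = length(years))
  year <- rep(years, n_id)
  x <- rep(rnorm(n_id), each = length(years))
  N <- rep(c(566, 1071), length.out = length(years))[match(year, years)]
  Ns <- (N - mean(N)) / sd(N)
  yr_eff <- rnorm(length(years), 0, year_sd)[match(year, years)]
  id_eff <- rep(rnorm(n_id, 0, 0.3), each = length(years))
  eta <- -0.2 + slope * x + 0.25 * Ns + yr_eff + id_eff
  data.frame(id = id, year = year, x = x, N = N, age = 3L,
             success = rbinom(length(eta), 1, plogis(eta)),
             brood = .rztpois_test(length(eta), exp(0.5 + 0.2 * x)))
}

.rztpois_test <- function(n, lambda) {
  u <- runif(n, ppois(0, lambda), 1)
  qpois(u, lambda)
}

test_that("binomial reproductive-rate GLMM recovers the condition slope", {
  d <- make_repro_data(seed = 71)
  fit <- fit_reproduction(d, "reproductive_rate", terms = c("x", "N"))
  expect_s3_class(fit, "repro_fit")
  row <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(row$estimate - 0.4), 2 * row$se)
  expect_equal(fit$n, nrow(d))
})

test_that("zero year variance collapses to the fixed-effect fit, flagged", {
  d <- make_repro_data(seed = 72, n_id = 400, year_sd = 0)
  # also remove the id effect signal by regenerating success without it
  set.seed(720)
  Ns <- (d$N - mean(d$N)) / sd(d$N)
  d$success <- rbinom(nrow(d), 1, plogis(-0.2 + 0.4 * d$x + 0.25 * Ns))
  fit <- suppressMessages(fit_reproduction(d, "reproductive_rate",
                                           terms = c("x", "N")))
  expect_true(fit$boundary)
  glm_fit <- glm(success ~ x + Ns, data = transform(d, Ns = Ns),
                 family = binomial())
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(glm_fit)), tolerance = 1e-2)
})

test_that("brood-size model excludes zero broods and uses the truncated family", {
  d <- make_repro_data(seed = 73, n_id = 150)
  d$brood[d$success == 0] <- 0L
  fit <- fit_reproduction(d, "fledged_brood_size", terms = "x")
  expect_identical(fit$engine, "glmmTMB")
  expect_equal(unname(fit$dropped["zero_brood"]), sum(d$brood == 0))
  expect_equal(fit$n, sum(d$brood >= 1))
  # untruncated alternative runs through glmer
  fit2 <- suppressWarnings(fit_reproduction(d, "fledged_brood_size",
                                            terms = "x", brood_model = "poisson"))
  expect_identical(fit2$engine, "glmer")
})

test_that("degenerate reproduction data are refused", {
  d <- make_repro_data(seed = 74, n_id = 40)
  d$success <- 1L
  expect_error(fit_reproduction(d, "reproductive_rate"), "degenerate")
  d$success <- 0L
  expect_error(fit_reproduction(d, "reproductive_rate"), "degenerate")
  d$brood <- 0L
  expect_error(fit_reproduction(d, "fledged_brood_size"), "no successful")
})

test_that("immature females are dropped from the reproductive-rate model", {
  d <- make_repro_data(seed = 75, n_id = 120)
  d$age[1:100] <- 1L
  fit <- fit_reproduction(d, "reproductive_rate", terms = "x")
  expect_equal(unname(fit$dropped["immature"]), 100)
  expect_equal(fit$n, nrow(d) - 100)
})

test_that("rate predictions respect link bounds and interaction geometry", {
  d <- make_repro_data(seed = 76)
  fit <- fit_reproduction(d, "reproductive_rate", terms = c("x", "N"))
  grid <- seq(-3, 3, length.out = 25)
  lo <- predict_rate(fit, grid, 566)
  hi <- predict_rate(fit, grid, 1071)
  expect_true(all(lo$fit > 0 & lo$fit < 1))
  expect_true(all(lo$lwr <= lo$fit & lo$fit <= lo$upr))
  # no interaction term: the two curves are parallel on the link scale
  gap <- qlogis(hi$fit) - qlogis(lo$fit)
  expect_lt(diff(range(gap)), 1e-10)
  expect_error(predict_rate(fit, numeric(0), 800), "empty")
  expect_warning(predict_rate(fit, grid, 5000), "outside the fitted range")

  # a positive x:N interaction steepens the high-density curve on link scale
  set.seed(77)
  Ns <- (d$N - mean(d$N)) / sd(d$N)
  d$success <- rbinom(nrow(d), 1, plogis(0.1 + 0.3 * d$x + 0.4 * d$x * Ns))
  fit_int <- suppressMessages(fit_reproduction(d, "reproductive_rate",
                                               terms = c("x", "N", "x:N")))
  lo2 <- predict_rate(fit_int, grid, 566)
  hi2 <- predict_rate(fit_int, grid, 1071)
  slope_lo <- diff(qlogis(lo2$fit)) / diff(grid)
  slope_hi <- diff(qlogis(hi2$fit)) / diff(grid)
  expect_gt(mean(slope_hi), mean(slope_lo))
})
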