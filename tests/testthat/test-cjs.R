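test_that("two-occasion likelihood contributions match hand enumeration", {
  h11 <- list(det = matrix(c(1L, 1L), 1), first = 1L)
  h10 <- list(det = matrix(c(1L, 0L), 1), first = 1L)
  expect_equal(as.numeric(cjs_log_likelihood(h11, phi = 0.8, p = 0.6)),
               log(0.48), tolerance = 1e-12)          # survived and seen
  expect_equal(as.numeric(cjs_log_likelihood(h10, phi = 0.8, p = 0.6)),
               log(0.52), tolerance = 1e-12)          # died, or survived unseen
})

test_that("history probabilities from one release sum to one (enumeration)", {
  set.seed(41)
  for (T in 2:5) {
    phi <- runif(T - 1, 0.3, 0.95)
    p <- runif(T, 0.2, 0.95)
    patterns <- expand.grid(rep(list(0:1), T - 1))
    total <- 0
    for (r in seq_len(nrow(patterns))) {
      det <- matrix(c(1L, as.integer(patterns[r, ])), 1)
      h <- list(det = det, first = 1L)
      total <- total + exp(as.numeric(
        cjs_log_likelihood(h, phi = matrix(phi, 1), p = p)))
    }
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("perfect detection reduces the likelihood to Bernoulli survival", {
  h <- list(det = matrix(c(1L, 1L, 1L, 0L, 0L,
                           1L, 1L, 0L, 0L, 0L), 2, byrow = TRUE),
            first = c(1L, 1L))
  phi <- matrix(c(0.9, 0.8, 0.7, 0.6), 2, 4, byrow = TRUE)
  ll <- as.numeric(cjs_log_likelihood(h, phi = phi, p = 1))
  # ind 1: survive, survive, die; ind 2: survive(seen), die
  expect_equal(ll, log(0.9 * 0.8 * (1 - 0.7)) + log(0.9 * (1 - 0.8)),
               tolerance = 1e-12)
})

test_that("with detection fixed at 1 the MLE is the observed survival fraction", {
  hist <- simulate_cjs_histories(n = 400, T = 4,
                                 phi_fun = function(x, t) c(0.9, 0.7, 0.5)[t],
                                 p = 1, seed = 43)
  fit <- fit_cjs(hist, phi_terms = "year", age_effect = FALSE, p_fixed = 1)
  expect_true(fit$converged)
  est <- fit$coefficients$estimate
  phi_hat <- plogis(c(est[1], est[1] + est[2], est[1] + est[3]))
  det <- hist$det
  emp <- vapply(1:3, function(t) {
    at_risk <- det[, t] == 1 & hist$first <= t
    sum(det[at_risk, t + 1]) / sum(at_risk)
  }, numeric(1))
  expect_equal(phi_hat, emp, tolerance = 1e-4)
})

test_that("a condition slope on survival is recovered within two standard errors", {
  hist <- simulate_cjs_histories(n = 1200, T = 6,
                                 phi_fun = function(x, t) plogis(0.6 + 0.5 * x),
                                 p = 0.7, seed = 44)
  fit <- fit_cjs(hist, phi_terms = "x", age_effect = FALSE, p_model = "constant")
  expect_true(fit$converged)
  row <- fit$coefficients[fit$coefficients$term == "phi_x", ]
  expect_lt(abs(row$estimate - 0.5), 2 * row$se)
})

test_that("two occasions with free detection report only the confounded product", {
  hist <- simulate_cjs_histories(n = 300, T = 2,
                                 phi_fun = function(x, t) 0.8, p = 0.6, seed = 45)
  fit <- fit_cjs(hist, phi_terms = character(), age_effect = FALSE)
  expect_true(fit$confounded)
  expect_match(fit$message, "product")
  # the product MLE is the raw re-encounter fraction, near 0.48
  expect_lt(abs(fit$composite_phi_p - 0.48), 3 * fit$se_composite + 0.02)
})

test_that("invalid inputs are refused", {
  h <- list(det = matrix(c(1L, 1L), 1), first = 1L)
  expect_error(cjs_log_likelihood(h, phi = 1.2, p = 0.5), "probabilities")
  expect_error(cjs_log_likelihood(list(det = matrix(1L, 1, 1), first = 1L),
                                  phi = 0.5, p = 0.5), "two occasions")
  expect_error(make_histories(data.frame(id = "a", year = 2000, detected = 0)),
               "no release")
  hist <- simulate_cjs_histories(n = 50, T = 3,
                                 phi_fun = function(x, t) 0.8, p = 0.9, seed = 46)
  expect_error(fit_cjs(hist, phi_terms = "x:N"), "requires both main effects")
  expect_error(fit_cjs(hist, phi_terms = "N"), "no population series")
})
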