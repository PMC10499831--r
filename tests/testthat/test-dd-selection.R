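test_that("the sampler recovers generating parameters with clean diagnostics", {
  coh <- simulate_cohort(recovery_config(seed = 101, n_per_year = 100L))
  fit <- fit_dd_selection(coh$fitness, mcmc = quick_mcmc(seed = 101))
  expect_s3_class(fit, "dd_posterior")
  expect_true(fit$converged)
  expect_true(all(fit$summary$rhat <= 1.01))
  expect_true(all(fit$summary$ess >= 400))
  expect_equal(nrow(fit$draws), 4 * (3000 - 1500) / 2)

  truth <- unclass(coh$truth)
  covered <- vapply(c("beta1p", "beta2", "beta3", "alpha1", "alpha2", "sigma_e"),
                    function(pn) {
                      ci <- credible_interval(fit, pn)
                      truth[[pn]] >= ci[1] && truth[[pn]] <= ci[2]
                    }, logical(1))
  expect_gte(sum(covered), 4)  # at least 4 of 6 truths inside their CrI
})

test_that("input validation: counts, year coverage and identifiability", {
  coh <- small_cohort(seed = 3)
  f <- coh$fitness
  f$twoW[1] <- 1.5
  expect_error(fit_dd_selection(f, mcmc = quick_mcmc()), "non-negative integers")
  one_year <- coh$fitness[coh$fitness$year == 1991, ]
  expect_error(fit_dd_selection(one_year, mcmc = quick_mcmc()),
               "at least two years")
  f2 <- coh$fitness
  f2$N <- NULL
  expect_error(fit_dd_selection(f2, series = coh$series[-1, ],
                                mcmc = quick_mcmc()), "does not cover")
})

test_that("posterior quantiles agree with an independent MCMC engine (JAGS)", {
  # tiny fixture so the reference sampler stays fast
  coh <- simulate_cohort(recovery_config(seed = 55, n_per_year = 40L))
  fit <- fit_dd_selection(coh$fitness, mcmc = quick_mcmc(seed = 55))

  library(rjags)
  model_str <- "
  model {
    for (i in 1:n) {
      twoW[i] ~ dpois(lambda[i])
      log(lambda[i]) <- beta1p + beta2*x[i] + beta3*x[i]*x[i] -
                        N[i]*exp(alpha1 + alpha2*x[i]) + sigma_e*z[yr[i]]
    }
    for (j in 1:J) { z[j] ~ dnorm(0, 1) }
    beta1p ~ dnorm(0, 1.0E-4)
    beta2  ~ dnorm(0, 1.0E-4)
    beta3  ~ dnorm(0, 1.0E-4)
    alpha1 ~ dnorm(-1, 0.25)
    alpha2 ~ dnorm(-1, 0.25)
    sigma_e ~ dunif(0, 10)
  }"
  f <- coh$fitness
  yrs <- sort(unique(f$year))
  dat <- list(twoW = f$twoW, x = f$x, N = f$N,
              yr = match(f$year, yrs), n = nrow(f), J = length(yrs))
  inits <- lapply(1:2, function(k)
    list(beta1p = 1, beta2 = 0, beta3 = 0, alpha1 = -log(mean(f$N)) - 1,
         alpha2 = 0, sigma_e = 0.2,
         .RNG.name = "base::Mersenne-Twister", .RNG.seed = 300 + k))
  jm <- jags.model(textConnection(model_str), data = dat, inits = inits,
                   n.chains = 2, n.adapt = 500, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  samp <- coda.samples(jm, c("beta1p", "beta2", "beta3", "alpha1", "alpha2",
                             "sigma_e"), n.iter = 4000, progress.bar = "none")
  jags_med <- summary(samp)$quantiles[, "50%"]

  for (pn in c("beta1p", "beta2", "beta3", "alpha2")) {
    ours <- fit$summary$median[fit$summary$parameter == pn]
    ci_w <- diff(credible_interval(fit, pn))
    expect_lt(abs(ours - jags_med[pn]), 0.35 * ci_w)
  }
  # alpha1 has a wider, skewed posterior on this small fixture
  expect_lt(abs(fit$summary$median[fit$summary$parameter == "alpha1"] -
                jags_med["alpha1"]),
            0.5 * diff(credible_interval(fit, "alpha1")))
})

test_that("posterior optima propagate draws and shift upward with density", {
  coh <- simulate_cohort(recovery_config(seed = 77, n_per_year = 100L))
  fit <- fit_dd_selection(coh$fitness, mcmc = quick_mcmc(seed = 77))
  opt <- posterior_optima(fit, N = c(566, 800, 1071), n_draws = 100)
  expect_equal(opt$N, c(566, 800, 1071))
  expect_true(all(diff(opt$xstar) > 0))      # truth has alpha2 < 0, beta2 > 0
  expect_true(all(opt$q2.5 <= opt$xstar & opt$xstar <= opt$q97.5))
})
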