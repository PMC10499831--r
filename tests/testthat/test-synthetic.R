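test_that("two-level population series hits the configured period means", {
  cfg <- sim_config(seed = 3, years = 1991:1999, pop_levels = c(520, 620),
                    pop_boundary_year = 1996)
  s <- simulate_population_series(cfg)
  expect_equal(s$year, 1991:1999)
  expect_equal(mean(s$goose_n[s$year <= 1995]), 520)
  expect_equal(mean(s$goose_n[s$year >= 1996]), 620)

  const <- simulate_population_series(sim_config(seed = 3, pop_mode = "constant",
                                                 pop_constant = 800))
  expect_true(all(const$goose_n == 800))
})

test_that("boundary year outside the range is a configuration error", {
  expect_error(sim_config(years = 1991:1999, pop_boundary_year = 1991),
               "boundary year")
  expect_error(sim_config(years = 1991:1999, pop_boundary_year = 2005),
               "boundary year")
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(sim_config(seed = 42, years = 1991:1994,
                                  pop_boundary_year = 1993,
                                  n_females_per_year = 40))
  b <- simulate_cohort(sim_config(seed = 42, years = 1991:1994,
                                  pop_boundary_year = 1993,
                                  n_females_per_year = 40))
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$fitness, b$fitness)
  expect_identical(a$encounters, b$encounters)
  expect_identical(a$series, b$series)
})

test_that("phenotypes are draws from the configured normal distribution", {
  cfg <- sim_config(seed = 9, years = 1991, pop_mode = "constant",
                    pop_constant = 800, n_females_per_year = 10000)
  ind <- simulate_individuals(cfg, simulate_population_series(cfg))$individuals
  # sampling sd of the sd is about 1/sqrt(2(n-1))
  se_sd <- 1 / sqrt(2 * (nrow(ind) - 1))
  expect_lt(abs(sd(ind$x) - 1), 3 * se_sd)
  expect_lt(abs(mean(ind$x) - 0), 3 / sqrt(nrow(ind)))
})

test_that("zero females yields empty tables without error", {
  cfg <- sim_config(seed = 1, years = 1991:1993, pop_boundary_year = 1992,
                    n_females_per_year = 0)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$individuals), 0)
  expect_equal(nrow(coh$fitness), 0)
  expect_equal(nrow(coh$encounters), 0)
})

test_that("perfect detection reproduces the true alive record", {
  coh <- small_cohort(seed = 5, detection_prob = 1)
  det1 <- coh$encounters[coh$encounters$detected == 1, c("id", "year")]
  alive <- coh$individuals[, c("id", "year")]
  expect_equal(nrow(coh$encounters), nrow(alive))  # rows exist only while alive
  expect_identical(det1[order(det1$id, det1$year), ],
                   alive[order(alive$id, alive$year), ],
                   ignore_attr = TRUE)
})

test_that("doubled fitness is Poisson with the model mean at a fixed predictor", {
  # beta2 = beta3 = alpha2 = 0 and sigma_e = 0 make the log mean the same for
  # every female: eta = beta1p - N exp(alpha1)
  cfg <- sim_config(seed = 31, years = 1991, pop_mode = "constant",
                    pop_constant = 800, n_females_per_year = 100000,
                    true_params = dd_params(1, 0, 0, -7, 0, 0))
  coh <- simulate_cohort(cfg)
  eta <- 1 - 800 * exp(-7)
  expect_lt(abs(mean(coh$fitness$twoW) - exp(eta)) / exp(eta), 0.01)
  ratio <- var(coh$fitness$twoW) / mean(coh$fitness$twoW)
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("fitness records satisfy the definitional identities in both modes", {
  for (mode in c("poisson_2w", "component")) {
    coh <- small_cohort(seed = 11, fitness_mode = mode)
    f <- coh$fitness
    expect_true(all(f$twoW >= 0))
    expect_true(all(f$twoW == round(f$twoW)))
    expect_equal(f$twoW, 2L * f$I + f$B)
    expect_equal(f$W, f$I + f$B / 2)
    expect_true(all((f$twoW - f$B) %% 2 == 0))  # parity: 2I is even
    expect_true(all(f$I %in% 0:1))
    # every fitness record has a matching individual-year
    expect_true(all(paste(f$id, f$year) %in%
                    paste(coh$individuals$id, coh$individuals$year)))
  }
})

test_that("component mode with zero survival probability kills every female", {
  coh <- small_cohort(seed = 2, fitness_mode = "component",
                      component = list(surv_intercept = -50, surv_fledgling = 0,
                                       surv_x = 0, surv_N = 0))
  expect_true(all(coh$fitness$I == 0))
})

test_that("a written cohort reads back equal (CSV round trip)", {
  coh <- small_cohort(seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$individuals, coh$individuals, ignore_attr = TRUE)
  expect_equal(back$fitness, coh$fitness, ignore_attr = TRUE)
  expect_equal(back$encounters, coh$encounters, ignore_attr = TRUE)
  expect_equal(back$series, coh$series, ignore_attr = TRUE)
  expect_equal(unclass(back$truth), unclass(coh$truth), tolerance = 1e-12)
})
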