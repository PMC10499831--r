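# Shared fixtures: reduced sampler schedules and small synthetic cohorts so
# the suite stays fast while exercising the full code paths.

quick_mcmc <- function(seed = 1L, n_chains = 4L, n_iter = 3000L,
                       burn_in = 1500L, thin = 2L, ...) {
  mcmc_config(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
              thin = thin, seed = seed, ...)
}

# the recovery study conditions: two-level N mapped onto the observed
# min/max population sizes (566 in the low period, 1071 in the high period)
recovery_config <- function(seed, n_per_year = 250L,
                            truth = dd_params(1.0, 0.2, -0.05, -7, -0.3, 0.1)) {
  sim_config(seed = seed, years = 1991:1999,
             n_females_per_year = n_per_year,
             pop_mode = "custom",
             pop_custom = c(rep(566, 5), rep(1071, 4)),
             true_params = truth, fitness_mode = "poisson_2w")
}

small_cohort <- function(seed = 1L, years = 1991:1995, n = 60L, ...) {
  simulate_cohort(sim_config(seed = seed, years = years,
                             n_females_per_year = n,
                             pop_boundary_year = 1994L, ...))
}

# direct simulation of encounter histories under known CJS parameters
simulate_cjs_histories <- function(n, T, phi_fun, p, seed) {
  set.seed(seed)
  x <- rnorm(n)
  alive <- matrix(FALSE, n, T)
  det <- matrix(0L, n, T)
  first <- sample(rep(1:max(1, T - 2), length.out = n))
  for (i in seq_len(n)) {
    alive[i, first[i]] <- TRUE
    det[i, first[i]] <- 1L
    for (t in first[i]:(T - 1)) {
      if (!alive[i, t]) break
      alive[i, t + 1] <- runif(1) < phi_fun(x[i], t)
      if (alive[i, t + 1]) det[i, t + 1] <- rbinom(1, 1, p)
    }
  }
  keep <- rowSums(det) > 0
  structure(list(det = det[keep, , drop = FALSE],
                 first = first[keep], years = 2000 + seq_len(T),
                 id = as.character(seq_len(sum(keep))), x = x[keep]),
            class = "cjs_histories")
}
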