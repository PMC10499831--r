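# Shared driver for the Poisson log-link selection models (with or without
# the density term), running the compiled HMC sampler chain by chain.

.validate_twoW <- function(twoW) {
  if (any(!is.finite(twoW)) || any(twoW < 0) ||
      any(abs(twoW - round(twoW)) > 1e-8))
    stop("doubled fitness 2W must be non-negative integers", call. = FALSE)
  as.integer(round(twoW))
}

# Feasibility-aware jittered starting values: alpha1 must start near
# -ln(mean N) or the density term drives lambda to numerical zero.
.selection_inits <- function(chain, twoW, x, N, J, density) {
  mu0 <- log(mean(twoW) + 0.1)
  if (density) {
    a1 <- -log(mean(N)) - 1 + rnorm(1, 0, 0.3)
    a2 <- rnorm(1, 0, 0.1)
    b1 <- mu0 + mean(N) * exp(a1) + rnorm(1, 0, 0.2)
    c(b1, rnorm(2, 0, 0.1), a1, a2, log(runif(1, 0.05, 0.5)), rnorm(J, 0, 0.1))
  } else {
    c(mu0 + rnorm(1, 0, 0.2), rnorm(2, 0, 0.1),
      log(runif(1, 0.05, 0.5)), rnorm(J, 0, 0.1))
  }
}

.fit_selection_mcmc <- function(twoW, x, N, year, density, mcmc) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  twoW <- .validate_twoW(twoW)
  if (length(x) != length(twoW) || length(year) != length(twoW))
    stop("twoW, x and year must have equal length", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite trait values", call. = FALSE)
  years <- sort(unique(year))
  J <- length(years)
  if (J < 2L)
    stop("at least two years are required: the year effect is not identifiable from a single year",
         call. = FALSE)
  yr0 <- match(year, years) - 1L
  if (density) {
    if (length(N) == J) N <- N[yr0 + 1L]
    if (length(N) != length(twoW)) stop("N must match records or years", call. = FALSE)
    if (any(!is.finite(N)) || any(N < 0)) stop("population sizes must be non-negative", call. = FALSE)
  } else {
    N <- rep(0, length(twoW))
  }

  fixed <- if (density) c("beta1p", "beta2", "beta3", "alpha1", "alpha2")
           else c("b1p", "b2", "b3")
  pnames <- c(fixed, "log_sigma", paste0("eps_raw[", years, "]"))

  set.seed(mcmc$seed)
  chains <- vector("list", mcmc$n_chains)
  divergences <- 0L
  accept <- numeric(mcmc$n_chains)
  for (m in seq_len(mcmc$n_chains)) {
    init <- .selection_inits(m, twoW, x, N, J, density)
    res <- .hmc_chain(twoW, x, N, yr0, J, density, init,
                      mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                      mcmc$L_max, mcmc$sigma_max, mcmc$target_accept,
                      mcmc$alpha_prior_mean, mcmc$alpha_prior_sd)
    d <- res$draws
    colnames(d) <- pnames
    chains[[m]] <- d
    divergences <- divergences + res$divergences
    accept[m] <- res$accept_rate
  }

  # report sigma_e on the natural scale alongside the fixed effects
  report <- c(fixed, "sigma_e")
  rep_chains <- lapply(chains, function(d) {
    out <- cbind(d[, fixed, drop = FALSE], sigma_e = exp(d[, "log_sigma"]))
    out
  })
  conv <- check_convergence(rep_chains,
                            rhat_threshold = mcmc$rhat_threshold,
                            ess_threshold = mcmc$ess_threshold,
                            divergences = divergences)
  draws <- do.call(rbind, rep_chains)
  qs <- t(apply(draws, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE))
  summary <- data.frame(parameter = report,
                        mean = colMeans(draws),
                        median = qs[, 2], q2.5 = qs[, 1], q97.5 = qs[, 3],
                        rhat = conv$rhat, ess = conv$ess,
                        row.names = NULL, stringsAsFactors = FALSE)

  structure(list(summary = summary, draws = draws, chains = rep_chains,
                 raw_chains = chains, convergence = conv,
                 converged = isTRUE(attr(conv, "pass")),
                 divergences = divergences, accept_rate = accept,
                 years = years, n = length(twoW), mcmc = mcmc,
                 density = density),
            class = "dd_posterior")
}

#' @export
print.dd_posterior <- function(x, ...) {
  cat(sprintf("%s selection model fit: %d records, %d years, %d draws\n",
              if (x$density) "Density-dependent" else "Period (quadratic)",
              x$n, length(x$years), nrow(x$draws)))
  if (!x$converged)
    cat("WARNING: convergence thresholds not met; estimates flagged unreliable\n")
  cat(sprintf("Post-warmup divergences: %d\n", x$divergences))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Credible interval for a fitted selection-model parameter
#'
#' @param fit A `dd_posterior` object.
#' @param parameter Parameter name as listed in `fit$summary$parameter`.
#' @param level Credible level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "dd_posterior"))
  if (!parameter %in% colnames(fit$draws))
    stop("unknown parameter: ", parameter, call. = FALSE)
  a <- (1 - level) / 2
  unname(quantile(fit$draws[, parameter], probs = c(a, 1 - a)))
}
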