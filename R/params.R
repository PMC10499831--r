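#' Density-dependent selection parameters
#'
#' Container for the parameters of the Malthusian fitness surface: the
#' quadratic growth-rate approximation \eqn{r_0(x) = \beta_1 + \beta_2 x +
#' \beta_3 x^2} and the phenotype-dependent density-dependence strength
#' \eqn{\gamma(x) = e^{\alpha_1 + \alpha_2 x}}. The intercept is stored on the
#' doubled-fitness scale, \eqn{\beta_1' = \beta_1 + \ln 2}, because the count
#' model is fitted to \eqn{2W}.
#'
#' @param beta1p Intercept \eqn{\beta_1'}: log expected doubled fitness at
#'   \eqn{x = 0}, \eqn{N = 0}.
#' @param beta2 Directional-selection coefficient \eqn{\beta_2}.
#' @param beta3 Stabilising-selection coefficient \eqn{\beta_3} (negative for
#'   an interior optimum).
#' @param alpha1 Log baseline strength of density dependence \eqn{\alpha_1}.
#' @param alpha2 Density-dependent selection coefficient \eqn{\alpha_2}.
#' @param sigma_e Environmental (year-effect) standard deviation
#'   \eqn{\sigma_e \ge 0}.
#' @return An object of class `dd_params` (a named list).
#' @examples
#' dd_params(beta1p = 1, beta2 = 0.2, beta3 = -0.05, alpha1 = -7,
#'           alpha2 = -0.3, sigma_e = 0.1)
#' @export
dd_params <- function(beta1p, beta2, beta3, alpha1, alpha2, sigma_e) {
  for (nm in c("beta1p", "beta2", "beta3", "alpha1", "alpha2", "sigma_e")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (sigma_e < 0) stop("'sigma_e' must be non-negative", call. = FALSE)
  structure(list(beta1p = beta1p, beta2 = beta2, beta3 = beta3,
                 alpha1 = alpha1, alpha2 = alpha2, sigma_e = sigma_e),
            class = "dd_params")
}

#' @export
print.dd_params <- function(x, ...) {
  cat("Density-dependent selection parameters (2W scale)\n")
  cat(sprintf("  beta1' = %.4g  (beta1 = beta1' - ln 2 = %.4g)\n",
              x$beta1p, x$beta1p - log(2)))
  cat(sprintf("  beta2  = %.4g   beta3 = %.4g\n", x$beta2, x$beta3))
  cat(sprintf("  alpha1 = %.4g   alpha2 = %.4g\n", x$alpha1, x$alpha2))
  cat(sprintf("  sigma_e = %.4g\n", x$sigma_e))
  invisible(x)
}

as_dd_params <- function(x) {
  if (inherits(x, "dd_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(dd_params(x$beta1p, x$beta2, x$beta3, x$alpha1, x$alpha2, x$sigma_e))
  }
  stop("cannot interpret 'params' as dd_params", call. = FALSE)
}

#' MCMC sampler configuration
#'
#' Defaults reproduce the reference schedule: four chains of 30,000 iterations
#' with a 20,000-iteration burn-in and thinning by 10, retaining 4,000
#' posterior draws in total. Convergence is assessed with the rank-based
#' split-\eqn{\hat{R}} (threshold 1.01) and bulk effective sample size
#' (threshold 400).
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param burn_in Warmup iterations per chain (adaptation window).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed governing initial values and trajectories.
#' @param alpha_prior_mean,alpha_prior_sd Normal prior on \eqn{\alpha_1} and
#'   \eqn{\alpha_2} (weakly informative; mean -1, sd 2). The `sd` is a
#'   standard deviation, not a variance.
#' @param sigma_max Upper bound of the flat prior on \eqn{\sigma_e}.
#' @param L_max Maximum number of leapfrog steps per trajectory (the number of
#'   steps is drawn uniformly from 1..`L_max` each iteration).
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param rhat_threshold,ess_threshold Convergence thresholds.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 30000L, burn_in = 20000L,
                        thin = 10L, seed = 1L,
                        alpha_prior_mean = -1, alpha_prior_sd = 2,
                        sigma_max = 10, L_max = 25L, target_accept = 0.8,
                        rhat_threshold = 1.01, ess_threshold = 400) {
  stopifnot(n_chains >= 1, n_iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 alpha_prior_mean = alpha_prior_mean,
                 alpha_prior_sd = alpha_prior_sd,
                 sigma_max = sigma_max, L_max = as.integer(L_max),
                 target_accept = target_accept,
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold),
            class = "mcmc_config")
}
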