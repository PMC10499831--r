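# Cormack-Jolly-Seber open-population survival model, conditioned on first
# release, with age-class-specific survival (fledgling first interval, adult
# after), individual condition and time-varying density covariates on the
# logit scale, and year-fixed detection probabilities. The never-seen-again
# probabilities chi are computed by backward recursion.

#' Build encounter histories from the long detection table
#'
#' @param encounters Long data frame `id, year, detected` (0/1).
#' @param individuals Optional individuals table supplying per-female
#'   covariates: the latent/normalised trait (`x`, or `condition` failing
#'   that) at first capture and the age class at first capture.
#' @return A `cjs_histories` list: `det` (individuals x occasions 0/1
#'   matrix), `first` (release occasion index per individual), `years`,
#'   `id`, and per-individual `x` and `age_at_first` when available.
#' @export
make_histories <- function(encounters, individuals = NULL) {
  stopifnot(is.data.frame(encounters),
            all(c("id", "year", "detected") %in% names(encounters)))
  years <- sort(unique(encounters$year))
  ids <- unique(encounters$id)
  det <- matrix(0L, nrow = length(ids), ncol = length(years),
                dimnames = list(ids, years))
  det[cbind(match(encounters$id, ids), match(encounters$year, years))] <-
    as.integer(encounters$detected)
  first <- apply(det, 1, function(r) which(r == 1L)[1])
  if (anyNA(first))
    stop("some histories contain no release (no detection at all)", call. = FALSE)
  out <- list(det = det, first = unname(first), years = years, id = ids)
  if (!is.null(individuals)) {
    xcol <- if ("x" %in% names(individuals)) "x" else
            if ("condition" %in% names(individuals)) "condition" else NULL
    first_rows <- individuals[order(individuals$year), ]
    first_rows <- first_rows[!duplicated(first_rows$id), ]
    m <- match(ids, first_rows$id)
    if (!is.null(xcol)) out$x <- first_rows[[xcol]][m]
    if ("age_class" %in% names(individuals))
      out$age_at_first <- first_rows$age_class[m]
  }
  class(out) <- "cjs_histories"
  out
}

#' Cormack-Jolly-Seber log-likelihood
#'
#' Standard CJS probability of the encounter histories conditional on first
#' release: products of interval survival and detection terms up to the last
#' detection, times the never-seen-again probability
#' \eqn{\chi_t = 1 - \phi_t + \phi_t (1 - p_{t+1}) \chi_{t+1}},
#' \eqn{\chi_T = 1}, accumulated by backward recursion.
#'
#' @param histories A `cjs_histories` object (see [make_histories()]), or a
#'   list with elements `det` and `first`.
#' @param phi Survival probabilities: scalar, or an individuals x (T-1)
#'   matrix (`phi[i, t]` = survival over interval t to t+1).
#' @param p Detection probabilities: scalar or length-T vector (`p[1]` is
#'   unused because the likelihood conditions on release).
#' @return Total log-likelihood (attribute `"by_individual"` holds the
#'   per-history contributions).
#' @examples
#' h <- list(det = matrix(c(1L, 1L), 1), first = 1L)
#' cjs_log_likelihood(h, phi = 0.8, p = 0.6)  # log(0.48)
#' @export
cjs_log_likelihood <- function(histories, phi, p) {
  det <- histories$det
  first <- histories$first
  n <- nrow(det); T <- ncol(det)
  if (T < 2L) stop("need at least two occasions", call. = FALSE)
  if (length(phi) == 1L) phi <- matrix(phi, n, T - 1L)
  if (!is.matrix(phi) || nrow(phi) != n || ncol(phi) != T - 1L)
    stop("phi must be scalar or an n x (T-1) matrix", call. = FALSE)
  if (length(p) == 1L) p <- rep(p, T)
  if (length(p) != T) stop("p must be scalar or length T", call. = FALSE)
  if (any(phi < 0 | phi > 1) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)

  # chi[i, t]: P(never seen after occasion t | alive at t)
  chi <- matrix(1, n, T)
  for (t in (T - 1L):1L) {
    chi[, t] <- 1 - phi[, t] + phi[, t] * (1 - p[t + 1L]) * chi[, t + 1L]
  }
  last <- max.col(det == 1L, ties.method = "last")
  # active cells: intervals t in [first, last - 1] per individual
  tt <- matrix(seq_len(T - 1L), n, T - 1L, byrow = TRUE)
  act <- which(tt >= first & tt < last)
  obs <- det[, 2:T, drop = FALSE] == 1L
  logp <- matrix(log(p[2:T]), n, T - 1L, byrow = TRUE)
  logq <- matrix(log(1 - p[2:T]), n, T - 1L, byrow = TRUE)
  M <- matrix(0, n, T - 1L)
  M[act] <- log(phi[act]) + ifelse(obs[act], logp[act], logq[act])
  ll <- rowSums(M) + log(chi[cbind(seq_len(n), last)])
  structure(sum(ll), by_individual = ll)
}

.cjs_terms <- function(terms) {
  allowed <- c("x", "N", "x:N", "year")
  bad <- setdiff(terms, allowed)
  if (length(bad)) stop("unknown survival terms: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if ("x:N" %in% terms && !all(c("x", "N") %in% terms))
    stop("interaction x:N requires both main effects", call. = FALSE)
  terms
}

#' Fit a Cormack-Jolly-Seber survival model by maximum likelihood
#'
#' Survival is modelled on the logit scale from an intercept plus optional
#' terms: individual condition `x`, standardised population size `N`
#' (year-specific, internally centred and scaled), their interaction `x:N`,
#' a free effect per interval (`"year"`), and — when age classes are known —
#' an additive fledgling offset for a female's first interval after fledging.
#' Detection is year-fixed (one free logit per re-encounter occasion), shared
#' across individuals, or fixed via `p_fixed`. Estimates are obtained by
#' BFGS maximisation with standard errors from the observed information.
#'
#' With two occasions and free detection the survival-detection product is
#' the only identified quantity; the fit then reports the composite
#' \eqn{\widehat{\phi p}} and flags the confounding instead of separating the
#' pair. With year-specific detection the terminal interval's \eqn{\phi} and
#' \eqn{p} are weakly separated only through the covariate structure; boundary
#' estimates and ill-conditioned information matrices are flagged.
#'
#' @param histories A `cjs_histories` from [make_histories()].
#' @param series Optional population series (`year`, `goose_n`) for the `N`
#'   covariate.
#' @param phi_terms Character subset of `c("x", "N", "x:N", "year")`.
#' @param age_effect Include the fledgling first-interval offset (requires
#'   `age_at_first` on the histories).
#' @param p_model `"year"` (default, one detection logit per occasion) or
#'   `"constant"`.
#' @param p_fixed Optional fixed detection probability (e.g. 1 for perfect
#'   detection); overrides `p_model`.
#' @return A `cjs_fit`: coefficient table (`estimate`, `se`), `logLik`, `k`,
#'   `n` (released individuals), `n_intervals` (individual-intervals),
#'   convergence info, and the design metadata needed by [predict_rate()].
#' @export
fit_cjs <- function(histories, series = NULL, phi_terms = "x",
                    age_effect = !is.null(histories$age_at_first),
                    p_model = c("year", "constant"), p_fixed = NULL) {
  stopifnot(inherits(histories, "cjs_histories"))
  p_model <- match.arg(p_model)
  phi_terms <- .cjs_terms(phi_terms)
  det <- histories$det
  n <- nrow(det); T <- ncol(det)
  if (T < 2L) stop("need at least two occasions", call. = FALSE)

  # two-occasion free-p case: only the product phi * p is identified
  if (T == 2L && is.null(p_fixed)) {
    released <- histories$first == 1L
    y2 <- det[released, 2L]
    prod_hat <- mean(y2)
    ll <- sum(y2 * log(prod_hat) + (1 - y2) * log(1 - prod_hat))
    out <- list(confounded = TRUE, composite_phi_p = prod_hat,
                se_composite = sqrt(prod_hat * (1 - prod_hat) / length(y2)),
                logLik = ll, k = 1L, n = sum(released),
                coefficients = data.frame(term = "phi*p (terminal composite)",
                                          estimate = prod_hat, se = NA_real_),
                message = "two occasions with free detection: terminal phi and p are confounded; reporting their product")
    class(out) <- "cjs_fit"
    return(out)
  }

  use_x <- "x" %in% phi_terms
  use_N <- "N" %in% phi_terms
  use_xN <- "x:N" %in% phi_terms
  use_year <- "year" %in% phi_terms
  if (use_x && is.null(histories$x))
    stop("phi term 'x' requested but histories carry no covariate", call. = FALSE)
  if (use_N && is.null(series))
    stop("phi term 'N' requested but no population series given", call. = FALSE)
  if (age_effect && is.null(histories$age_at_first))
    stop("age_effect requested but histories carry no age class", call. = FALSE)

  xv <- if (use_x) histories$x else rep(0, n)
  if (use_x && anyNA(xv)) stop("missing covariate values for some histories", call. = FALSE)
  Nv <- rep(0, T - 1L)
  N_center <- 0; N_scale <- 1
  if (use_N) {
    Nraw <- series$goose_n[match(histories$years, series$year)]
    if (anyNA(Nraw[seq_len(T - 1L)]))
      stop("population series does not cover the encounter years", call. = FALSE)
    N_center <- mean(Nraw[seq_len(T - 1L)]); N_scale <- sd(Nraw[seq_len(T - 1L)])
    if (!is.finite(N_scale) || N_scale == 0) N_scale <- 1
    Nv <- (Nraw[seq_len(T - 1L)] - N_center) / N_scale
  }
  fledg_first <- if (age_effect) histories$age_at_first == "fledgling" else rep(FALSE, n)

  # design columns for the (individual, interval) grid
  phi_design <- function(beta) {
    eta <- matrix(beta[1], n, T - 1L)
    j <- 1L
    if (use_x) { j <- j + 1L; eta <- eta + beta[j] * xv }
    if (use_N) { j <- j + 1L; eta <- eta + matrix(beta[j] * Nv, n, T - 1L, byrow = TRUE) }
    if (use_xN) { j <- j + 1L; eta <- eta + beta[j] * outer(xv, Nv) }
    if (use_year && T >= 3L) {
      for (t in 2:(T - 1L)) { j <- j + 1L; eta[, t] <- eta[, t] + beta[j] }
    }
    if (age_effect) {
      j <- j + 1L
      # a fledgling's first interval is the one starting at her release year;
      # releases at the final occasion have no interval (and no information)
      for (i in which(fledg_first & histories$first <= T - 1L)) {
        f <- histories$first[i]
        eta[i, f] <- eta[i, f] + beta[j]
      }
    }
    plogis(eta)
  }
  phi_names <- c("phi_intercept",
                 if (use_x) "phi_x", if (use_N) "phi_N", if (use_xN) "phi_x:N",
                 if (use_year && T >= 3L) paste0("phi_year", histories$years[2:(T - 1L)]),
                 if (age_effect) "phi_fledgling")
  k_phi <- length(phi_names)

  if (!is.null(p_fixed)) {
    k_p <- 0L
    p_fun <- function(gam) rep(p_fixed, T)
    p_names <- character()
  } else if (p_model == "constant") {
    k_p <- 1L
    p_fun <- function(gam) rep(plogis(gam[1]), T)
    p_names <- "p_intercept"
  } else {
    k_p <- T - 1L
    p_fun <- function(gam) c(NA, plogis(gam))
    p_names <- paste0("p_", histories$years[2:T])
  }

  nll <- function(par) {
    phi <- phi_design(par[seq_len(k_phi)])
    p <- p_fun(par[k_phi + seq_len(k_p)])
    p[1] <- 0.5  # unused; conditioning on release
    -as.numeric(cjs_log_likelihood(histories, phi, p))
  }
  par0 <- c(rep(0, k_phi), rep(qlogis(0.7), k_p))
  opt <- optim(par0, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-10))
  grad_norm <- max(abs(.num_grad(nll, opt$par)))
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(opt$par)) else sqrt(pmax(diag(vc), 0))
  boundary <- any(abs(opt$par) > 10)

  coefs <- data.frame(term = c(phi_names, p_names),
                      estimate = opt$par, se = se, stringsAsFactors = FALSE)
  n_intervals <- sum(T - histories$first)
  out <- list(coefficients = coefs, logLik = -opt$value,
              k = length(opt$par), n = n, n_intervals = n_intervals,
              vcov = vc, converged = opt$convergence == 0L,
              gradient_norm = grad_norm, boundary = boundary,
              confounded = FALSE,
              phi_terms = phi_terms, age_effect = age_effect,
              p_model = if (!is.null(p_fixed)) "fixed" else p_model,
              p_fixed = p_fixed, k_phi = k_phi,
              N_center = N_center, N_scale = N_scale,
              N_range = if (use_N) N_center + N_scale * range(Nv) else NULL,
              years = histories$years)
  if (!out$converged)
    warning("CJS optimisation did not converge (gradient norm ",
            signif(grad_norm, 3), ")", call. = FALSE)
  class(out) <- "cjs_fit"
  out
}

.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' @export
logLik.cjs_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, class = "logLik")
}

#' @export
print.cjs_fit <- function(x, ...) {
  if (x$confounded) {
    cat("CJS fit (confounded):", x$message, "\n")
    print(x$coefficients, row.names = FALSE, digits = 4)
    return(invisible(x))
  }
  cat(sprintf("CJS fit: %d histories, logLik = %.3f, k = %d%s\n",
              x$n, x$logLik, x$k,
              if (x$boundary) " [boundary estimate flagged]" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}
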