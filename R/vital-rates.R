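# Reproduction GLMMs (binomial reproductive rate; Poisson or zero-truncated
# Poisson fledged brood size) with individual and year random intercepts,
# AICc model selection, and inverse-link predictions with delta-method CIs.

.vital_terms <- function(terms) {
  allowed <- c("x", "N", "x:N")
  bad <- setdiff(terms, allowed)
  if (length(bad)) stop("unknown terms: ", paste(bad, collapse = ", "), call. = FALSE)
  if ("x:N" %in% terms && !all(c("x", "N") %in% terms))
    stop("interaction x:N requires both main effects", call. = FALSE)
  terms
}

.terms_formula <- function(response, terms) {
  rhs <- if (length(terms) == 0L) "1" else
    paste(sub("x:N", "x:Ns", sub("^N$", "Ns", terms)), collapse = " + ")
  as.formula(paste(response, "~", rhs, "+ (1 | id) + (1 | year)"))
}

#' Fit a reproduction model with individual and year random effects
#'
#' Two responses are supported. `reproductive_rate`: whether a female had at
#' least one fledgling (0/1), binomial GLMM, restricted to females of
#' breeding age (2 years and older) when an `age` column is present.
#' `fledged_brood_size`: the brood count of successfully reproducing females
#' only (records with zero young are excluded with a logged count), fitted as
#' a zero-truncated Poisson GLMM by default (`brood_model = "poisson"` gives
#' the untruncated variant). Both carry random intercepts for individual
#' (`id`) and `year`. Population size enters standardised (centred, scaled
#' by its sd); coefficients are reported on that scale and [predict_rate()]
#' back-transforms.
#'
#' @param data Data frame with columns `id`, `year`, `x`, `N`, and the
#'   response: `success` (0/1) for the rate, `brood` (count) for brood size;
#'   optional `age` in years.
#' @param response `"reproductive_rate"` or `"fledged_brood_size"`.
#' @param terms Fixed-effect terms, a subset of `c("x", "N", "x:N")`
#'   (the interaction requires both main effects).
#' @param brood_model `"ztpoisson"` (default) or `"poisson"`.
#' @return A `repro_fit`: coefficient table, `logLik`, `k`, `n`, the fitted
#'   model object, dropped-record counts, and a `boundary` flag when a
#'   random-effect variance is estimated at (or near) zero.
#' @export
fit_reproduction <- function(data, response = c("reproductive_rate",
                                                "fledged_brood_size"),
                             terms = c("x", "N"),
                             brood_model = c("ztpoisson", "poisson")) {
  response <- match.arg(response)
  brood_model <- match.arg(brood_model)
  terms <- .vital_terms(terms)
  stopifnot(is.data.frame(data), all(c("id", "year", "x", "N") %in% names(data)))
  dropped <- c(immature = 0L, zero_brood = 0L)
  if (response == "reproductive_rate") {
    if (!("success" %in% names(data)))
      stop("'data' needs a 'success' column (0/1)", call. = FALSE)
    if ("age" %in% names(data)) {
      keep <- data$age >= 2
      dropped["immature"] <- sum(!keep)
      data <- data[keep, , drop = FALSE]
    }
    if (all(data$success == 1))
      stop("all females successful: reproductive-rate model is degenerate (no zeros)",
           call. = FALSE)
    if (all(data$success == 0))
      stop("no successful females: reproductive-rate model is degenerate", call. = FALSE)
  } else {
    if (!("brood" %in% names(data)))
      stop("'data' needs a 'brood' column", call. = FALSE)
    keep <- data$brood >= 1
    dropped["zero_brood"] <- sum(!keep)
    data <- data[keep, , drop = FALSE]
    if (nrow(data) == 0L)
      stop("no successful females: cannot model brood size", call. = FALSE)
  }

  N_center <- mean(data$N); N_scale <- sd(data$N)
  if (!is.finite(N_scale) || N_scale == 0) N_scale <- 1
  data$Ns <- (data$N - N_center) / N_scale
  data$id <- factor(data$id)
  data$year <- factor(data$year)

  if (response == "reproductive_rate") {
    fml <- .terms_formula("success", terms)
    mod <- suppressMessages(lme4::glmer(fml, data = data, family = binomial()))
    engine <- "glmer"
  } else if (brood_model == "poisson") {
    fml <- .terms_formula("brood", terms)
    mod <- suppressMessages(lme4::glmer(fml, data = data, family = poisson()))
    engine <- "glmer"
  } else {
    fml <- .terms_formula("brood", terms)
    mod <- glmmTMB::glmmTMB(fml, data = data,
                            family = glmmTMB::truncated_poisson())
    engine <- "glmmTMB"
  }

  if (engine == "glmer") {
    fe <- lme4::fixef(mod)
    vc <- as.matrix(vcov(mod))
    vcors <- unlist(lapply(lme4::VarCorr(mod), function(v) attr(v, "stddev")^2))
    boundary <- lme4::isSingular(mod, tol = 1e-4)
  } else {
    fe <- glmmTMB::fixef(mod)$cond
    vc <- as.matrix(vcov(mod)$cond)
    vcors <- unlist(lapply(glmmTMB::VarCorr(mod)$cond, function(v) attr(v, "stddev")^2))
    boundary <- any(vcors < 1e-4)
  }
  ll <- logLik(mod)
  coefs <- data.frame(term = names(fe), estimate = unname(fe),
                      se = sqrt(diag(vc)), stringsAsFactors = FALSE)
  out <- list(coefficients = coefs, vcov = vc, logLik = as.numeric(ll),
              k = attr(ll, "df"), n = nrow(data), model = mod,
              engine = engine, response = response, terms = terms,
              brood_model = if (response == "fledged_brood_size") brood_model else NULL,
              ranef_variances = vcors, boundary = boundary,
              dropped = dropped, N_center = N_center, N_scale = N_scale,
              N_range = range(data$N))
  if (boundary)
    message("random-effect variance estimated at the boundary (near zero); flagged")
  class(out) <- "repro_fit"
  out
}

#' @export
logLik.repro_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, class = "logLik")
}

#' @export
print.repro_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): n = %d, logLik = %.3f, k = %d%s\n",
              x$response, x$engine, x$n, x$logLik, x$k,
              if (x$boundary) " [boundary variance]" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' AICc model-comparison table
#'
#' Akaike's information criterion with the small-sample correction,
#' \deqn{\mathrm{AICc} = -2 \ln L + 2k + \frac{2k(k+1)}{n - k - 1},}
#' for a set of candidate models fitted to the identical dataset. Candidates
#' within 2 AICc units of the best are flagged as equally supported, and the
#' preferred model is the most parsimonious (fewest parameters, ties broken
#' by label order) within that support set.
#'
#' @param candidates Named list of fitted models. Anything with a [logLik()]
#'   method (with a `df` attribute) works: `cjs_fit`, `repro_fit`, `merMod`,
#'   `glmmTMB` objects, or plain lists with `logLik` and `k` elements.
#' @param n Effective sample size used in the correction (the package
#'   convention is individual-years; individuals is the alternative — report
#'   whichever you use).
#' @return A `model_comparison` data frame: `model`, `k`, `logLik`, `AICc`,
#'   `delta_AICc`, `supported`, sorted by AICc, with attribute `"preferred"`.
#' @examples
#' cands <- list(m1 = list(logLik = -100, k = 3), m2 = list(logLik = -99.8, k = 4))
#' model_selection_aicc(cands, n = 50)
#' @export
model_selection_aicc <- function(candidates, n) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  labels <- names(candidates)
  if (is.null(labels) || any(labels == ""))
    labels <- paste0("model", seq_along(candidates))
  extract <- function(m) {
    if (is.list(m) && !is.object(m) && all(c("logLik", "k") %in% names(m)))
      return(c(ll = as.numeric(m$logLik), k = as.numeric(m$k)))
    ll <- logLik(m)
    c(ll = as.numeric(ll), k = as.numeric(attr(ll, "df")))
  }
  vals <- t(vapply(candidates, extract, numeric(2)))
  k <- vals[, "k"]; ll <- vals[, "ll"]
  if (any(n <= k + 1))
    stop("AICc undefined: n <= k + 1 for ",
         paste(labels[n <= k + 1], collapse = ", "), call. = FALSE)
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  tab <- data.frame(model = labels, k = k, logLik = ll, AICc = aicc,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc, tab$k, tab$model), ]
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  tab$supported <- tab$delta_AICc < 2
  sup <- tab[tab$supported, ]
  preferred <- sup$model[order(sup$k, sup$model)][1]
  rownames(tab) <- NULL
  structure(tab, class = c("model_comparison", "data.frame"),
            preferred = preferred, n = n)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("AICc model comparison (n = %g); preferred: %s\n",
              attr(x, "n"), attr(x, "preferred")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Predict a vital rate over a trait grid at a given population size
#'
#' Fixed-effect (population-level) predictions on the link scale with
#' delta-method 95% confidence intervals, inverse-linked to the response
#' scale, so survival/reproductive-rate predictions lie in (0, 1) and brood
#' means are positive. Warns when `N` lies outside the range the model was
#' fitted to (extrapolation guard).
#'
#' @param fit A `repro_fit` or (non-confounded) `cjs_fit`.
#' @param x Trait grid (non-empty numeric).
#' @param N Population size (scalar, raw scale).
#' @param age For CJS fits with an age effect: `"adult"` (default) or
#'   `"fledgling"` curve.
#' @param level Confidence level.
#' @return Data frame `x`, `N`, `fit`, `lwr`, `upr` (response scale).
#' @export
predict_rate <- function(fit, x, N, age = "adult", level = 0.95) {
  if (length(x) == 0L) stop("empty trait grid", call. = FALSE)
  if (length(N) != 1L || !is.finite(N)) stop("'N' must be a single number", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  UseMethod("predict_rate")
}

#' @export
predict_rate.repro_fit <- function(fit, x, N, age = "adult", level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  if (!is.null(fit$N_range) && (N < fit$N_range[1] || N > fit$N_range[2]))
    warning("N = ", N, " lies outside the fitted range [",
            paste(signif(fit$N_range, 4), collapse = ", "), "]: extrapolating",
            call. = FALSE)
  Ns <- (N - fit$N_center) / fit$N_scale
  X <- .vital_design(fit$coefficients$term, x, Ns)
  eta <- drop(X %*% fit$coefficients$estimate)
  se <- sqrt(pmax(rowSums((X %*% fit$vcov) * X), 0))
  inv <- if (fit$response == "reproductive_rate") plogis else exp
  data.frame(x = x, N = N, fit = inv(eta),
             lwr = inv(eta - z * se), upr = inv(eta + z * se))
}

#' @export
predict_rate.cjs_fit <- function(fit, x, N, age = "adult", level = 0.95) {
  if (fit$confounded)
    stop("confounded two-occasion fit: no separate survival prediction", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  if (!is.null(fit$N_range) && (N < fit$N_range[1] || N > fit$N_range[2]))
    warning("N = ", N, " lies outside the fitted range [",
            paste(signif(fit$N_range, 4), collapse = ", "), "]: extrapolating",
            call. = FALSE)
  Ns <- (N - fit$N_center) / fit$N_scale
  terms <- fit$coefficients$term[seq_len(fit$k_phi)]
  X <- matrix(0, length(x), fit$k)
  X[, 1] <- 1
  for (j in seq_along(terms)) {
    X[, j] <- switch(terms[j],
                     phi_intercept = 1,
                     phi_x = x,
                     phi_N = Ns,
                     `phi_x:N` = x * Ns,
                     phi_fledgling = as.numeric(age == "fledgling"),
                     0)  # free year effects: predictions at the reference interval
  }
  est <- fit$coefficients$estimate
  eta <- drop(X %*% est)
  if (is.null(fit$vcov)) {
    se <- rep(NA_real_, length(x))
  } else {
    se <- sqrt(pmax(rowSums((X %*% fit$vcov) * X), 0))
  }
  data.frame(x = x, N = N, fit = plogis(eta),
             lwr = plogis(eta - z * se), upr = plogis(eta + z * se))
}

.vital_design <- function(terms, x, Ns) {
  X <- matrix(0, length(x), length(terms))
  for (j in seq_along(terms)) {
    X[, j] <- switch(terms[j],
                     `(Intercept)` = 1,
                     x = x,
                     Ns = Ns,
                     `x:Ns` = x * Ns,
                     stop("unknown coefficient term: ", terms[j]))
  }
  X
}
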