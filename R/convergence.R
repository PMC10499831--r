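# Rank-based convergence diagnostics (Vehtari et al. 2021 style):
# split chains in half, rank-normalise pooled draws, then compute the classic
# between/within-chain potential scale reduction factor and a bulk effective
# sample size from Geyer initial-monotone-sequence autocorrelation sums.

.rank_normalize <- function(mat) {
  S <- length(mat)
  z <- qnorm((rank(as.vector(mat), ties.method = "average") - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow = nrow(mat), ncol = ncol(mat))
}

.split_halves <- function(mat) {
  n <- nrow(mat)
  h <- n %/% 2L
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[(n - h + 1L):n, , drop = FALSE])
}

# mat: iterations x chains (already split + rank-normalised)
.rhat_basic <- function(mat) {
  n <- nrow(mat); M <- ncol(mat)
  mns <- colMeans(mat)
  vars <- apply(mat, 2, var)
  W <- mean(vars)
  B <- n * var(mns)
  var_plus <- (n - 1) / n * W + B / n
  if (W <= 0) return(NA_real_)
  sqrt(var_plus / W)
}

.ess_basic <- function(mat) {
  n <- nrow(mat); M <- ncol(mat)
  vars <- apply(mat, 2, var)
  W <- mean(vars)
  B <- n * var(mns <- colMeans(mat))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus <= 0) return(NA_real_)
  # mean autocovariance across chains at each lag
  max_lag <- n - 2L
  acov <- sapply(seq_len(M), function(m)
    acf(mat[, m], lag.max = max_lag, type = "covariance",
        plot = FALSE, demean = TRUE)$acf[, 1, 1])
  mean_acov <- rowMeans(acov)  # lag 0 .. max_lag
  rho <- 1 - (W - mean_acov) / var_plus  # rho[1] is lag 0
  # Geyer initial positive + monotone sequence on paired sums
  K <- floor(length(rho) / 2)
  P <- rho[2 * seq_len(K) - 1] + rho[2 * seq_len(K)]
  cut <- which(!is.finite(P) | P <= 0)[1]
  if (!is.na(cut)) P <- P[seq_len(cut - 1)]
  if (length(P) == 0L) return(M * n)
  P <- cummin(P)
  tau <- max(-1 + 2 * sum(P), 1e-8)
  M * n / tau
}

#' Convergence diagnostics for multi-chain MCMC output
#'
#' Computes the rank-normalised split-\eqn{\hat{R}} and a bulk effective
#' sample size per parameter, together with pass/fail flags against the
#' configured thresholds (defaults \eqn{\hat{R} \le 1.01} and
#' \eqn{n_{\mathrm{eff}} \ge 400}).
#'
#' @param chains A list of draw matrices (one per chain, iterations x
#'   parameters, identical column names), or a 3-d array (iterations x chains
#'   x parameters).
#' @param rhat_threshold Maximum acceptable split-\eqn{\hat{R}}.
#' @param ess_threshold Minimum acceptable effective sample size.
#' @param divergences Optional count of post-warmup divergent transitions,
#'   carried into the report.
#' @return A `convergence_report`: data frame with columns `parameter`,
#'   `rhat`, `ess`, `pass`, plus attributes `pass` (overall) and
#'   `divergences`.
#' @examples
#' set.seed(1)
#' chains <- replicate(4, matrix(rnorm(1000), ncol = 1,
#'                     dimnames = list(NULL, "theta")), simplify = FALSE)
#' check_convergence(chains)
#' @export
check_convergence <- function(chains, rhat_threshold = 1.01,
                              ess_threshold = 400, divergences = 0L) {
  if (is.array(chains) && length(dim(chains)) == 3L) {
    chains <- lapply(seq_len(dim(chains)[2]), function(m) chains[, m, ])
  }
  if (!is.list(chains)) stop("'chains' must be a list of matrices or a 3-d array")
  chains <- lapply(chains, function(m) {
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    m
  })
  if (length(chains) < 2L)
    stop("at least two chains are required for split-Rhat")
  if (any(vapply(chains, nrow, 1L) < 4L))
    stop("each chain needs at least 4 draws")
  P <- ncol(chains[[1]])
  pnames <- colnames(chains[[1]])
  if (is.null(pnames)) pnames <- paste0("par", seq_len(P))

  rhat <- ess <- numeric(P)
  for (p in seq_len(P)) {
    split_mat <- do.call(cbind, lapply(chains, function(m) .split_halves(m[, p, drop = FALSE])))
    if (diff(range(split_mat)) == 0) { rhat[p] <- NA_real_; ess[p] <- NA_real_; next }
    z <- .rank_normalize(split_mat)
    rhat[p] <- .rhat_basic(z)
    ess[p] <- .ess_basic(z)
  }
  out <- data.frame(parameter = pnames, rhat = rhat, ess = ess,
                    pass = !is.na(rhat) & rhat <= rhat_threshold &
                           !is.na(ess) & ess >= ess_threshold,
                    stringsAsFactors = FALSE)
  structure(out, class = c("convergence_report", "data.frame"),
            pass = all(out$pass), divergences = as.integer(divergences),
            rhat_threshold = rhat_threshold, ess_threshold = ess_threshold)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence report (Rhat <= %.3g, ESS >= %g): %s; divergences: %d\n",
              attr(x, "rhat_threshold"), attr(x, "ess_threshold"),
              if (isTRUE(attr(x, "pass"))) "PASS" else "FAIL",
              attr(x, "divergences")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
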