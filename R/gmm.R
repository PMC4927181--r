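#' Diagonal-covariance Gaussian mixture fitted by EM
#'
#' Fits a k-component Gaussian mixture with diagonal covariances to rows of
#' `X` by expectation-maximisation, initialised from a hard partition
#' (typically a cosine k-means solution). Full 42-dimensional covariances are
#' not identifiable from a few hundred segments, hence the diagonal
#' restriction; per-dimension variances are floored at
#' `var_floor_rel` times the per-dimension data variance (plus a tiny
#' absolute floor for constant dimensions), which keeps every density — and
#' therefore every downstream negative log-likelihood — finite.
#'
#' @param X Numeric matrix, observations in rows.
#' @param init Integer vector of initial hard assignments (length
#'   `nrow(X)`), e.g. `kmeans_cosine(X, k)$assignments`.
#' @param max_iter EM iteration cap (default 200).
#' @param tol Relative log-likelihood change below which EM stops
#'   (default 1e-6).
#' @param var_floor_rel Relative variance floor (default 1e-6).
#' @return List of class `gmm_diag`: `weights` (sum to 1), `means` (`k x d`),
#'   `variances` (`k x d`), `responsibilities`, `assignments` (max
#'   posterior), `loglik` (per-iteration trace, non-decreasing), `k`, `d`.
#' @export
fit_gmm_diag <- function(X, init, max_iter = 200, tol = 1e-6,
                         var_floor_rel = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  init <- as.integer(init)
  stopifnot(length(init) == n)
  k <- max(init)
  floor_vec <- pmax(var_floor_rel * apply(X, 2, var), 1e-12)

  w <- tabulate(init, k) / n
  mu <- matrix(0, k, d); sig <- matrix(0, k, d)
  for (j in seq_len(k)) {
    rows <- X[init == j, , drop = FALSE]
    mu[j, ] <- colMeans(rows)
    v <- if (nrow(rows) > 1) apply(rows, 2, var) * (nrow(rows) - 1) / nrow(rows) else rep(0, d)
    sig[j, ] <- pmax(v, floor_vec)
  }
  w <- pmax(w, 1e-12); w <- w / sum(w)

  ll_trace <- numeric(0)
  resp <- NULL
  for (it in seq_len(max_iter)) {
    lp <- gmm_log_density_by_comp(X, w, mu, sig)   # n x k
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    resp <- exp(lp - lse)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <=
        tol * (abs(ll_trace[it - 1]) + .Machine$double.eps)) break
    nj <- colSums(resp)
    for (j in seq_len(k)) {
      if (nj[j] < 1e-10) next   # vanished component keeps its parameters
      mu[j, ] <- colSums(resp[, j] * X) / nj[j]
      ex2 <- colSums(resp[, j] * X^2) / nj[j]
      sig[j, ] <- pmax(ex2 - mu[j, ]^2, floor_vec)
    }
    w <- pmax(nj / n, 1e-12); w <- w / sum(w)
  }
  structure(list(weights = w, means = mu, variances = sig,
                 responsibilities = resp,
                 assignments = max.col(resp, ties.method = "first"),
                 loglik = ll_trace, k = k, d = d),
            class = "gmm_diag")
}

# log(w_j) + log N(x; mu_j, diag(sig_j)) for every row and component.
gmm_log_density_by_comp <- function(X, w, mu, sig) {
  n <- nrow(X); k <- nrow(mu)
  lp <- matrix(0, n, k)
  for (j in seq_len(k)) {
    const <- -0.5 * sum(log(2 * pi * sig[j, ]))
    dev <- sweep(X, 2, mu[j, ])
    lp[, j] <- log(w[j]) + const - 0.5 * colSums(t(dev^2) / sig[j, ])
  }
  lp
}

#' Negative log-likelihood of observations under a Gaussian mixture
#'
#' The total (or per-row mean) negative log mixture density of `rows` under a
#' fitted model. Lower values mean the observations are more consistent with
#' the model; this is the quantity ranked in area classification and used as
#' the inter-area distance in similarity analysis.
#'
#' @param model A `gmm_diag` or `group_model` object.
#' @param rows Numeric matrix of observations (columns must match the model
#'   dimension).
#' @param average Divide by the number of rows? (default `FALSE`).
#' @return A single non-negative-dimension scalar in nats.
#' @export
nll_score <- function(model, rows, average = FALSE) {
  g <- if (inherits(model, "group_model")) model$gmm else model
  stopifnot(inherits(g, "gmm_diag"))
  rows <- as.matrix(rows)
  if (nrow(rows) < 1) abort("Need at least one observation row.")
  if (ncol(rows) != g$d) {
    abort(sprintf("Observation dimension (%d) does not match the model (%d).",
                  ncol(rows), g$d))
  }
  lp <- gmm_log_density_by_comp(rows, g$weights, g$means, g$variances)
  m <- apply(lp, 1, max)
  nll <- -sum(m + log(rowSums(exp(lp - m))))
  if (average) nll / nrow(rows) else nll
}
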