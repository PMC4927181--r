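#' k-means clustering under cosine distance
#'
#' Spherical k-means: the distance between two spectra is one minus the
#' cosine of their included angle, so clustering is driven by spectral shape,
#' not amplitude. Rows are projected to the unit sphere; centroids are the
#' mean of their assigned rows renormalised to unit length. The algorithm is
#' restarted `n_replicates` times from random row subsets and the solution
#' with the smallest total within-cluster distance is kept. Clusters that
#' empty during iteration are re-seeded from the row farthest from its
#' current centroid.
#'
#' @param X Numeric matrix, observations in rows.
#' @param k Number of clusters (<= rows).
#' @param n_replicates Random restarts (default 10).
#' @param max_iter Iteration cap per restart (default 100).
#' @param seed Optional seed for reproducible restarts.
#' @return List of class `kmeans_cosine`: `assignments` (integer per row),
#'   `centroids` (`k x d`, unit rows), `within` (total within-cluster cosine
#'   distance of the best restart), `within_replicates`.
#' @export
kmeans_cosine <- function(X, k, n_replicates = 10, max_iter = 100, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) abort(sprintf("k = %d exceeds the number of observations (%d).", k, n))
  U <- unit_rows(X)
  with_seed(seed, {
    best <- NULL
    withins <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      sol <- kmeans_cosine_once(U, k, max_iter)
      withins[r] <- sol$within
      if (is.null(best) || sol$within < best$within) best <- sol
    }
    structure(list(assignments = best$assignments, centroids = best$centroids,
                   within = best$within, within_replicates = withins),
              class = "kmeans_cosine")
  })
}

# Rows scaled to unit norm; near-zero rows are left at (numerical) zero and
# sit at cosine distance 1 from everything.
unit_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  X / pmax(nrm, 1e-12)
}

kmeans_cosine_once <- function(U, k, max_iter) {
  n <- nrow(U)
  C <- U[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    sim <- U %*% t(C)
    assignments <- max.col(sim, ties.method = "first")
    # re-seed empty clusters from the worst-fitting row
    for (j in which(tabulate(assignments, k) == 0L)) {
      worst <- which.min(sim[cbind(seq_len(n), assignments)])
      C[j, ] <- U[worst, ]
      assignments[worst] <- j
      sim <- U %*% t(C)
      assignments <- max.col(sim, ties.method = "first")
    }
    if (identical(assignments, assign_old)) break
    assign_old <- assignments
    for (j in seq_len(k)) {
      m <- colSums(U[assignments == j, , drop = FALSE])
      nm <- sqrt(sum(m^2))
      if (nm > 1e-12) C[j, ] <- m / nm
    }
  }
  sim <- U %*% t(C)
  assignments <- max.col(sim, ties.method = "first")
  within <- sum(1 - sim[cbind(seq_len(n), assignments)])
  list(assignments = assignments, centroids = C, within = within)
}

# Pairwise cosine distance matrix (1 - cosine similarity) between rows.
cosine_dist <- function(X) {
  U <- unit_rows(as.matrix(X))
  d <- 1 - U %*% t(U)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}
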