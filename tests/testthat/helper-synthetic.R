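# Shared fixtures, built in code.

# k tight direction bundles in d dimensions: `per` points per bundle around
# orthogonal axis directions, with small isotropic jitter.
make_bundles <- function(k, per, d = 10, noise = 0.03, seed = 1) {
  stopifnot(k <= d)
  set.seed(seed)
  centers <- diag(d)[rep(seq_len(k), each = per), , drop = FALSE]
  centers + matrix(rnorm(k * per * d, 0, noise), k * per, d)
}

# Minimal hand-built subject_model: enough structure for fit_group_model.
fake_subject_model <- function(subject, rows, fractions = NULL) {
  rows <- as.matrix(rows)
  k1 <- nrow(rows)
  fractions <- fractions %||% rep(100 / k1, k1)
  structure(list(
    subject = subject, area = "areaX", k1 = k1,
    gmm = list(means = rows), segment_fraction = fractions,
    n_segments = 100
  ), class = "subject_model")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force best 2-partition under cosine distance (for small n).
best_cosine_2partition <- function(X) {
  U <- X / sqrt(rowSums(X^2))
  n <- nrow(U)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {           # fix point 1 in group 1
    g <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(g)) < 2) next
    within <- 0
    for (j in 1:2) {
      rows <- U[g == j, , drop = FALSE]
      m <- colSums(rows); m <- m / sqrt(sum(m^2))
      within <- within + sum(1 - rows %*% m)
    }
    if (is.null(best) || within < best$within) best <- list(g = g, within = within)
  }
  best
}

# Naive UPGMA: heights of successive merges, where the distance between two
# clusters is the mean of all original pairwise distances between them.
upgma_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, j, i)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}
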