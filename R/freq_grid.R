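#' Banded logarithmic analysis frequency grid
#'
#' Builds the 42-frequency grid used throughout the package: frequencies are
#' log-spaced within each classical band (delta, theta, alpha, beta, gamma)
#' between 1 and 120 Hz and snapped to the 0.5-Hz lattice that a 1-s segment
#' zero-padded to 2 s resolves. Snapping collisions are resolved upward to the
#' next free 0.5-Hz step, working from low to high frequencies, so the grid is
#' strictly increasing. Band labels follow the construction (6 delta, 9 theta,
#' 5 alpha, 8 beta, 14 gamma values); because the 0.5-Hz lattice has fewer
#' slots than that below 7 Hz, the last delta and theta values sit just past
#' their nominal band edge.
#'
#' @return A tibble of class `freq_grid` with columns `freq_hz` (strictly
#'   increasing multiples of 0.5 Hz in \[1, 120\]) and `band` (factor with
#'   levels delta, theta, alpha, beta, gamma). The nominal band edges are
#'   attached as attribute `band_edges`.
#' @examples
#' grid <- build_frequency_grid()
#' nrow(grid)          # 42
#' table(grid$band)    # 6 9 5 8 14
#' @export
build_frequency_grid <- function() {
  edges <- list(
    delta = c(1, 3), theta = c(3, 7), alpha = c(7, 13),
    beta = c(13, 30), gamma = c(30, 120)
  )
  counts <- c(delta = 6L, theta = 9L, alpha = 5L, beta = 8L, gamma = 14L)

  raw <- unlist(lapply(names(edges), function(b) {
    lo <- edges[[b]][1]; hi <- edges[[b]][2]; n <- counts[[b]]
    if (b == "delta") {
      exp(seq(log(lo), log(hi), length.out = n))
    } else {
      # lower edge is exclusive for bands above delta
      exp(seq(log(lo), log(hi), length.out = n + 1))[-1]
    }
  }))

  snapped <- 0.5 * round(2 * raw)
  freqs <- numeric(length(snapped))
  used <- numeric(0)
  for (i in seq_along(snapped)) {
    v <- snapped[i]
    while (v %in% used) v <- v + 0.5
    freqs[i] <- v
    used <- c(used, v)
  }

  out <- tibble(
    freq_hz = freqs,
    band = factor(rep(names(counts), counts), levels = names(counts))
  )
  attr(out, "band_edges") <- edges
  class(out) <- c("freq_grid", class(out))
  out
}

# Accept either a freq_grid tibble or a bare frequency vector.
grid_freqs <- function(grid) {
  if (is.numeric(grid)) return(as.numeric(grid))
  if (!is.data.frame(grid) || is.null(grid[["freq_hz"]])) {
    abort("`grid` must be a freq_grid tibble (see build_frequency_grid()) or a numeric vector of frequencies.")
  }
  grid$freq_hz
}
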