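#' Peak of a cluster-mean spectrum
#'
#' Frequency and amplitude of the global maximum of a spectrum on the grid.
#' A perfectly flat spectrum has no peak and is an error; a maximum on the
#' grid boundary (monotone spectrum) is returned with a warning.
#'
#' @param spectrum Numeric vector on the grid frequencies.
#' @param grid Frequency grid.
#' @return One-row tibble with `peak_hz` and `peak_amplitude`.
#' @export
find_peak <- function(spectrum, grid = build_frequency_grid()) {
  freqs <- grid_freqs(grid)
  stopifnot(length(spectrum) == length(freqs))
  if (diff(range(spectrum)) == 0) abort("Flat spectrum: no peak.")
  i <- which.max(spectrum)
  if (i == 1L || i == length(spectrum)) {
    warn("Spectrum is maximal at the grid boundary; peak may lie outside the analysed range.")
  }
  tibble(peak_hz = freqs[i], peak_amplitude = spectrum[i])
}

#' Peak table of a fingerprint's clusters
#'
#' @param model A `group_model`.
#' @param grid Frequency grid.
#' @return Tibble with one row per cluster: cluster, peak_hz,
#'   peak_amplitude, duration, stable.
#' @export
profile_peaks <- function(model, grid = build_frequency_grid()) {
  stopifnot(inherits(model, "group_model"))
  sp <- profile_spectra(model)
  pk <- dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(j) {
    find_peak(sp[j, ], grid)
  }))
  dplyr::bind_cols(model$clusters[, c("cluster", "duration", "stable")], pk)
}

#' Match spectral modes between two conditions by peak frequency
#'
#' Pairs clusters of two fingerprints (e.g. rest and listening) whose peak
#' frequencies are comparable, by greedy nearest-peak matching: candidate
#' pairs are considered in ascending order of peak-frequency difference and
#' accepted while both members are unmatched and the difference is within
#' tolerance. The default tolerance is one grid step at the peaks in
#' question. Unmatched clusters are reported as condition-specific modes.
#'
#' @param a,b `group_model` objects or peak tibbles (from
#'   [profile_peaks()]).
#' @param tol_hz Maximum peak difference in Hz, or `NULL` for one grid step.
#' @param grid Frequency grid (used for peak extraction and the default
#'   tolerance).
#' @return List with `matched` (tibble cluster_a, cluster_b, peak_hz_a,
#'   peak_hz_b, delta_hz), `unmatched_a`, `unmatched_b` (peak tibbles).
#' @export
match_modes <- function(a, b, tol_hz = NULL, grid = build_frequency_grid()) {
  pa <- if (inherits(a, "group_model")) profile_peaks(a, grid) else a
  pb <- if (inherits(b, "group_model")) profile_peaks(b, grid) else b
  freqs <- grid_freqs(grid)
  cand <- tidyr::expand_grid(i = seq_len(nrow(pa)), j = seq_len(nrow(pb)))
  cand$delta <- abs(pa$peak_hz[cand$i] - pb$peak_hz[cand$j])
  if (is.null(tol_hz)) {
    # one grid step, evaluated locally at each candidate pair
    step_at <- function(f) {
      k <- vapply(f, function(x) which.min(abs(freqs - x)), integer(1))
      pmax(freqs[pmin(k + 1, length(freqs))] - freqs[k],
           freqs[k] - freqs[pmax(k - 1, 1)])
    }
    cand$tol <- pmax(step_at(pa$peak_hz[cand$i]), step_at(pb$peak_hz[cand$j]))
  } else {
    cand$tol <- tol_hz
  }
  cand <- cand[cand$delta <= cand$tol, , drop = FALSE]
  cand <- cand[order(cand$delta, cand$i, cand$j), , drop = FALSE]
  used_i <- logical(nrow(pa)); used_j <- logical(nrow(pb))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_i[i] && !used_j[j]) {
      keep[r] <- TRUE; used_i[i] <- TRUE; used_j[j] <- TRUE
    }
  }
  m <- cand[keep, , drop = FALSE]
  list(
    matched = tibble(cluster_a = pa$cluster[m$i], cluster_b = pb$cluster[m$j],
                     peak_hz_a = pa$peak_hz[m$i], peak_hz_b = pb$peak_hz[m$j],
                     delta_hz = m$delta),
    unmatched_a = pa[!used_i, , drop = FALSE],
    unmatched_b = pb[!used_j, , drop = FALSE]
  )
}

#' Per-subject amplitude samples of a group cluster
#'
#' Traces a group cluster back to the 1st-level components assigned to it
#' and returns each component's own peak amplitude — one value per
#' contributing component, so subjects may contribute more than one value.
#' These samples feed the condition contrasts.
#'
#' @param model A `group_model`.
#' @param cluster Cluster index.
#' @return Tibble with columns subject and amplitude.
#' @export
mode_amplitude_samples <- function(model, cluster) {
  stopifnot(inherits(model, "group_model"))
  idx <- which(model$assignments == cluster)
  tibble(subject = model$row_subject[idx],
         amplitude = apply(model$rows[idx, , drop = FALSE], 1, max))
}

#' Welch two-sample t test of mode amplitudes
#'
#' Independent-samples t test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), two-sided.
#'
#' @param x,y Amplitude samples for the two conditions (>= 2 each).
#' @return One-row tibble: statistic, df, p_value, mean_x, mean_y.
#' @export
compare_amplitudes <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(x) == 0 && var(y) == 0) {
    abort("Both samples have zero variance; the Welch statistic is undefined.")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Compare matched spectral modes between two conditions
#'
#' Full condition contrast for one area: peaks of both fingerprints are
#' matched by frequency, per-pair amplitude samples are traced back to the
#' contributing 1st-level components, compared by Welch t test, and the
#' family of tests is corrected with the sequential Bonferroni (Holm)
#' procedure.
#'
#' @param model_a,model_b `group_model` objects for the two conditions.
#' @param tol_hz,grid Passed to [match_modes()].
#' @param min_samples Minimum samples per condition for a pair to be tested
#'   (default the model's majority threshold).
#' @param alpha Family-wise significance level (default .05).
#' @return List: `comparison` (tibble pair, peak_hz_a, peak_hz_b, n_a, n_b,
#'   statistic, df, p_value, p_holm, significant), `unmatched_a`,
#'   `unmatched_b`.
#' @export
compare_conditions <- function(model_a, model_b, tol_hz = NULL,
                               grid = build_frequency_grid(),
                               min_samples = NULL, alpha = 0.05) {
  mm <- match_modes(model_a, model_b, tol_hz = tol_hz, grid = grid)
  min_samples <- min_samples %||% min(model_a$majority, model_b$majority)
  rows <- list()
  for (r in seq_len(nrow(mm$matched))) {
    sa <- mode_amplitude_samples(model_a, mm$matched$cluster_a[r])
    sb <- mode_amplitude_samples(model_b, mm$matched$cluster_b[r])
    if (nrow(sa) < max(2, min_samples) || nrow(sb) < max(2, min_samples)) next
    w <- compare_amplitudes(sa$amplitude, sb$amplitude)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(cluster_a = mm$matched$cluster_a[r],
             cluster_b = mm$matched$cluster_b[r],
             peak_hz_a = mm$matched$peak_hz_a[r],
             peak_hz_b = mm$matched$peak_hz_b[r],
             n_a = nrow(sa), n_b = nrow(sb)), w)
  }
  comparison <- dplyr::bind_rows(rows)
  if (nrow(comparison)) {
    hc <- holm_correct(comparison$p_value, alpha = alpha)
    comparison$p_holm <- hc$p_holm
    comparison$significant <- hc$reject
  }
  list(comparison = comparison, unmatched_a = mm$unmatched_a,
       unmatched_b = mm$unmatched_b)
}

#' Sequential Bonferroni (Holm) correction
#'
#' Step-down correction controlling the family-wise error rate: p-values are
#' sorted ascending and the i-th smallest is multiplied by (m - i + 1), with
#' a running maximum enforcing monotonicity and capping at 1.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param alpha Rejection level for the flags (default .05).
#' @return Tibble in the input order: p, p_holm, reject.
#' @export
holm_correct <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  tibble(p = p, p_holm = adj, reject = adj < alpha)
}

#' Spherical coordinates of area centroids
#'
#' Converts Cartesian centroids (cm) to spherical coordinates about an
#' origin: radius `r_cm` (Euclidean distance), elevation in degrees from the
#' axial (xy) plane in \[-90, 90\], and azimuth in degrees from the +x axis
#' in (-180, 180\]. The default origin is the unweighted centroid of all
#' areas, standing in for the centre of the brain.
#'
#' @param centroids Data frame with columns `x_cm`, `y_cm`, `z_cm` (e.g. a
#'   `parcel_table`), or a 3-column matrix.
#' @param origin Length-3 numeric, or `NULL` for the mean centroid.
#' @return Tibble with columns r_cm, elevation_deg, azimuth_deg (plus `name`
#'   if the input had one).
#' @export
spherical_coords <- function(centroids, origin = NULL) {
  if (is.data.frame(centroids)) {
    nm <- centroids[["name"]]
    xyz <- as.matrix(centroids[, c("x_cm", "y_cm", "z_cm")])
  } else {
    nm <- NULL
    xyz <- as.matrix(centroids)
    stopifnot(ncol(xyz) == 3)
  }
  origin <- origin %||% colMeans(xyz)
  rel <- sweep(xyz, 2, origin)
  r <- sqrt(rowSums(rel^2))
  elev <- ifelse(r > 0, asin(pmin(pmax(rel[, 3] / pmax(r, 1e-300), -1), 1)) * 180 / pi, 0)
  azim <- ifelse(r > 0, atan2(rel[, 2], rel[, 1]) * 180 / pi, 0)
  if (any(r == 0)) warn("A centroid coincides with the origin; its angles are set to 0.")
  out <- tibble(r_cm = r, elevation_deg = elev, azimuth_deg = azim)
  if (!is.null(nm)) out <- dplyr::bind_cols(tibble(name = nm), out)
  out
}

#' Regress an area-level metric on one spatial coordinate
#'
#' Ordinary least squares of a per-area metric (mean rank, cluster count,
#' peak frequency, ...) on a single spherical coordinate.
#'
#' @param metric Numeric vector, one value per area (>= 3 areas).
#' @param coordinate Numeric vector of the same length.
#' @param metric_name,coordinate_name Labels for the output row.
#' @return One-row tibble: metric, coordinate, slope, intercept, r_squared,
#'   f_statistic, df1, df2, p_value.
#' @export
regress_metric <- function(metric, coordinate, metric_name = "metric",
                           coordinate_name = "coordinate") {
  stopifnot(length(metric) == length(coordinate), length(metric) >= 3)
  if (var(coordinate) == 0) abort("Coordinate is constant; regression is undefined.")
  fit <- lm(metric ~ coordinate)
  s <- summary(fit)
  tibble(metric = metric_name, coordinate = coordinate_name,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = s$r.squared,
         f_statistic = unname(s$fstatistic[1]),
         df1 = unname(s$fstatistic[2]), df2 = unname(s$fstatistic[3]),
         p_value = stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                             lower.tail = FALSE))
}

#' Regress a metric on all three spherical coordinates
#'
#' Runs [regress_metric()] against radius, elevation and azimuth and
#' Holm-corrects the three p-values jointly.
#'
#' @param metric Numeric vector, one value per area.
#' @param coords Tibble from [spherical_coords()] (same area order).
#' @param metric_name Label.
#' @param alpha Family-wise level for the significance flags.
#' @return Tibble with one row per coordinate, including p_holm and
#'   significant.
#' @export
regress_geometry <- function(metric, coords, metric_name = "metric",
                             alpha = 0.05) {
  out <- dplyr::bind_rows(
    regress_metric(metric, coords$r_cm, metric_name, "r_cm"),
    regress_metric(metric, coords$elevation_deg, metric_name, "elevation_deg"),
    regress_metric(metric, coords$azimuth_deg, metric_name, "azimuth_deg")
  )
  hc <- holm_correct(out$p_value, alpha = alpha)
  out$p_holm <- hc$p_holm
  out$significant <- hc$reject
  out
}
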