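#' Fit a 1st-level (subject-level) spectral model for one area
#'
#' Reduces one subject's segment spectra for one brain area to a compact
#' mixture description: segments are partitioned into `k1 = 10` clusters by
#' cosine-distance k-means (best of 10 restarts, 100 iterations), and the
#' partition initialises a diagonal-covariance Gaussian mixture refined by EM
#' on the raw normalised spectra. Each component's segment fraction — the
#' percentage of segments assigned to it by maximum posterior — carries the
#' time the subject spent in that spectral state.
#'
#' @param power `segments x frequencies` matrix of normalised spectra, or a
#'   one-row `spectra_tbl`.
#' @param k1 Number of 1st-level clusters (default 10).
#' @param seed Optional seed.
#' @param subject,area Labels stored in the model (taken from the
#'   `spectra_tbl` if one is given).
#' @return Object of class `subject_model`: subject, area, `k1`, the
#'   `kmeans_cosine` solution, the refined `gmm_diag`, per-segment
#'   `assignments` and per-component `segment_fraction` (%, sums to 100).
#' @export
fit_subject_model <- function(power, k1 = 10, seed = NULL,
                              subject = NA_character_, area = NA_character_) {
  if (inherits(power, "spectra_tbl") || is.data.frame(power)) {
    stopifnot(nrow(power) == 1)
    subject <- power$subject[1]; area <- power$area[1]
    power <- power$power[[1]]
  }
  power <- as.matrix(power)
  if (nrow(power) < k1) {
    abort(sprintf("Need at least k1 = %d segments; got %d.", k1, nrow(power)))
  }
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1), 2)
  km <- kmeans_cosine(power, k1, n_replicates = 10, max_iter = 100,
                      seed = seeds[1])
  gmm <- fit_gmm_diag(power, km$assignments)
  frac <- 100 * tabulate(gmm$assignments, k1) / nrow(power)
  structure(list(subject = subject, area = area, k1 = k1, kmeans = km,
                 gmm = gmm, assignments = gmm$assignments,
                 segment_fraction = frac, n_segments = nrow(power)),
            class = "subject_model")
}

#' Fit 1st-level models for every subject x area of a spectra table
#'
#' @param x A normalised `spectra_tbl`.
#' @param k1 Clusters per subject model (default 10).
#' @param seed Master seed; per-row seeds are derived from it by subject and
#'   area so results do not depend on row order.
#' @return Tibble with columns subject, area and list-column `model`.
#' @export
fit_subject_models <- function(x, k1 = 10, seed = 1) {
  stopifnot(inherits(x, "spectra_tbl"))
  x <- dplyr::arrange(x, .data$subject, .data$area)
  seeds <- derive_seeds(seed, nrow(x))
  models <- purrr::map(seq_len(nrow(x)), function(i) {
    fit_subject_model(x$power[[i]], k1 = k1, seed = seeds[i],
                      subject = x$subject[i], area = x$area[i])
  })
  tibble(subject = x$subject, area = x$area, model = models)
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("<subject_model> subject %s, area %s: %d segments, k1 = %d\n",
              x$subject, x$area, x$n_segments, x$k1))
  invisible(x)
}
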