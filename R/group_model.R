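#' Chi-square test for a majority of contributing subjects
#'
#' Goodness-of-fit of the observed contributor split against an equal split:
#' with `n_contributing` of `n_total` subjects contributing to a cluster, the
#' statistic is the chi-square over the two cells (contributors,
#' non-contributors) with expectation `n_total / 2` each, on 1 degree of
#' freedom. For 16 of 22 subjects this gives 4.55, p = .03 — the smallest
#' contributor count that is significantly more than half.
#'
#' @param n_contributing,n_total Contributor count and total subject count.
#' @return One-row tibble with `statistic`, `df` and `p_value`.
#' @export
majority_chisq <- function(n_contributing, n_total) {
  stopifnot(n_total >= 2, n_contributing >= 0, n_contributing <= n_total)
  e <- n_total / 2
  stat <- (n_contributing - e)^2 / e + ((n_total - n_contributing) - e)^2 / e
  tibble(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Smallest contributor count that constitutes a significant majority
#'
#' @param n_total Total number of subjects.
#' @param alpha Significance level (default .05).
#' @return Integer: the smallest N with [majority_chisq()] p below `alpha`
#'   (16 for 22 subjects).
#' @export
majority_threshold <- function(n_total, alpha = 0.05) {
  for (n in seq(ceiling(n_total / 2), n_total)) {
    if (majority_chisq(n, n_total)$p_value < alpha) return(as.integer(n))
  }
  as.integer(n_total)
}

#' Select the number of group-level clusters by the silhouette criterion
#'
#' For each candidate k, cosine k-means is run `n_repeats` times from random
#' starts and the mean silhouette width (on the cosine distance matrix) of
#' each solution is averaged over repeats. k = 1 is assigned silhouette 0 by
#' convention. The selected k maximises the mean silhouette, with ties broken
#' toward smaller k; if no candidate exceeds `min_silhouette` the data are
#' treated as unclustered and k = 1 is returned.
#'
#' @param X Pooled observation matrix (e.g. all subjects' 1st-level component
#'   means for one area).
#' @param k_range Candidate cluster numbers (default 1:15).
#' @param n_repeats Random restarts averaged per k (default 1000).
#' @param min_silhouette Acceptance floor for the best silhouette
#'   (default 0.25).
#' @param seed Optional seed.
#' @return List: `k2` (selected), `curve` (tibble k, silhouette),
#'   `n_repeats`, `min_silhouette`.
#' @export
silhouette_select_k <- function(X, k_range = 1:15, n_repeats = 1000,
                                min_silhouette = 0.25, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) abort("Silhouette selection needs at least 2 observations.")
  D <- cosine_dist(X)
  ks <- sort(unique(as.integer(k_range)))
  ks <- ks[ks >= 1 & ks <= n]
  with_seed(seed, {
    sil <- vapply(ks, function(k) {
      if (k == 1) return(0)
      mean(vapply(seq_len(n_repeats), function(r) {
        km <- kmeans_cosine(X, k, n_replicates = 1, max_iter = 100)
        mean_silhouette(km$assignments, D)
      }, numeric(1)))
    }, numeric(1))
    best <- max(sil)
    k2 <- if (best > min_silhouette) ks[which.max(sil)] else 1L
    list(k2 = as.integer(k2), curve = tibble(k = ks, silhouette = sil),
         n_repeats = n_repeats, min_silhouette = min_silhouette)
  })
}

mean_silhouette <- function(assignments, D) {
  if (length(unique(assignments)) < 2) return(0)
  s <- cluster::silhouette(assignments, dmatrix = D)
  mean(s[, "sil_width"])
}

#' Fit a 2nd-level (group-level) spectral fingerprint for one area
#'
#' Pools the 1st-level Gaussian component means of all subjects for one area
#' (`n_subjects x k1` rows in spectral space) and clusters them with cosine
#' k-means at `k2` clusters, refined into a diagonal Gaussian mixture by EM —
#' the area's spectral fingerprint. A subject contributes to a group cluster
#' if at least one of its component rows lands there under maximum posterior;
#' clusters reaching the majority threshold (default: smallest significant
#' majority of subjects, 16 of 22) are flagged stable. Each cluster's
#' duration is the mean, over its contributing subjects, of the summed
#' segment fractions of their contributing components; because subjects
#' contribute to several clusters, durations may cumulate above 100%.
#'
#' @param subject_models List of `subject_model` objects for one area, or a
#'   tibble with a `model` list-column (as from [fit_subject_models()],
#'   filtered to one area).
#' @param k2 Number of group clusters (e.g. from [silhouette_select_k()]).
#' @param majority Contributor count required for stability; default
#'   [majority_threshold()] of the subject count.
#' @param seed Optional seed.
#' @return Object of class `group_model`: area, `k2`, the refined `gmm_diag`,
#'   pooled `rows` with their subject labels and `assignments`, and a
#'   `clusters` tibble (cluster, weight, n_contributing, stable, duration).
#' @export
fit_group_model <- function(subject_models, k2, majority = NULL, seed = NULL) {
  models <- as_model_list(subject_models)
  if (length(models) < 2) abort("Need at least 2 subjects.")
  models <- models[order(vapply(models, function(m) m$subject, character(1)))]
  area <- models[[1]]$area
  subjects <- vapply(models, function(m) m$subject, character(1))
  rows <- do.call(rbind, lapply(models, function(m) m$gmm$means))
  row_subject <- rep(subjects, vapply(models, function(m) as.integer(m$k1), integer(1)))
  row_fraction <- unlist(lapply(models, function(m) m$segment_fraction))
  if (k2 > nrow(rows)) {
    abort(sprintf("k2 = %d exceeds the %d pooled component rows.", k2, nrow(rows)))
  }
  majority <- majority %||% majority_threshold(length(models))
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1), 1)
  km <- kmeans_cosine(rows, k2, n_replicates = 10, max_iter = 100, seed = seeds[1])
  gmm <- fit_gmm_diag(rows, km$assignments)
  assign <- gmm$assignments
  k_eff <- gmm$k
  contrib <- integer(k_eff); duration <- numeric(k_eff)
  for (j in seq_len(k_eff)) {
    in_j <- assign == j
    subs <- unique(row_subject[in_j])
    contrib[j] <- length(subs)
    if (length(subs)) {
      duration[j] <- mean(vapply(subs, function(s) {
        sum(row_fraction[in_j & row_subject == s])
      }, numeric(1)))
    }
  }
  structure(list(
    area = area, k2 = as.integer(k2), gmm = gmm,
    rows = rows, row_subject = row_subject, row_fraction = row_fraction,
    assignments = assign, n_subjects = length(models), majority = majority,
    clusters = tibble(cluster = seq_len(k_eff), weight = gmm$weights,
                      n_contributing = contrib,
                      stable = contrib >= majority, duration = duration)
  ), class = "group_model")
}

as_model_list <- function(x) {
  if (inherits(x, "subject_model")) return(list(x))
  if (is.data.frame(x)) {
    if (length(unique(x$area)) > 1) {
      abort("Subject models span several areas; filter to one area first.")
    }
    return(x$model)
  }
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "subject_model")))
  x
}

#' Cluster-mean spectra of a fingerprint
#'
#' @param model A `group_model`.
#' @return `k x frequencies` matrix of group-cluster mean spectra.
#' @export
profile_spectra <- function(model) {
  stopifnot(inherits(model, "group_model"))
  model$gmm$means
}

#' Fit fingerprints for every area of a study
#'
#' Convenience wrapper running [silhouette_select_k()] (unless `k2` is fixed)
#' and [fit_group_model()] for each area over a table of 1st-level models.
#'
#' @param subject_models Tibble from [fit_subject_models()].
#' @param k2 Fixed cluster number, or `NULL` to select per area by
#'   silhouette.
#' @param k_range,n_repeats Passed to [silhouette_select_k()].
#' @param majority Stability threshold (default [majority_threshold()]).
#' @param seed Master seed.
#' @return Tibble with columns area, k2 and list-columns `model`
#'   (`group_model`) and `silhouette` (selection curve or `NULL`).
#' @export
fit_fingerprints <- function(subject_models, k2 = NULL, k_range = 1:15,
                             n_repeats = 1000, majority = NULL, seed = 1) {
  areas <- sort(unique(subject_models$area))
  seeds <- derive_seeds(seed, 2L * length(areas))
  out <- purrr::map(seq_along(areas), function(i) {
    sm <- subject_models[subject_models$area == areas[i], ]
    sil <- NULL
    kk <- k2
    if (is.null(kk)) {
      pooled <- do.call(rbind, lapply(sm$model, function(m) m$gmm$means))
      sil <- silhouette_select_k(pooled, k_range = k_range,
                                 n_repeats = n_repeats, seed = seeds[2 * i - 1])
      kk <- sil$k2
    }
    gm <- fit_group_model(sm, k2 = kk, majority = majority, seed = seeds[2 * i])
    tibble(area = areas[i], k2 = kk, model = list(gm), silhouette = list(sil))
  })
  dplyr::bind_rows(out)
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model> area %s: k2 = %d, %d subjects, %d stable cluster(s)\n",
              x$area, x$k2, x$n_subjects, sum(x$clusters$stable)))
  print(x$clusters)
  invisible(x)
}
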