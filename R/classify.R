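#' Random split-half of subjects
#'
#' @param subject_ids Character or integer vector of subject identifiers
#'   (>= 4 subjects).
#' @param seed Optional seed; the same seed reproduces the same split.
#' @return List with disjoint `train` (size `ceiling(n/2)`) and `test`
#'   (size `floor(n/2)`).
#' @export
split_half <- function(subject_ids, seed = NULL) {
  n <- length(subject_ids)
  if (n < 4) abort("Split-half classification needs at least 4 subjects.")
  with_seed(seed, {
    perm <- sample(subject_ids)
    n_train <- ceiling(n / 2)
    list(train = perm[seq_len(n_train)], test = perm[-seq_len(n_train)])
  })
}

#' Rank of the correct area among candidate models
#'
#' Areas are sorted by ascending negative log-likelihood of the test data;
#' the correct area's position is its rank (1 = best fit). Ties receive
#' midranks.
#'
#' @param nlls Named numeric vector of NLL scores, one per candidate area.
#' @param correct Name(s) of the area(s) counted as correct; with several
#'   (e.g. an area and its homologue) the minimum rank is returned.
#' @return Numeric rank in `[1, length(nlls)]`.
#' @export
rank_area <- function(nlls, correct) {
  stopifnot(!is.null(names(nlls)), all(correct %in% names(nlls)))
  r <- rank(nlls, ties.method = "average")
  min(r[correct])
}

#' Split-half classification of brain areas by spectral fingerprint
#'
#' Tests whether areas can be identified from their spectral fingerprints
#' alone. Per iteration: subjects are split into a training and a test half;
#' a group model with a fixed number of clusters `k_train` is fitted to every
#' area from the training half; each area's test data — the pooled 1st-level
#' component means of the test subjects — are scored against every area's
#' training model by negative log-likelihood, and the correct area's rank is
#' recorded. `k_train` is held constant across areas so likelihoods are
#' comparable (a varying cluster number would bias the NLL). Ranks are
#' aggregated as the 20% trimmed mean over all areas and iterations; a
#' homologue-aware variant also counts the contralateral partner as correct
#' (taking the smaller of the two ranks).
#'
#' @param subject_models Tibble from [fit_subject_models()] covering >= 2
#'   areas and >= 4 subjects.
#' @param n_iterations Number of random splits (default 120).
#' @param k_train Fixed group-cluster number for training models (default 4,
#'   the modal optimal cluster number).
#' @param trim Total trimming fraction for the trimmed mean (default 0.20,
#'   i.e. 10% in each tail).
#' @param homologue Named character vector mapping areas to their
#'   contralateral partners (see [homologue_map()]), or `NULL`.
#' @param seed Master seed; per-iteration seeds are derived from it and
#'   recorded.
#' @return Object of class `classification_result`: `ranks` (tibble area,
#'   iteration, rank, rank_homologue), `trimmed_mean_rank`,
#'   `trimmed_mean_rank_homologue`, the parameters and iteration seeds.
#' @export
run_classification <- function(subject_models, n_iterations = 120,
                               k_train = 4, trim = 0.20, homologue = NULL,
                               seed = 1) {
  areas <- sort(unique(subject_models$area))
  subjects <- sort(unique(subject_models$subject))
  if (length(areas) < 2) abort("Classification needs at least 2 areas.")
  if (length(subjects) < 4) abort("Classification needs at least 4 subjects.")
  iter_seeds <- derive_seeds(seed, n_iterations)
  res <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    sub_seeds <- derive_seeds(iter_seeds[it], 1 + length(areas))
    halves <- split_half(subjects, seed = sub_seeds[1])
    models <- purrr::map(seq_along(areas), function(i) {
      sm <- subject_models[subject_models$area == areas[i] &
                             subject_models$subject %in% halves$train, ]
      fit_group_model(sm, k2 = k_train, seed = sub_seeds[1 + i])
    })
    names(models) <- areas
    test_rows <- purrr::map(areas, function(a) {
      sm <- subject_models[subject_models$area == a &
                             subject_models$subject %in% halves$test, ]
      do.call(rbind, lapply(sm$model, function(m) m$gmm$means))
    })
    names(test_rows) <- areas
    res[[it]] <- dplyr::bind_rows(lapply(areas, function(a) {
      nlls <- vapply(areas, function(b) nll_score(models[[b]], test_rows[[a]]),
                     numeric(1))
      correct <- a
      hom <- if (!is.null(homologue) && a %in% names(homologue)) {
        intersect(unname(homologue[a]), areas)
      } else character(0)
      tibble(area = a, iteration = it,
             rank = rank_area(nlls, correct),
             rank_homologue = rank_area(nlls, c(correct, hom)))
    }))
  }
  ranks <- dplyr::bind_rows(res)
  structure(list(
    ranks = ranks,
    trimmed_mean_rank = mean(ranks$rank, trim = trim / 2),
    trimmed_mean_rank_homologue = mean(ranks$rank_homologue, trim = trim / 2),
    n_iterations = n_iterations, k_train = k_train, trim = trim,
    n_areas = length(areas), iteration_seeds = iter_seeds, seed = seed
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> %d areas, %d iterations, k_train = %d\n",
    x$n_areas, x$n_iterations, x$k_train))
  cat(sprintf("  %.0f%% trimmed mean rank: %.3f (homologue-aware: %.3f)\n",
              100 * x$trim, x$trimmed_mean_rank, x$trimmed_mean_rank_homologue))
  invisible(x)
}
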