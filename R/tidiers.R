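#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn fit_subject_model One row per mixture component: weight and
#'   segment fraction.
#' @param x Fitted object.
#' @param ... Unused.
#' @export
tidy.subject_model <- function(x, ...) {
  tibble(subject = x$subject, area = x$area,
         component = seq_len(x$k1), weight = x$gmm$weights,
         segment_fraction = x$segment_fraction)
}

#' @describeIn fit_subject_model One-row model summary.
#' @export
glance.subject_model <- function(x, ...) {
  tibble(subject = x$subject, area = x$area, k1 = x$k1,
         n_segments = x$n_segments,
         loglik = x$gmm$loglik[length(x$gmm$loglik)],
         em_iterations = length(x$gmm$loglik))
}

#' @describeIn fit_group_model One row per group cluster: weight,
#'   contributor count, stability flag and duration.
#' @param x Fitted object.
#' @param ... Unused.
#' @export
tidy.group_model <- function(x, ...) {
  dplyr::bind_cols(tibble(area = x$area), x$clusters)
}

#' @describeIn fit_group_model One-row fingerprint summary.
#' @export
glance.group_model <- function(x, ...) {
  tibble(area = x$area, k2 = x$k2, n_subjects = x$n_subjects,
         n_stable = sum(x$clusters$stable),
         cumulative_duration = sum(x$clusters$duration),
         loglik = x$gmm$loglik[length(x$gmm$loglik)])
}

#' @describeIn run_classification Per-area mean ranks over iterations.
#' @param x Fitted object.
#' @param ... Unused.
#' @export
tidy.classification_result <- function(x, ...) {
  x$ranks |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(mean_rank = mean(.data$rank),
                     mean_rank_homologue = mean(.data$rank_homologue),
                     .groups = "drop")
}

#' @describeIn run_classification One-row summary with the trimmed means.
#' @export
glance.classification_result <- function(x, ...) {
  tibble(n_areas = x$n_areas, n_iterations = x$n_iterations,
         k_train = x$k_train, trim = x$trim,
         trimmed_mean_rank = x$trimmed_mean_rank,
         trimmed_mean_rank_homologue = x$trimmed_mean_rank_homologue)
}

#' @describeIn cluster_areas Area cluster membership at the cut.
#' @param x Fitted object.
#' @param ... Unused.
#' @export
tidy.similarity_tree <- function(x, ...) {
  tibble(area = names(x$labels), cluster = unname(x$labels))
}
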