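#' Plot a fingerprint's cluster-mean spectra
#'
#' One line per group cluster on a logarithmic frequency axis, labelled with
#' the cluster's duration; unstable clusters are drawn dashed.
#'
#' @param object A `group_model`.
#' @param grid Frequency grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_model <- function(object, grid = build_frequency_grid(), ...) {
  freqs <- grid_freqs(grid)
  sp <- profile_spectra(object)
  df <- dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(j) {
    tibble(freq_hz = freqs, power = sp[j, ],
           cluster = sprintf("mode %d (%.0f%%)", j, object$clusters$duration[j]),
           stable = object$clusters$stable[j])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$power,
                                   colour = .data$cluster,
                                   linetype = .data$stable)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "frequency (Hz)", y = "normalised power (ratio - 1)",
                  colour = NULL,
                  title = sprintf("Spectral fingerprint: %s", object$area)) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of classification mean ranks
#'
#' Histogram of per-area mean ranks, with the trimmed mean marked.
#'
#' @param object A `classification_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classification_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_rank)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0.5,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$trimmed_mean_rank,
                        linetype = "dashed") +
    ggplot2::labs(x = "mean rank", y = "areas",
                  title = sprintf("Area classification (trimmed mean rank %.2f)",
                                  object$trimmed_mean_rank)) +
    ggplot2::theme_minimal()
}

#' Plot a silhouette model-selection curve
#'
#' @param selection Result of [silhouette_select_k()].
#' @return A ggplot object.
#' @export
plot_silhouette_curve <- function(selection) {
  df <- selection$curve
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = selection$k2, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette",
                  title = sprintf("Silhouette selection (k2 = %d)", selection$k2)) +
    ggplot2::theme_minimal()
}

#' @export
plot.similarity_tree <- function(x, ...) {
  plot(x$hclust, ylab = "cosine distance between NLL profiles",
       xlab = "", sub = "", main = "Area similarity (UPGMA)", ...)
  invisible(x)
}
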