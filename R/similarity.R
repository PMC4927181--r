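#' Cross-fit negative log-likelihood profiles between areas
#'
#' Entry (a, b) is the per-row negative log-likelihood of area b's pooled
#' 1st-level component rows under area a's fingerprint model. Row a of the
#' matrix is area a's "NLL profile": how well its model explains every
#' area's data. These profiles are the feature vectors for the similarity
#' clustering of areas.
#'
#' @param models Named list of `group_model` objects (or a tibble with
#'   columns `area` and `model`).
#' @param data_rows Named list of observation matrices, one per area (pooled
#'   subject component means), with the same area names.
#' @return `A x A` numeric matrix with area dimnames.
#' @export
nll_profile_matrix <- function(models, data_rows) {
  if (is.data.frame(models)) {
    models <- setNames(models$model, models$area)
  }
  areas <- names(models)
  if (is.null(areas) || !setequal(areas, names(data_rows))) {
    abort("`models` and `data_rows` must be named by the same areas.")
  }
  M <- matrix(NA_real_, length(areas), length(areas),
              dimnames = list(model = areas, data = areas))
  for (a in areas) {
    for (b in areas) {
      M[a, b] <- nll_score(models[[a]], data_rows[[b]], average = TRUE)
    }
  }
  M
}

#' Hierarchical similarity clustering of areas
#'
#' Clusters areas by the similarity of their spectral fingerprints: the
#' distance between two areas is the cosine distance between their NLL
#' profile rows (see [nll_profile_matrix()]), agglomerated with the
#' unweighted average-linkage (UPGMA) method into a dendrogram, which is cut
#' at `max_clusters` groups.
#'
#' @param M Square NLL profile matrix.
#' @param max_clusters Cut level (default 20); capped at the number of areas.
#' @return Object of class `similarity_tree`: `distance` (area x area cosine
#'   distance), `hclust`, `labels` (cluster membership at the cut),
#'   `max_clusters`.
#' @export
cluster_areas <- function(M, max_clusters = 20) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) abort("NLL profile matrix must be square.")
  areas <- rownames(M) %||% paste0("area", seq_len(nrow(M)))
  D <- cosine_dist(M)
  dimnames(D) <- list(areas, areas)
  hc <- hclust(as.dist(D), method = "average")
  k <- min(max_clusters, nrow(M))
  labels <- cutree(hc, k = k)
  structure(list(distance = D, hclust = hc, labels = labels,
                 max_clusters = max_clusters),
            class = "similarity_tree")
}

#' Export a similarity dendrogram as newick
#'
#' @param tree A `similarity_tree`.
#' @param path Output file.
#' @export
export_newick <- function(tree, path) {
  stopifnot(inherits(tree, "similarity_tree"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Package 'ape' is required for newick export.")
  }
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}

#' @export
print.similarity_tree <- function(x, ...) {
  cat(sprintf("<similarity_tree> %d areas, cut into %d cluster(s)\n",
              nrow(x$distance), length(unique(x$labels))))
  invisible(x)
}

#' Rand index between two labelings
#'
#' Fraction of object pairs on which two partitions agree (both together or
#' both apart); 1 = identical partitions. Used to compare a dendrogram cut
#' against ground-truth area families.
#'
#' @param a,b Two label vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  pairs <- utils::combn(length(a), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}
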