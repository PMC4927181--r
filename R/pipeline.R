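#' Build a validated pipeline configuration
#'
#' Collects every tunable of the fingerprinting pipeline with its default:
#' `k1 = 10` 1st-level clusters, silhouette selection over `k_range = 1:15`
#' with `silhouette_repeats` restarts, the majority stability threshold
#' (`NULL` = smallest significant majority), `n_iterations = 120` split-half
#' classification iterations at fixed `k_train = 4` with 20% total trimming,
#' and a similarity dendrogram cut at `max_clusters = 20`. A master `seed` is
#' mandatory; every stochastic stage draws a child seed from it.
#'
#' @param seed Master seed (required).
#' @param input Path to a spectra container, or `NULL` to simulate.
#' @param simulate Arguments for [make_truth()] (list) used when `input` is
#'   `NULL`.
#' @param stages Character subset of c("fit", "classify", "similarity").
#' @param k1,k_range,silhouette_repeats,majority,n_iterations,k_train,trim,max_clusters
#'   Stage parameters, as above.
#' @param homologue Named homologue vector for classification, or `NULL`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, input = NULL, simulate = list(),
                            stages = c("fit", "classify", "similarity"),
                            k1 = 10, k_range = 1:15, silhouette_repeats = 1000,
                            majority = NULL, n_iterations = 120, k_train = 4,
                            trim = 0.20, max_clusters = 20, homologue = NULL) {
  if (missing(seed) || is.null(seed)) abort("A master seed is mandatory.")
  stopifnot(k1 >= 1, all(k_range >= 1), silhouette_repeats >= 1,
            n_iterations >= 1, k_train >= 1, trim >= 0, trim < 1,
            max_clusters >= 1)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(seed = as.integer(seed), input = input, simulate = simulate,
                 stages = stages, k1 = k1, k_range = k_range,
                 silhouette_repeats = silhouette_repeats, majority = majority,
                 n_iterations = n_iterations, k_train = k_train, trim = trim,
                 max_clusters = max_clusters, homologue = homologue),
            class = "pipeline_config")
}

#' Run the fingerprinting pipeline end to end
#'
#' Executes the stages in pipeline order — load or simulate normalised area
#' spectra, fit 1st-level subject models, fit silhouette-selected 2nd-level
#' fingerprints, then optionally split-half classification and area
#' similarity clustering — and writes every result table as CSV into
#' `out_dir`, together with a `log.json` recording all parameters, child
#' seeds and a content hash of the configuration. Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results (spectra,
#'   subject_models, fingerprints, classification, similarity).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- build_frequency_grid()
  seeds <- derive_seeds(config$seed, 4)

  if (!is.null(config$input)) {
    if (!dir.exists(config$input)) {
      abort(sprintf("Input container '%s' does not exist.", config$input))
    }
    spectra <- read_spectra_container(config$input)
  } else {
    truth <- do.call(make_truth, c(config$simulate, list(seed = seeds[1])))
    gen <- generate_spectra(truth, grid)
    spectra <- gen$spectra
    write_spectra_container(spectra, file.path(out_dir, "spectra"),
                            states = gen$states, truth = truth)
  }
  n_seg <- min(vapply(spectra$power, nrow, integer(1)))
  if (config$k1 > n_seg) {
    abort(sprintf("k1 = %d exceeds the smallest segment count (%d).",
                  config$k1, n_seg))
  }

  subject_models <- fit_subject_models(spectra, k1 = config$k1, seed = seeds[2])
  results <- list(spectra = spectra, subject_models = subject_models)

  if ("fit" %in% config$stages) {
    fp <- fit_fingerprints(subject_models, k_range = config$k_range,
                           n_repeats = config$silhouette_repeats,
                           majority = config$majority, seed = seeds[3])
    results$fingerprints <- fp
    modes <- dplyr::bind_rows(lapply(seq_len(nrow(fp)), function(i) {
      pk <- profile_peaks(fp$model[[i]], grid)
      dplyr::bind_cols(tibble(area = fp$area[i], k2 = fp$k2[i]), pk)
    }))
    write.csv(modes, file.path(out_dir, "modes.csv"), row.names = FALSE)
  }

  if ("classify" %in% config$stages) {
    cl <- run_classification(subject_models, n_iterations = config$n_iterations,
                             k_train = config$k_train, trim = config$trim,
                             homologue = config$homologue, seed = seeds[4])
    results$classification <- cl
    write.csv(tidy(cl), file.path(out_dir, "classification.csv"),
              row.names = FALSE)
  }

  if ("similarity" %in% config$stages) {
    fp <- results$fingerprints
    if (is.null(fp)) abort("Similarity stage requires the fit stage.")
    rows_by_area <- lapply(setNames(fp$area, fp$area), function(a) {
      sm <- subject_models[subject_models$area == a, ]
      do.call(rbind, lapply(sm$model, function(m) m$gmm$means))
    })
    M <- nll_profile_matrix(fp, rows_by_area)
    tree <- cluster_areas(M, max_clusters = config$max_clusters)
    results$similarity <- tree
    write.csv(tibble(area = names(tree$labels), cluster = unname(tree$labels)),
              file.path(out_dir, "similarity_clusters.csv"), row.names = FALSE)
    if (requireNamespace("ape", quietly = TRUE)) {
      export_newick(tree, file.path(out_dir, "similarity.nwk"))
    }
  }

  log <- list(
    config = unclass(config[setdiff(names(config), "homologue")]),
    config_hash = rlang::hash(unclass(config)),
    child_seeds = seeds,
    parameters = list(k1 = config$k1, kmeans_replicates = 10,
                      kmeans_max_iter = 100,
                      silhouette_k_range = range(config$k_range),
                      silhouette_repeats = config$silhouette_repeats,
                      majority = config$majority %||%
                        majority_threshold(length(unique(spectra$subject))),
                      n_subjects = length(unique(spectra$subject)),
                      classification_iterations = config$n_iterations,
                      k_train = config$k_train, trim = config$trim,
                      similarity_max_clusters = config$max_clusters)
  )
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
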