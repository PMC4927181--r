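#' Write a spectra table to a plain-text container
#'
#' The on-disk container is a directory holding `meta.json` (subjects, areas,
#' frequency grid, normalisation flag, segment counts) and one CSV per
#' subject (`power_<subject>.csv` with columns area, segment and one column
#' per grid frequency). Per-subject files keep reads memory-bounded: one
#' subject can be loaded at a time. Optional sidecars: `states.csv` (hidden
#' mode labels of synthetic data) and `truth.json` (the full generating
#' truth).
#'
#' @param x A `spectra_tbl`.
#' @param dir Output directory (created if missing).
#' @param states Optional tibble of hidden state labels.
#' @param truth Optional `synthetic_truth` to record alongside.
#' @return `dir`, invisibly.
#' @export
write_spectra_container <- function(x, dir, states = NULL, truth = NULL) {
  stopifnot(inherits(x, "spectra_tbl"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- attr(x, "freqs")
  subjects <- unique(x$subject)
  meta <- list(
    subjects = subjects,
    areas = unique(x$area),
    freqs = freqs,
    normalised = is_normalised(x),
    n_segments = lapply(split(vapply(x$power, nrow, integer(1)), x$subject),
                        unname)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  fcols <- sprintf("f%05.1f", freqs)
  for (s in subjects) {
    xs <- x[x$subject == s, ]
    df <- dplyr::bind_rows(lapply(seq_len(nrow(xs)), function(i) {
      p <- xs$power[[i]]
      colnames(p) <- fcols
      dplyr::bind_cols(tibble(area = xs$area[i], segment = seq_len(nrow(p))),
                       as_tibble(p))
    }))
    write.csv(df, file.path(dir, paste0("power_", s, ".csv")), row.names = FALSE)
  }
  if (!is.null(states)) {
    write.csv(states, file.path(dir, "states.csv"), row.names = FALSE)
  }
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(modes = truth$modes,
           params = truth[setdiff(names(truth), "modes")]),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a spectra container
#'
#' @param dir Container directory written by [write_spectra_container()].
#' @param subjects Subset of subjects to load (default all); loading one
#'   subject at a time bounds memory for large studies.
#' @return A `spectra_tbl`.
#' @export
read_spectra_container <- function(dir, subjects = NULL) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) abort(sprintf("No meta.json in '%s'.", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  needed <- c("subjects", "areas", "freqs", "normalised")
  missing <- setdiff(needed, names(meta))
  if (length(missing)) {
    abort(paste0("Container schema is missing fields: ",
                 paste(missing, collapse = ", ")))
  }
  subjects <- subjects %||% meta$subjects
  rows <- list(); subj <- character(0); area <- character(0)
  for (s in subjects) {
    path <- file.path(dir, paste0("power_", s, ".csv"))
    if (!file.exists(path)) abort(sprintf("Missing container file '%s'.", path))
    df <- read.csv(path, check.names = FALSE)
    fcols <- setdiff(names(df), c("area", "segment"))
    for (a in unique(df$area)) {
      block <- df[df$area == a, , drop = FALSE]
      block <- block[order(block$segment), , drop = FALSE]
      m <- as.matrix(block[, fcols, drop = FALSE])
      dimnames(m) <- NULL
      rows <- c(rows, list(m)); subj <- c(subj, s); area <- c(area, a)
    }
  }
  new_spectra_tbl(tibble(subject = subj, area = area, power = rows),
                  meta$freqs, meta$normalised)
}

#' Read the hidden-state sidecar of a synthetic container
#'
#' @param dir Container directory.
#' @return Tibble subject, area, segment, mode.
#' @export
read_container_states <- function(dir) {
  path <- file.path(dir, "states.csv")
  if (!file.exists(path)) abort(sprintf("No states.csv in '%s'.", dir))
  as_tibble(read.csv(path))
}
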