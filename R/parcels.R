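#' Read a parcel (atlas) table
#'
#' A parcel table lists the brain areas of a parcellation with one row per
#' area: `name`, `hemisphere` ("L", "R" or "M" for unpaired midline
#' structures), `homologue` (the name of the corresponding area in the other
#' hemisphere, or empty), and a centroid in Cartesian cm (`x_cm`, `y_cm`,
#' `z_cm`). The homologue relation must be symmetric.
#'
#' @param path CSV file with columns name, hemisphere, homologue, x_cm, y_cm,
#'   z_cm.
#' @return A tibble of class `parcel_table`.
#' @export
read_parcel_table <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  needed <- c("name", "hemisphere", "homologue", "x_cm", "y_cm", "z_cm")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(paste0("Parcel table is missing columns: ", paste(missing, collapse = ", ")))
  }
  df$homologue[is.na(df$homologue)] <- ""
  if (anyDuplicated(df$name)) abort("Parcel names must be unique.")
  paired <- df[df$homologue != "", ]
  back <- setNames(paired$homologue, paired$name)
  for (nm in names(back)) {
    partner <- back[[nm]]
    if (!partner %in% df$name || !identical(unname(back[partner]), nm)) {
      abort(sprintf("Homologue relation is not symmetric for '%s'.", nm))
    }
  }
  class(df) <- c("parcel_table", class(df))
  df
}

#' Packaged 115-area parcel table (synthetic centroids)
#'
#' The default atlas table shipped with the package: the 116 areas of the AAL
#' parcellation minus Cerebelum_3_L, yielding 115 areas — the area set used
#' for whole-brain fingerprinting. Names, hemisphere labels and left/right
#' homologue pairing follow the AAL naming scheme; the centroid coordinates
#' are synthetic (plausible head-frame positions in cm, generated once with a
#' fixed seed), suitable for exercising the spherical-coordinate geometry
#' analyses but not for anatomical localisation.
#'
#' @return A `parcel_table` tibble with 115 rows.
#' @export
aal_parcels <- function() {
  read_parcel_table(system.file("extdata", "aal115_parcels_synthetic.csv",
                                package = "specfp", mustWork = TRUE))
}

#' Homologue lookup from a parcel table
#'
#' @param parcels A `parcel_table`.
#' @return Named character vector mapping each paired area to its homologue.
#' @export
homologue_map <- function(parcels) {
  paired <- parcels[parcels$homologue != "", ]
  setNames(paired$homologue, paired$name)
}
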