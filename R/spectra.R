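#' Cut a continuous signal into fixed-length segments
#'
#' Splits a continuous single- or multi-channel recording into consecutive,
#' non-overlapping segments of `seg_len_s` seconds (1 s by default, the
#' segment length used for single-segment spectral estimation). Any trailing
#' remainder shorter than one segment is dropped.
#'
#' @param x Numeric vector (one channel) or matrix with samples in rows and
#'   channels in columns.
#' @param fs Sampling rate in Hz.
#' @param seg_len_s Segment duration in seconds.
#' @return For a vector input, a `segments x samples` matrix; for a matrix
#'   input, a `segments x samples x channels` array.
#' @export
segment_signal <- function(x, fs, seg_len_s = 1) {
  stopifnot(is.numeric(fs), fs > 0, seg_len_s > 0)
  seg_n <- as.integer(round(seg_len_s * fs))
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(xm)
  if (n < seg_n) {
    abort(sprintf("Signal (%d samples) is shorter than one %g-s segment (%d samples).",
                  n, seg_len_s, seg_n))
  }
  n_seg <- n %/% seg_n
  idx <- seq_len(n_seg * seg_n)
  out <- array(NA_real_, dim = c(n_seg, seg_n, ncol(xm)))
  for (ch in seq_len(ncol(xm))) {
    out[, , ch] <- matrix(xm[idx, ch], nrow = n_seg, ncol = seg_n, byrow = TRUE)
  }
  if (!is.matrix(x)) out <- out[, , 1, drop = TRUE]
  if (is.null(dim(out))) out <- matrix(out, nrow = n_seg)
  out
}

#' Single-pass z-score rejection of artefactual items
#'
#' Flags items (channels or segments) whose summary value lies more than
#' `z_threshold` standard deviations above the mean of all items. The z-score
#' uses the population standard deviation (denominator n) and is computed once
#' over all items — rejection is not iterated. With zero variance nothing is
#' rejected.
#'
#' @param values Per-item scalar summaries (e.g. per-channel signal variance);
#'   at least 2 items.
#' @param z_threshold Positive rejection threshold; an item is rejected iff
#'   its z-score strictly exceeds it. Conventional values: 1.5 for channels,
#'   2 for segments.
#' @return A list with integer index vectors `kept` and `rejected`, and the
#'   z-scores `z`.
#' @export
reject_outliers <- function(values, z_threshold) {
  stopifnot(is.numeric(values), length(values) >= 2,
            is.numeric(z_threshold), z_threshold > 0)
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) {
    z <- rep(0, length(values))
  } else {
    z <- (values - mu) / sigma
  }
  rejected <- which(z > z_threshold)
  list(kept = setdiff(seq_along(values), rejected), rejected = rejected, z = z)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem. Tapers
#' are normalised to unit energy; symmetric tapers are signed to have positive
#' mean and antisymmetric ones to start positive.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 2: a 1-s segment smoothed over
#'   +/- 2 Hz).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An `n x k` matrix, one taper per column, ordered by decreasing
#'   spectral concentration.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- t[-1] * (n - t[-1]) / 2
  tri <- matrix(0, n, n)
  tri[cbind(t + 1, t + 1)] <- diag_main
  tri[cbind(1:(n - 1), 2:n)] <- diag_off
  tri[cbind(2:n, 1:(n - 1))] <- diag_off
  eig <- eigen(tri, symmetric = TRUE)
  tapers <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    if (abs(sum(v)) > 1e-8) {
      if (sum(v) < 0) v <- -v          # symmetric: positive mean
    } else if (v[which(abs(v) > 1e-12)[1]] < 0) {
      v <- -v                          # antisymmetric: positive onset
    }
    tapers[, j] <- v
  }
  tapers
}

#' Multitaper power spectrum of a single 1-s segment
#'
#' Estimates power at the grid frequencies from one 1-s segment: the segment
#' is demeaned, multiplied with each of 3 DPSS tapers (time-bandwidth 2, i.e.
#' +/- 2 Hz smoothing), zero-padded to 2 s, Fourier transformed, and the
#' squared magnitudes are averaged over tapers. Zero-padding puts the FFT bins
#' on a 0.5-Hz lattice, on which every grid frequency falls exactly.
#'
#' @param segment Numeric vector, one 1-s segment (length = `fs` samples).
#' @param fs Sampling rate in Hz; must be at least 240 so that 120 Hz is
#'   resolvable.
#' @param grid A [build_frequency_grid()] tibble or numeric frequency vector.
#' @return Numeric vector of non-negative power values, one per grid
#'   frequency (arbitrary units).
#' @seealso [multitaper_spectra()] for many segments at once.
#' @export
segment_spectrum <- function(segment, fs, grid = build_frequency_grid()) {
  out <- multitaper_spectra(matrix(segment, nrow = 1), fs, grid)
  out[1, ]
}

#' Multitaper power spectra for a set of segments
#'
#' Vectorised form of [segment_spectrum()]: one row per segment.
#'
#' @param segments Matrix `segments x samples`, each row one 1-s segment.
#' @param fs Sampling rate in Hz (>= 240).
#' @param grid Frequency grid (see [build_frequency_grid()]).
#' @return Matrix `segments x frequencies` of non-negative power.
#' @export
multitaper_spectra <- function(segments, fs, grid = build_frequency_grid()) {
  stopifnot(is.matrix(segments) || is.numeric(segments))
  if (!is.matrix(segments)) segments <- matrix(segments, nrow = 1)
  freqs <- grid_freqs(grid)
  if (fs < 2 * max(freqs)) {
    abort(sprintf("Sampling rate %g Hz cannot represent %g Hz; need fs >= %g.",
                  fs, max(freqs), 2 * max(freqs)))
  }
  n <- ncol(segments)
  n_pad <- 2L * as.integer(fs)          # zero-pad 1 s -> 2 s: 0.5-Hz bins
  bins <- as.integer(round(freqs * 2)) + 1L
  if (any(bins > n_pad %/% 2 + 1L)) {
    abort("Frequency grid exceeds the Nyquist frequency of the padded FFT.")
  }
  tapers <- dpss_tapers(n, nw = 2, k = 3)
  segs <- segments - rowMeans(segments)  # offsets carry no power above 0 Hz
  power <- matrix(0, nrow(segments), length(freqs))
  for (j in seq_len(ncol(tapers))) {
    tap <- segs * matrix(tapers[, j], nrow(segs), n, byrow = TRUE)
    padded <- cbind(tap, matrix(0, nrow(segs), n_pad - n))
    sp <- t(stats::mvfft(t(padded)))
    power <- power + abs(sp[, bins, drop = FALSE])^2
  }
  power / ncol(tapers)
}

new_spectra_tbl <- function(df, freqs, normalised) {
  stopifnot(all(c("subject", "area", "power") %in% names(df)))
  out <- as_tibble(df)
  attr(out, "freqs") <- as.numeric(freqs)
  attr(out, "normalised") <- isTRUE(normalised)
  class(out) <- unique(c("spectra_tbl", class(out)))
  out
}

#' Assemble a spectra table
#'
#' The package's container for segment spectra: a tibble with one row per
#' subject x area (or subject x voxel) and a list-column `power` holding a
#' `segments x frequencies` matrix, with the frequency grid and a
#' normalisation flag carried as attributes.
#'
#' @param subject,area Character vectors (recycled against `power`).
#' @param power List of `segments x frequencies` matrices.
#' @param grid Frequency grid the columns refer to.
#' @param normalised Whether the values are on the ratio-minus-1 scale.
#' @return A `spectra_tbl` tibble.
#' @export
spectra_tbl <- function(subject, area, power, grid = build_frequency_grid(),
                        normalised = FALSE) {
  freqs <- grid_freqs(grid)
  stopifnot(all(vapply(power, function(p) ncol(p) == length(freqs), logical(1))))
  new_spectra_tbl(tibble(subject = subject, area = area, power = power),
                  freqs, normalised)
}

#' @export
spectra_freqs <- function(x) attr(x, "freqs")

#' @export
is_normalised <- function(x) isTRUE(attr(x, "normalised"))

#' Ratio normalisation of power spectra
#'
#' Expresses each segment's power relative to the participant's grand-mean
#' spectrum: every raw spectrum is divided, frequency-wise, by the mean power
#' over all segments and all units (voxels or areas) of that participant, and
#' 1 is subtracted. Values are then dimensionless, greater than -1, and
#' positive where a segment has more power than the whole-brain average at
#' that frequency; by construction the mean of (value + 1) over the
#' normalisation set is exactly 1 at every frequency.
#'
#' @param x Either a 3-d array `segments x units x frequencies` of raw power,
#'   or a raw `spectra_tbl` (normalised per subject across all its rows).
#' @return Same shape as the input, on the ratio-minus-1 scale (for a
#'   `spectra_tbl`, with the `normalised` attribute set).
#' @export
ratio_normalise <- function(x) {
  if (inherits(x, "spectra_tbl") || is.data.frame(x)) {
    if (is_normalised(x)) abort("Input spectra are already ratio-normalised.")
    freqs <- attr(x, "freqs")
    out <- x
    for (s in unique(x$subject)) {
      rows <- which(x$subject == s)
      stacked <- do.call(rbind, x$power[rows])
      check_raw_power(stacked)
      denom <- colMeans(stacked)
      if (any(denom <= 0)) {
        abort("Ratio normalisation is undefined: a frequency has zero mean power.")
      }
      out$power[rows] <- lapply(x$power[rows], function(p) {
        sweep(p, 2, denom, "/") - 1
      })
    }
    attr(out, "normalised") <- TRUE
    return(out)
  }
  stopifnot(is.array(x), length(dim(x)) == 3)
  flat <- matrix(x, ncol = dim(x)[3])   # (segment, unit) rows x frequency
  check_raw_power(flat)
  denom <- colMeans(flat)
  if (any(denom <= 0)) {
    abort("Ratio normalisation is undefined: a frequency has zero mean power.")
  }
  array(sweep(flat, 2, denom, "/") - 1, dim = dim(x), dimnames = dimnames(x))
}

check_raw_power <- function(m) {
  if (any(!is.finite(m))) abort("Power values must be finite.")
  if (any(m < 0)) abort("Raw power must be non-negative.")
  invisible(m)
}

#' Average voxel spectra into atlas areas
#'
#' Replaces the voxel-level rows of a spectra table by per-area rows: for
#' every area and segment, the unweighted mean over the area's voxels.
#' Averaging is done after ratio normalisation, so area spectra stay on the
#' ratio-minus-1 scale.
#'
#' @param x A `spectra_tbl` whose `area` column holds voxel labels.
#' @param labels Data frame with columns `voxel` and `area` mapping every
#'   voxel to its parcel, or a named character vector (names = voxels).
#' @return A `spectra_tbl` with one row per subject x area.
#' @export
average_parcels <- function(x, labels) {
  if (!is.data.frame(labels)) {
    labels <- tibble(voxel = names(labels), area = unname(labels))
  }
  stopifnot(all(c("voxel", "area") %in% names(labels)))
  unlabelled <- setdiff(unique(x$area), labels$voxel)
  if (length(unlabelled)) {
    abort(paste0("Voxels without a parcel label: ",
                 paste(unlabelled, collapse = ", ")))
  }
  rows <- list(); subj <- character(0); area <- character(0)
  for (s in unique(x$subject)) {
    xs <- x[x$subject == s, ]
    for (a in unique(labels$area)) {
      vox <- labels$voxel[labels$area == a]
      idx <- which(xs$area %in% vox)
      if (!length(idx)) {
        abort(sprintf("Area '%s' has no voxels in the data.", a))
      }
      acc <- Reduce(`+`, xs$power[idx]) / length(idx)
      rows <- c(rows, list(acc)); subj <- c(subj, s); area <- c(area, a)
    }
  }
  new_spectra_tbl(tibble(subject = subj, area = area, power = rows),
                  attr(x, "freqs"), attr(x, "normalised"))
}
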