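#' Define a synthetic ground truth of per-area spectral modes
#'
#' Builds the generating model for synthetic multi-subject segment spectra.
#' Every area owns `modes_per_area` spectral modes — log-frequency Gaussian
#' bumps on the ratio-minus-1 scale, each with a mixing proportion — and
#' segments switch between modes independently with those proportions.
#' A shared base mode set is drawn once; each area then perturbs mode centres,
#' amplitudes and proportions by an amount scaled by `separation`. At
#' `separation = 0` all areas are identical (a chance-level preset); large
#' values give every area a distinct fingerprint. With `homologue = TRUE`
#' areas come in left/right pairs ("areaXX_L"/"areaXX_R") whose mode sets are
#' near-identical, emulating hemispheric homologues.
#'
#' Defaults mirror the resting-state study scale the generator emulates: 22
#' subjects with 466 retained 1-s segments each. A lighter desk-scale preset
#' (8 areas x 8 subjects x 120 segments) is available via
#' [synthetic_preset()].
#'
#' @param n_areas Number of areas (>= 2; even when `homologue = TRUE`).
#' @param modes_per_area Modes per area (>= 1).
#' @param separation Non-negative scalar controlling how distinct the areas'
#'   mode sets are (0 = identical).
#' @param n_subjects,n_segments Study size (>= 2 subjects, >= 10 segments).
#' @param freq_jitter_sd Between-subject sd of mode peak frequency, in Hz.
#' @param amp_jitter_sd Between-subject sd of log amplitude multipliers.
#' @param noise_shape Shape of the multiplicative Gamma estimation noise
#'   (mean 1); default 3, matching the chi-square-like variability of a
#'   3-taper multitaper estimate. `Inf` switches noise off.
#' @param homologue Generate left/right homologue pairs?
#' @param seed Master seed; recorded in the truth object.
#' @return An object of class `synthetic_truth`: a list with a `modes` tibble
#'   (area, mode, center_hz, bandwidth_hz, amplitude, proportion) and all
#'   generator parameters.
#' @export
make_truth <- function(n_areas, modes_per_area = 2, separation = 1,
                       n_subjects = 22, n_segments = 466,
                       freq_jitter_sd = 0.5, amp_jitter_sd = 0.1,
                       noise_shape = 3, homologue = FALSE, seed = 1) {
  stopifnot(n_areas >= 2, modes_per_area >= 1, separation >= 0,
            n_subjects >= 2, n_segments >= 10)
  if (homologue && n_areas %% 2 != 0) {
    abort("Homologue pairing needs an even number of areas.")
  }
  modes <- with_seed(seed, {
    base_center <- exp(runif(modes_per_area, log(4), log(30)))
    base_amp <- runif(modes_per_area, 0.6, 1.4)
    base_prop <- runif(modes_per_area, 0.5, 1.5)
    base_prop <- base_prop / sum(base_prop)
    n_fam <- if (homologue) n_areas %/% 2L else n_areas
    fam_rows <- lapply(seq_len(n_fam), function(a) {
      center <- exp(log(base_center) + separation * rnorm(modes_per_area, 0, 0.15))
      amp <- base_amp * exp(separation * rnorm(modes_per_area, 0, 0.20))
      prop <- base_prop * exp(separation * rnorm(modes_per_area, 0, 0.15))
      tibble(mode = seq_len(modes_per_area), center_hz = center,
             amplitude = amp, proportion = prop / sum(prop))
    })
    if (homologue) {
      rows <- lapply(seq_len(n_areas), function(i) {
        fam <- (i + 1L) %/% 2L
        side <- if (i %% 2L == 1L) "L" else "R"
        r <- fam_rows[[fam]]
        # tiny within-pair jitter, independent of separation
        r$center_hz <- r$center_hz * exp(rnorm(modes_per_area, 0, 0.005))
        r$area <- sprintf("area%02d_%s", fam, side)
        r
      })
    } else {
      rows <- lapply(seq_len(n_areas), function(i) {
        r <- fam_rows[[i]]
        r$area <- sprintf("area%02d", i)
        r
      })
    }
    out <- dplyr::bind_rows(rows)
    out$bandwidth_hz <- 0.15 * out$center_hz
    out[, c("area", "mode", "center_hz", "bandwidth_hz", "amplitude", "proportion")]
  })
  if (any(modes$center_hz < 1 | modes$center_hz > 120)) {
    abort("Mode placement failed: a mode centre fell outside [1, 120] Hz.")
  }
  structure(
    list(modes = modes, n_areas = n_areas, modes_per_area = modes_per_area,
         separation = separation, n_subjects = n_subjects,
         n_segments = n_segments, freq_jitter_sd = freq_jitter_sd,
         amp_jitter_sd = amp_jitter_sd, noise_shape = noise_shape,
         homologue = homologue, seed = seed),
    class = "synthetic_truth"
  )
}

#' Preset synthetic study designs
#'
#' `"desk"`: 8 areas x 8 subjects x 120 segments, a size every stage runs on
#' in seconds. `"paper"`: 115 areas x 22 subjects x 466 segments, the scale of
#' the resting-state study the generator emulates.
#'
#' @param name `"desk"` or `"paper"`.
#' @param ... Overrides passed on to [make_truth()].
#' @export
synthetic_preset <- function(name = c("desk", "paper"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    desk = list(n_areas = 8, modes_per_area = 2, separation = 2,
                n_subjects = 8, n_segments = 120),
    paper = list(n_areas = 115, modes_per_area = 2, separation = 2,
                 n_subjects = 22, n_segments = 466)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(make_truth, args)
}

# Mode template on the grid: a Gaussian bump in log frequency, on the
# ratio-minus-1 scale. Width is expressed relative to the centre so that
# bandwidth_hz is the (approximate) linear-frequency sd at the centre.
mode_template <- function(freqs, center_hz, bandwidth_hz, amplitude) {
  w <- bandwidth_hz / center_hz
  amplitude * exp(-0.5 * ((log(freqs) - log(center_hz)) / w)^2)
}

#' Generate synthetic segment spectra with hidden mode labels
#'
#' Draws, for every subject x area, `n_segments` single-segment spectra on
#' the normalised (ratio-minus-1) scale. Each segment's hidden mode is drawn
#' from the area's mixing proportions; the segment's expected spectrum is the
#' subject-jittered template of that mode (peak frequency shifted by a
#' per-subject normal jitter, amplitude scaled by a per-subject log-normal
#' multiplier); multiplicative Gamma noise with mean 1 and shape
#' `truth$noise_shape` is applied on the power-ratio scale, so generated
#' values always stay above -1.
#'
#' @param truth A [make_truth()] object.
#' @param grid Frequency grid.
#' @param seed Seed; defaults to the truth's recorded seed (offset so spectra
#'   draws are independent of the truth draw).
#' @return A list with `spectra` (a normalised `spectra_tbl`) and `states`
#'   (tibble subject, area, segment, mode — the hidden labels).
#' @export
generate_spectra <- function(truth, grid = build_frequency_grid(), seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  freqs <- grid_freqs(grid)
  seed <- seed %||% (truth$seed + 1000L)
  with_seed(seed, {
    subjects <- sprintf("sub%02d", seq_len(truth$n_subjects))
    areas <- unique(truth$modes$area)
    rows <- vector("list", length(subjects) * length(areas))
    st <- vector("list", length(rows))
    i <- 0L
    for (s in subjects) {
      for (a in areas) {
        m <- truth$modes[truth$modes$area == a, ]
        center <- pmin(pmax(m$center_hz + rnorm(nrow(m), 0, truth$freq_jitter_sd), 1), 120)
        amp <- m$amplitude * exp(rnorm(nrow(m), 0, truth$amp_jitter_sd))
        templates <- vapply(seq_len(nrow(m)), function(j) {
          mode_template(freqs, center[j], m$bandwidth_hz[j], amp[j])
        }, numeric(length(freqs)))           # freq x mode
        state <- sample.int(nrow(m), truth$n_segments, replace = TRUE,
                            prob = m$proportion)
        expected <- t(templates[, state, drop = FALSE])  # segment x freq
        if (is.finite(truth$noise_shape)) {
          g <- matrix(rgamma(length(expected), shape = truth$noise_shape,
                             rate = truth$noise_shape), nrow(expected))
          p <- (expected + 1) * g - 1
        } else {
          p <- expected
        }
        i <- i + 1L
        rows[[i]] <- p
        st[[i]] <- tibble(subject = s, area = a,
                          segment = seq_len(truth$n_segments), mode = m$mode[state])
      }
    }
    idx <- expand.grid(area = areas, subject = subjects,
                       stringsAsFactors = FALSE)[, 2:1]
    list(
      spectra = new_spectra_tbl(
        tibble(subject = idx$subject, area = idx$area, power = rows),
        freqs, normalised = TRUE),
      states = dplyr::bind_rows(st)
    )
  })
}

#' Generate synthetic continuous time series
#'
#' Produces per subject x area continuous signals that exercise the spectral
#' front end: each 1-s block is 1/f-shaped background noise plus a sinusoid at
#' the block's active mode centre with random phase; the active mode follows
#' the same hidden switching process as [generate_spectra()].
#'
#' @param truth A [make_truth()] object.
#' @param fs Sampling rate in Hz (>= 250).
#' @param duration_s Duration per subject x area in seconds; default
#'   `truth$n_segments`.
#' @param seed Seed (default derived from the truth's seed).
#' @return A list with `signals` (tibble subject, area, signal list-column of
#'   numeric vectors; sampling rate in attribute `fs`) and `states`.
#' @export
generate_time_series <- function(truth, fs = 250, duration_s = NULL, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), fs >= 250)
  duration_s <- duration_s %||% truth$n_segments
  n_blocks <- as.integer(floor(duration_s))
  seed <- seed %||% (truth$seed + 2000L)
  with_seed(seed, {
    subjects <- sprintf("sub%02d", seq_len(truth$n_subjects))
    areas <- unique(truth$modes$area)
    sig <- list(); st <- list(); subj_col <- character(0); area_col <- character(0)
    for (s in subjects) {
      for (a in areas) {
        m <- truth$modes[truth$modes$area == a, ]
        state <- sample.int(nrow(m), n_blocks, replace = TRUE, prob = m$proportion)
        blocks <- lapply(seq_len(n_blocks), function(b) {
          x <- pink_noise(fs)
          amp <- m$amplitude[state[b]]
          if (amp > 0) {
            tt <- (0:(fs - 1)) / fs
            x <- x + 2 * sqrt(amp) *
              sin(2 * pi * m$center_hz[state[b]] * tt + runif(1, 0, 2 * pi))
          }
          x
        })
        sig <- c(sig, list(unlist(blocks)))
        subj_col <- c(subj_col, s); area_col <- c(area_col, a)
        st <- c(st, list(tibble(subject = s, area = a,
                                segment = seq_len(n_blocks), mode = m$mode[state])))
      }
    }
    signals <- tibble(subject = subj_col, area = area_col, signal = sig)
    attr(signals, "fs") <- fs
    list(signals = signals, states = dplyr::bind_rows(st))
  })
}

# One second of 1/f-amplitude ("pink") noise at unit sd, via spectral shaping.
pink_noise <- function(n) {
  white <- rnorm(n)
  sp <- fft(white)
  f <- c(1, seq_len(n %/% 2), rev(seq_len((n - 1) %/% 2)))  # symmetric bin freqs
  sp <- sp / sqrt(f)
  x <- Re(fft(sp, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}
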