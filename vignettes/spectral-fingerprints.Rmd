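---
title: "Spectral fingerprints: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral fingerprints: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`specfp` models the spectral repertoire of a brain area as a small set of
recurring spectrum shapes ("modes") that the area switches between on the
time scale of seconds. This vignette explains the model and its
assumptions, the parameters that matter, the synthetic ground-truth
generator, and the numerical and design choices made where more than one
reasonable option existed.

## The model

Let $x_{s,i} \in \mathbb{R}^{42}$ be the ratio-normalised power spectrum of
segment $i$ of subject $s$ in one area, on the banded logarithmic grid of 42
frequencies between 1 and 120 Hz. The working assumptions are:

1. **Piecewise stationarity.** Within a 1-s segment the signal is
   stationary enough for a multitaper estimate; dynamics live in the
   switching between segments, which is treated as exchangeable (no
   temporal model — segments are an i.i.d. sample from the area's mode
   mixture).
2. **Shape over amplitude.** What distinguishes modes is mainly the shape
   of the spectrum; clustering therefore uses the cosine distance
   $d(x,y) = 1 - \cos\angle(x,y)$. Amplitude information re-enters in the
   Gaussian-mixture refinement, which operates on the raw normalised
   spectra.
3. **Hierarchy.** Subject-level structure is summarised first (k-means with
   $k_1 = 10$, refined into a 10-component diagonal-covariance Gaussian
   mixture by EM); group structure is then fitted to the pooled subject
   component means. Pooling component means rather than raw segments makes
   the group fit insensitive to per-subject segment counts and reduces
   $\sim$10,000 segments to $n_\mathrm{subjects} \times 10$ rows.

The group model for an area is a $k_2$-component diagonal Gaussian mixture;
$k_2$ is selected by the silhouette criterion (cosine distance) over
$k = 1\ldots15$. A group cluster is *stable* when at least a significant
majority of subjects contribute at least one component to it; for 22
subjects that threshold is 16 ($\chi^2(1) = 4.55$, $p = .03$, i.e. 73%).
A cluster's *duration* is the mean over its contributing subjects of the
percentage of segments they spent in it; because subjects typically
contribute to several clusters, cumulative durations can exceed 100%.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| segment length | 1 | s | time scale of mode switching; Rayleigh resolution 1 Hz, padded to 0.5 Hz |
| multitaper NW / tapers | 2 / 3 | — | ±2 Hz smoothing of 1-s segments |
| channel / segment rejection z | 1.5 / 2 | sd | single-pass z-score of per-item variance |
| $k_1$ | 10 | clusters | subject-level dimensionality reduction |
| k-means restarts / iterations | 10 / 100 | — | best-of-restarts by within-cluster cosine distance |
| silhouette range / restarts | 1–15 / 1000 | — | group cluster number selection |
| silhouette floor | 0.25 | — | below it data are treated as unclustered, $k_2 = 1$ |
| majority threshold | $\chi^2$-based | subjects | smallest significant majority (16 of 22) |
| classification iterations | 120 | splits | split-half stability |
| $k_\mathrm{train}$ | 4 | clusters | fixed across areas to keep NLL comparable |
| trimming | 20% total | — | 10% in each tail of the rank sample |
| similarity cut | 20 | clusters | dendrogram reporting level |
| peak-match tolerance | 1 grid step | Hz | grid spacing is the frequency resolution of a mode's location |

## The frequency grid

Only the grid's summary properties are fixed by the design (42 values
between 1 and 120 Hz; 6/9/5/8/14 per band); the exact values follow from
the package's construction rule: log-spacing within each band, snapped to
the 0.5-Hz lattice of the zero-padded FFT, with collisions resolved upward
to the next free step. Below 7 Hz the lattice has fewer slots than the
banded counts require, so the last delta value (3.5 Hz) and the last two
theta values (7.5, 8 Hz) sit just past their nominal band edges; band
labels follow the construction, keeping the printed counts exact.

## The synthetic generator

`make_truth()` / `generate_spectra()` emulate the features of segmented,
ratio-normalised MEG source spectra that the pipeline relies on:

* per-area mode sets — Gaussian bumps in log frequency on the
  ratio-minus-1 scale (matching the logarithmic grid);
* segment-wise switching with fixed mixing proportions (i.i.d.
  categorical);
* between-subject variability — normal jitter of peak frequency
  (default sd 0.5 Hz) and log-normal amplitude scaling (default sd 0.1);
* estimation noise — multiplicative Gamma noise with mean 1 applied to
  power ratios (shape 3, mimicking the chi-square-like variability of a
  3-taper estimate), which also guarantees the $>-1$ bound of the
  normalised scale.

Defaults mirror a resting-state study scale (22 subjects × 466 segments);
the `"desk"` preset (8 areas × 8 subjects × 120 segments, separation 2) is
the size used throughout the test suite so that every stage runs in
seconds. `generate_time_series()` additionally produces 1/f-background
signals with per-block sinusoids to exercise the spectral front end
end-to-end.

What the generator does **not** emulate: temporal autocorrelation of mode
switching (no HMM dynamics), cross-area leakage and correlated noise from
source projection, non-Gaussian mode shapes (harmonics, asymmetric peaks),
line noise, and non-stationary drift within a recording. Passing the
recovery tests therefore shows the estimator chain is correct under the
stated generative assumptions, not that real MEG data meet those
assumptions.

## Numerical choices

* **Variance floor.** Mixture covariances are diagonal with a per-dimension
  floor of $10^{-6}$ × data variance (absolute floor $10^{-12}$): full
  42-dimensional covariances are not identifiable from a few hundred
  segments, and the floor keeps every log-density — hence every NLL score —
  finite, including for degenerate all-identical inputs.
* **EM stopping.** Relative log-likelihood change below $10^{-6}$ or 200
  iterations; the trace is monotone and tested to be so.
* **Empty k-means clusters** are re-seeded from the row farthest from its
  current centroid; rows with numerically zero norm are left at zero and
  sit at cosine distance 1 from everything.
* **Silhouette conventions.** $k = 1$ has silhouette 0 by definition; ties
  break toward smaller $k$ (parsimony); a best silhouette below 0.25 falls
  back to $k_2 = 1$, so isotropic noise is not assigned spurious structure.
* **Ranking ties** receive midranks, avoiding index-order bias when NLLs
  coincide (exactly tied models yield rank $(A+1)/2$).
* **Rejection z-scores** use the population standard deviation in a single
  pass; zero-variance inputs reject nothing.
* **Segments are demeaned** before tapering, so a constant offset affects
  only the 0-Hz bin exactly rather than up to taper leakage.
* **Seeds.** Every stochastic stage draws child seeds from one master seed
  (subject-model seeds are assigned after sorting by subject and area), so
  results are reproducible and invariant to row order.

## Design decisions

* **Ratio normalisation before parcel averaging**, computed per participant
  over all segments and areas jointly — the mean of (value + 1) over the
  normalisation set is exactly 1 at every frequency, an identity the tests
  enforce at $10^{-10}$.
* **Group observations are the 1st-level component means** (the natural
  point summary of each refined cluster), not raw segments or k-means
  centroids.
* **Contribution rule:** a subject contributes to a group cluster if at
  least one of its components lands there under maximum posterior; duration
  averages over contributing subjects only. This is what makes cumulative
  durations exceed 100%, a property the tests construct explicitly.
* **Sequential Bonferroni = Holm step-down**, implemented from its
  definition and cross-checked against `p.adjust` and a brute-force oracle.
* **Similarity metric:** NLL cross-fit profiles give each area a feature
  vector; the inter-area distance is the cosine distance between profile
  rows, agglomerated by UPGMA. The profile matrix itself is not symmetrised.
* **Homologue-aware rank** is the minimum of the area's and its partner's
  midranks in the same NLL ordering.
* **Spherical coordinate origin** is the unweighted centroid of all area
  centroids (configurable); radius is in cm, elevation measured from the
  axial plane, azimuth from the +x axis.
* **Classification test representation:** the pooled test subjects'
  component means — the same representation the group models are fitted to,
  which makes train and test likelihoods directly comparable.
* The packaged 115-area atlas table carries the real AAL label structure
  (names, hemispheres, L/R homologue pairs, unpaired vermis) but
  **synthetic centroid coordinates**, suitable for exercising the geometry
  regressions, not for anatomical localisation.

## Known limitations

* Modes that differ only in amplitude, not shape, are invisible to the
  cosine k-means stage and separated only by the Gaussian refinement;
  duration estimates for such modes are markedly less reliable than for
  shape-distinct modes. The duration-recovery tests therefore use
  shape-distinct (different-band) modes.
* With between-subject peak jitter, the group cluster mean is a
  jitter-broadened consensus: its cosine distance to any single subject's
  template is inflated by construction. Template-recovery tests run in the
  jitter-free regime for this reason.
* Segment exchangeability discards temporal structure; dwell times and
  transition probabilities are out of scope.
* The silhouette floor (0.25) is a heuristic; data with genuinely weak but
  real structure near the floor may be conservatively assigned $k_2 = 1$.
* NLL comparisons assume the diagonal-Gaussian family is adequate for
  pooled component means; heavy-tailed subject variability would call for
  robust mixtures, which are not implemented.
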