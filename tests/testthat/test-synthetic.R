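test_that("truth generation is deterministic and separation behaves as documented", {
  t1 <- make_truth(4, 2, separation = 0, n_subjects = 4, n_segments = 20, seed = 7)
  t2 <- make_truth(4, 2, separation = 0, n_subjects = 4, n_segments = 20, seed = 7)
  expect_identical(t1$modes, t2$modes)

  # separation 0: all areas share one mode set
  by_area <- split(t1$modes[, c("center_hz", "amplitude", "proportion")],
                   t1$modes$area)
  for (a in by_area) expect_equal(a, by_area[[1]], ignore_attr = TRUE)

  # large separation: area mode-centre sets diverge
  t3 <- make_truth(4, 2, separation = 3, n_subjects = 4, n_segments = 20, seed = 7)
  centers <- split(t3$modes$center_hz, t3$modes$area)
  dists <- utils::combn(length(centers), 2, function(ij) {
    sum(abs(sort(centers[[ij[1]]]) - sort(centers[[ij[2]]])))
  })
  expect_true(min(dists) > 0)
})

test_that("impossible mode placement errors", {
  expect_error(make_truth(20, 2, separation = 60, seed = 2), "outside")
})

test_that("hidden states follow the mixing proportions", {
  truth <- make_truth(2, 2, separation = 0, n_subjects = 2, n_segments = 500,
                      seed = 3)
  truth$modes$proportion <- rep(c(0.8, 0.2), 2)
  gen <- generate_spectra(truth)
  st <- gen$states[gen$states$subject == "sub01" & gen$states$area == "area01", ]
  n1 <- sum(st$mode == 1)
  # binomial 99% interval at n = 500, p = 0.8
  expect_gte(n1, qbinom(0.005, 500, 0.8))
  expect_lte(n1, qbinom(0.995, 500, 0.8))
})

test_that("the noiseless, jitter-free limit reproduces the mode templates", {
  truth <- make_truth(2, 2, separation = 1, n_subjects = 2, n_segments = 50,
                      freq_jitter_sd = 0, amp_jitter_sd = 0,
                      noise_shape = Inf, seed = 5)
  grid <- build_frequency_grid()
  gen <- generate_spectra(truth, grid)
  m <- truth$modes[truth$modes$area == "area01", ]
  templates <- vapply(seq_len(nrow(m)), function(j) {
    specfp:::mode_template(grid$freq_hz, m$center_hz[j], m$bandwidth_hz[j],
                           m$amplitude[j])
  }, numeric(42))
  p <- gen$spectra$power[[which(gen$spectra$subject == "sub01" &
                                  gen$spectra$area == "area01")]]
  st <- gen$states[gen$states$subject == "sub01" & gen$states$area == "area01", ]
  for (i in seq_len(nrow(p))) {
    expect_equal(p[i, ], templates[, st$mode[i]], tolerance = 1e-12)
  }
})

test_that("the empirical mean spectrum converges to the mixture of templates", {
  truth <- make_truth(2, 2, separation = 1, n_subjects = 2, n_segments = 2000,
                      freq_jitter_sd = 0, amp_jitter_sd = 0, seed = 6)
  grid <- build_frequency_grid()
  gen <- generate_spectra(truth, grid)
  m <- truth$modes[truth$modes$area == "area01", ]
  expected <- Reduce(`+`, lapply(seq_len(nrow(m)), function(j) {
    m$proportion[j] * specfp:::mode_template(grid$freq_hz, m$center_hz[j],
                                             m$bandwidth_hz[j], m$amplitude[j])
  }))
  p <- gen$spectra$power[[which(gen$spectra$subject == "sub01" &
                                  gen$spectra$area == "area01")]]
  # per-frequency sd of the Gamma noise is (template+1)/sqrt(shape); the mean
  # of 2000 draws should sit well within 5 standard errors
  tol <- 5 * (max(expected) + 1) / sqrt(truth$noise_shape * 2000)
  expect_lt(max(abs(colMeans(p) - expected)), tol + 0.02)
})

test_that("generated spectra are reproducible and respect the > -1 bound", {
  truth <- make_truth(3, 2, separation = 1, n_subjects = 3, n_segments = 40,
                      seed = 9)
  g1 <- generate_spectra(truth)
  g2 <- generate_spectra(truth)
  expect_identical(g1$spectra$power, g2$spectra$power)
  expect_identical(g1$states, g2$states)
  expect_true(all(vapply(g1$spectra$power, function(p) all(p > -1), logical(1))))
})

test_that("k-means recovers mode templates at high separation and low noise", {
  truth <- make_truth(4, 2, separation = 2.5, n_subjects = 2, n_segments = 200,
                      freq_jitter_sd = 0, amp_jitter_sd = 0,
                      noise_shape = 200, seed = 13)
  grid <- build_frequency_grid()
  gen <- generate_spectra(truth, grid)
  for (a in unique(truth$modes$area)) {
    p <- gen$spectra$power[[which(gen$spectra$subject == "sub01" &
                                    gen$spectra$area == a)]]
    km <- kmeans_cosine(p, 2, seed = 21)
    m <- truth$modes[truth$modes$area == a, ]
    templates <- t(vapply(seq_len(nrow(m)), function(j) {
      specfp:::mode_template(grid$freq_hz, m$center_hz[j], m$bandwidth_hz[j],
                             m$amplitude[j])
    }, numeric(42)))
    tu <- templates / sqrt(rowSums(templates^2))
    # each centroid within cosine distance 0.05 of some template (and 1:1)
    d <- 1 - km$centroids %*% t(tu)
    expect_lt(max(apply(d, 1, min)), 0.05)
    expect_equal(sort(apply(d, 1, which.min)), 1:2)
  }
})

test_that("synthetic time series carry the active mode's rhythm", {
  truth <- make_truth(2, 1, separation = 0, n_subjects = 2, n_segments = 100,
                      freq_jitter_sd = 0, amp_jitter_sd = 0, seed = 17)
  truth$modes$center_hz[] <- 10
  truth$modes$amplitude[] <- 5
  truth$modes$proportion[] <- 1
  ts <- generate_time_series(truth, fs = 250, duration_s = 100)
  grid <- build_frequency_grid()
  x <- ts$signals$signal[[1]]
  segs <- segment_signal(x, fs = 250)
  ps <- multitaper_spectra(segs, 250, grid)
  peaks <- grid$freq_hz[max.col(ps)]
  expect_gte(mean(peaks == 10), 0.95)

  # zero-amplitude modes -> pure 1/f background: low-frequency dominance
  truth0 <- truth; truth0$modes$amplitude[] <- 0
  ts0 <- generate_time_series(truth0, fs = 250, duration_s = 20)
  ps0 <- colMeans(multitaper_spectra(segment_signal(ts0$signals$signal[[1]], 250),
                                     250, grid))
  expect_gt(mean(ps0[grid$freq_hz <= 5]), mean(ps0[grid$freq_hz >= 40]))

  # determinism
  ts2 <- generate_time_series(truth, fs = 250, duration_s = 100)
  expect_identical(ts$signals$signal, ts2$signals$signal)
})
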