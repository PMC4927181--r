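test_that("peak extraction follows the global-maximum rule", {
  grid <- build_frequency_grid()
  bump <- function(c, a) a * exp(-0.5 * ((log(grid$freq_hz) - log(c)) / 0.2)^2)
  pk <- find_peak(bump(10, 1), grid)
  expect_equal(pk$peak_hz, 10)
  two <- bump(5, 0.5) + bump(20, 0.3)
  expect_equal(find_peak(two, grid)$peak_hz, 5)
  expect_error(find_peak(rep(1, 42), grid), "Flat")
  expect_warning(pb <- find_peak(seq(0, 1, length.out = 42), grid), "boundary")
  expect_equal(pb$peak_hz, 120)
})

test_that("mode matching is greedy, tolerance-bounded, and symmetric", {
  pa <- tibble::tibble(cluster = 1:2, peak_hz = c(4.5, 6.5))
  pb <- tibble::tibble(cluster = 1:2, peak_hz = c(4.5, 8.5))
  mm <- match_modes(pa, pb, tol_hz = 1)
  expect_equal(nrow(mm$matched), 1)
  expect_equal(mm$matched$peak_hz_a, 4.5)
  expect_equal(mm$unmatched_a$peak_hz, 6.5)
  expect_equal(mm$unmatched_b$peak_hz, 8.5)

  # identical profiles match perfectly at zero offset
  mm2 <- match_modes(pa, pa, tol_hz = 1)
  expect_equal(nrow(mm2$matched), 2)
  expect_true(all(mm2$matched$delta_hz == 0))

  # symmetry: swapping conditions yields the same pair set
  set.seed(3)
  for (i in 1:10) {
    qa <- tibble::tibble(cluster = 1:4, peak_hz = sort(runif(4, 2, 40)))
    qb <- tibble::tibble(cluster = 1:4, peak_hz = sort(runif(4, 2, 40)))
    ab <- match_modes(qa, qb, tol_hz = 3)$matched
    ba <- match_modes(qb, qa, tol_hz = 3)$matched
    expect_setequal(paste(ab$cluster_a, ab$cluster_b),
                    paste(ba$cluster_b, ba$cluster_a))
  }
})

test_that("Welch comparison matches the textbook formula", {
  x <- c(12.1, 14.3, 13.8, 12.9, 13.4)          # n = 5
  y <- c(11.2, 10.8, 12.4, 11.9, 10.5, 11.1, 12.0)  # n = 7
  w <- compare_amplitudes(x, y)
  se2x <- var(x) / 5; se2y <- var(y) / 7
  t_hand <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df_hand <- (se2x + se2y)^2 / (se2x^2 / 4 + se2y^2 / 6)
  expect_equal(w$statistic, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  same <- c(1, 2, 3)
  expect_equal(compare_amplitudes(same, same)$statistic, 0)
  expect_equal(compare_amplitudes(same, same)$p_value, 1)
  sep <- compare_amplitudes(c(0, 0, 0, 0) + rnorm(4, 0, 1e-6),
                            c(1, 1, 1, 1) + rnorm(4, 0, 1e-6))
  expect_lt(sep$p_value, 0.001)
  expect_error(compare_amplitudes(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Welch p-values are uniform under the null", {
  set.seed(1)
  p <- replicate(1000, compare_amplitudes(rnorm(10), rnorm(10))$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("Holm correction matches its step-down definition and p.adjust", {
  expect_equal(holm_correct(c(0.01, 0.04, 0.03))$p_holm, c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(0.2)$p_holm, 0.2)
  expect_equal(holm_correct(rep(1, 4))$p_holm, rep(1, 4))
  set.seed(11)
  for (m in 1:6) {
    for (rep in 1:20) {
      p <- runif(m)^2
      expect_equal(holm_correct(p)$p_holm, stats::p.adjust(p, "holm"))
    }
  }
})

test_that("spherical coordinates follow the geometric conventions", {
  sc <- spherical_coords(rbind(c(0, 0, 5), c(3, 4, 0)), origin = c(0, 0, 0))
  expect_equal(sc$r_cm, c(5, 5))
  expect_equal(sc$elevation_deg[1], 90)
  expect_equal(sc$elevation_deg[2], 0)
  expect_equal(sc$azimuth_deg[2], atan2(4, 3) * 180 / pi)

  # radius is rotation invariant
  set.seed(13)
  pts <- matrix(rnorm(30), 10, 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(spherical_coords(pts, origin = c(0, 0, 0))$r_cm,
               spherical_coords(pts %*% t(R), origin = c(0, 0, 0))$r_cm,
               tolerance = 1e-12)

  expect_warning(sc0 <- spherical_coords(rbind(c(0, 0, 0), c(1, 1, 1)),
                                         origin = c(0, 0, 0)), "origin")
  expect_equal(sc0$r_cm[1], 0)
  expect_equal(sc0$elevation_deg[1], 0)
})

test_that("metric regressions match closed-form least squares", {
  r <- c(1, 2, 3, 4, 5, 6)
  perfect <- suppressWarnings(regress_metric(2 * r, r))  # lm flags exact fits
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 2)

  set.seed(17)
  y <- c(2.3, 4.1, 3.7, 5.2, 6.0, 5.5)
  fit <- regress_metric(y, r)
  slope_hand <- cov(y, r) / var(r)
  r2_hand <- cov(y, r)^2 / (var(y) * var(r))
  expect_equal(fit$slope, slope_hand, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2_hand, tolerance = 1e-12)
  expect_equal(fit$df2, 4)
  expect_error(regress_metric(y, rep(1, 6)), "constant")
})

test_that("geometry regression corrects the three coordinates jointly", {
  parcels <- aal_parcels()
  coords <- spherical_coords(parcels)
  set.seed(19)
  metric <- 0.2 * coords$r_cm + rnorm(115, 0, 0.3)
  out <- regress_geometry(metric, coords, metric_name = "mean_rank")
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_holm >= out$p_value))
  expect_true(out$significant[out$coordinate == "r_cm"])
  expect_true(all(out$r_squared >= 0 & out$r_squared <= 1))
})

test_that("condition contrasts trace amplitudes and correct the family", {
  truth <- make_truth(2, 2, separation = 2, n_subjects = 6, n_segments = 80,
                      seed = 23)
  gen_a <- generate_spectra(truth, seed = 24)
  gen_b <- generate_spectra(truth, seed = 25)
  sm_a <- fit_subject_models(gen_a$spectra[gen_a$spectra$area == "area01", ],
                             k1 = 5, seed = 26)
  sm_b <- fit_subject_models(gen_b$spectra[gen_b$spectra$area == "area01", ],
                             k1 = 5, seed = 27)
  gm_a <- fit_group_model(sm_a, k2 = 2, seed = 28)
  gm_b <- fit_group_model(sm_b, k2 = 2, seed = 29)
  cc <- compare_conditions(gm_a, gm_b, min_samples = 2)
  expect_gte(nrow(cc$comparison), 1)
  expect_true(all(cc$comparison$p_holm >= cc$comparison$p_value))
  samples <- mode_amplitude_samples(gm_a, 1)
  expect_true(all(c("subject", "amplitude") %in% names(samples)))
  expect_equal(nrow(samples), sum(gm_a$assignments == 1))
})
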