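test_that("segmentation cuts non-overlapping whole segments and drops the tail", {
  x <- seq_len(487 * 250)
  segs <- segment_signal(x, fs = 250)
  expect_equal(dim(segs), c(487, 250))
  expect_equal(segs[1, ], x[1:250])
  expect_equal(segs[2, 1], x[251])

  segs2 <- segment_signal(seq_len(475), fs = 250)  # 1.9 s
  expect_equal(dim(segs2), c(1, 250))

  expect_error(segment_signal(seq_len(125), fs = 250), "shorter")
})

test_that("multichannel segmentation keeps channels aligned", {
  x <- cbind(1:500, 501:1000)
  segs <- segment_signal(x, fs = 250)
  expect_equal(dim(segs), c(2, 250, 2))
  expect_equal(segs[2, , 2], 751:1000)
})

test_that("z-score rejection reproduces the worked examples", {
  # one extreme item among five: z = 2.0 (population sd), kept at threshold 2
  r2 <- reject_outliers(c(1, 1, 1, 1, 10), z_threshold = 2)
  expect_equal(r2$rejected, integer(0))
  r15 <- reject_outliers(c(1, 1, 1, 1, 10), z_threshold = 1.5)
  expect_equal(r15$rejected, 5L)
  # z = (100 - 25) / 43.3 = 1.73 > 1.5
  expect_equal(reject_outliers(c(0, 0, 0, 100), 1.5)$rejected, 4L)
  # zero variance rejects nothing
  expect_equal(reject_outliers(rep(3, 6), 0.1)$rejected, integer(0))
})

test_that("DPSS tapers match independently computed Slepian sequences", {
  # reference values computed with scipy.signal.windows.dpss(250, NW=2, Kmax=3)
  w <- dpss_tapers(250, nw = 2, k = 3)
  expect_equal(w[c(1, 51, 126, 201), 1],
               c(0.0017711563, 0.0359568951, 0.104473827, 0.0348275638),
               tolerance = 1e-8)
  expect_equal(w[c(1, 51, 126, 201), 2],
               c(0.0106984083, 0.0785122264, -0.0013681608, -0.0773488988),
               tolerance = 1e-8)
  expect_equal(w[c(1, 51, 126, 201), 3],
               c(0.0395234189, 0.0862567196, -0.066331267, 0.0872224754),
               tolerance = 1e-8)
  expect_equal(colSums(w^2), rep(1, 3), tolerance = 1e-12)
})

test_that("a pure tone peaks at the nearest grid frequency and zero maps to zero", {
  grid <- build_frequency_grid()
  t <- (0:249) / 250
  ps <- segment_spectrum(sin(2 * pi * 10 * t), fs = 250, grid = grid)
  expect_true(all(ps >= 0))
  expect_equal(grid$freq_hz[which.max(ps)], 10)
  expect_equal(segment_spectrum(rep(0, 250), 250, grid), rep(0, 42))
  expect_error(segment_spectrum(rnorm(200), fs = 200), "Sampling rate")
})

test_that("power scales quadratically and offsets do not leak above 0 Hz", {
  grid <- build_frequency_grid()
  set.seed(4)
  seg <- rnorm(250)
  ps <- segment_spectrum(seg, 250, grid)
  expect_equal(segment_spectrum(3 * seg, 250, grid), 9 * ps, tolerance = 1e-12)
  expect_equal(segment_spectrum(seg + 7.3, 250, grid), ps, tolerance = 1e-3)
})

test_that("averaged white-noise spectra are flat", {
  grid <- build_frequency_grid()
  set.seed(11)
  segs <- matrix(rnorm(200 * 250), 200)
  ps <- colMeans(multitaper_spectra(segs, 250, grid))
  # unit-variance white noise has flat expected multitaper power; Monte-Carlo
  # tolerance ~ 1/sqrt(3 tapers x 200 segments)
  expect_lt(sd(ps) / mean(ps), 0.10)
})

test_that("ratio normalisation obeys its defining identities", {
  set.seed(2)
  arr <- array(abs(rnorm(30 * 4 * 42)) + 0.05, c(30, 4, 42))
  nz <- ratio_normalise(arr)
  expect_lt(max(abs(apply(nz + 1, 3, mean) - 1)), 1e-10)
  expect_true(all(nz > -1))

  # constant input -> all zeros
  const <- array(2.5, c(5, 3, 42))
  expect_equal(ratio_normalise(const), array(0, c(5, 3, 42)))

  # two segments with power 2 and 4 -> -1/3 and 1/3
  two <- array(c(2, 4), c(2, 1, 1))
  expect_equal(as.numeric(ratio_normalise(two)), c(-1 / 3, 1 / 3))

  # degenerate input: a frequency with zero mean power
  bad <- array(1, c(4, 2, 3)); bad[, , 2] <- 0
  expect_error(ratio_normalise(bad), "zero mean power")
  neg <- array(-1, c(2, 2, 2))
  expect_error(ratio_normalise(neg), "non-negative")
})

test_that("spectra_tbl normalisation works per subject over all areas", {
  grid <- build_frequency_grid()
  set.seed(3)
  x <- spectra_tbl(
    subject = rep(c("s1", "s2"), each = 2),
    area = rep(c("a", "b"), 2),
    power = replicate(4, matrix(abs(rnorm(10 * 42)) + 0.1, 10), simplify = FALSE),
    grid = grid
  )
  nz <- ratio_normalise(x)
  expect_true(is_normalised(nz))
  for (s in c("s1", "s2")) {
    stacked <- do.call(rbind, nz$power[nz$subject == s])
    expect_lt(max(abs(colMeans(stacked + 1) - 1)), 1e-10)
  }
  expect_error(ratio_normalise(nz), "already")
})

test_that("parcel averaging is the unweighted voxel mean", {
  grid <- build_frequency_grid()
  p <- matrix(1, 5, 42)
  x <- spectra_tbl(
    subject = rep("s1", 3),
    area = c("v1", "v2", "v3"),
    power = list(p * 0.1, p * 0.2, p * 0.6),
    grid = grid, normalised = TRUE
  )
  labels <- data.frame(voxel = c("v1", "v2", "v3"), area = c("A", "A", "A"))
  avg <- average_parcels(x, labels)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$power[[1]][1, 1], 0.3)

  # one voxel per area -> identity; opposite voxels cancel
  lab2 <- data.frame(voxel = c("v1", "v2", "v3"), area = c("A", "B", "C"))
  expect_equal(average_parcels(x, lab2)$power, x$power)
  x2 <- x[1:2, ]; x2$power <- list(p, -p)
  avg2 <- average_parcels(x2, data.frame(voxel = c("v1", "v2"), area = "A"))
  expect_equal(avg2$power[[1]], p * 0)

  # unlabelled voxel and empty area are errors naming the offender
  expect_error(average_parcels(x, labels[1:2, ]), "v3")
  lab3 <- rbind(lab2, data.frame(voxel = "ghost", area = "D"))
  expect_error(suppressWarnings(average_parcels(x, lab3)), "'D'")
})

test_that("packaged parcel table has 115 areas and symmetric homologues", {
  parcels <- aal_parcels()
  expect_equal(nrow(parcels), 115)
  hm <- homologue_map(parcels)
  expect_true(all(unname(hm[unname(hm)]) == names(hm)))
  expect_false("Cerebelum_3_L" %in% parcels$name)
  expect_equal(unname(hm["Heschl_L"]), "Heschl_R")
})
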