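acq <- AcquisitionConfig()

test_that("analysis windows are 10 wavelengths on each side", {
  win <- windowSideSamples(acq)
  lambda <- acq@soundSpeed / acq@centerFrequency
  expect_equal(unname(win["axial"]),
               as.integer(round(10 * lambda / axialSampleStep(acq))))
  expect_equal(unname(win["lateral"]),
               as.integer(round(10 * lambda / acq@linePitch)))
})

test_that("ROI tiling obeys the floor((L-W)/hop)+1 window count", {
  fr <- simulatePhantomRF(PhantomSpec(extent = c(12, 4)), acq, seed = 1)
  d <- dim(rfSamples(fr))
  for (ov in c(0.5, 0.8, 0.94)) {
    tiles <- tileROI(fr, c(1, 1, d[1], d[2]), overlap = ov)
    win <- tiles$grid$window
    hopA <- max(1, round((1 - ov) * win[["axial"]]))
    hopL <- max(1, round((1 - ov) * win[["lateral"]]))
    expect_equal(tiles$grid$nAxial, (d[1] - win[["axial"]]) %/% hopA + 1)
    expect_equal(tiles$grid$nLateral, (d[2] - win[["lateral"]]) %/% hopL + 1)
    expect_length(tiles$blocks, tiles$grid$nAxial * tiles$grid$nLateral)
    ## every block has the window shape and an increasing depth down a column
    expect_true(all(vapply(tiles$blocks, function(b)
      all(dim(b$samples) == win), logical(1))))
  }
})

test_that("tiling rejects ROIs outside the frame or smaller than a window", {
  fr <- simulatePhantomRF(PhantomSpec(extent = c(12, 4)), acq, seed = 1)
  d <- dim(rfSamples(fr))
  expect_error(tileROI(fr, c(1, 1, d[1] + 1, d[2])), "inside the frame")
  expect_error(tileROI(fr, c(1, 1, 50, 5)), "smaller than one")
  expect_error(tileROI(fr, c(1, 1, d[1], d[2]), overlap = 1), "overlap")
})

test_that("block power spectra localize a pure tone and reject silence", {
  fs <- acq@samplingRate
  t <- (0:511) / fs
  tone <- matrix(sin(2 * pi * 6e6 * t), ncol = 1)
  sp <- blockPowerSpectrum(tone, acq)
  fPeak <- spectrumFrequencies(sp)[which.max(powerDb(sp))]
  expect_lt(abs(fPeak - 6e6), 2 * fs / 512)
  expect_error(blockPowerSpectrum(matrix(1, 64, 2), acq), "constant")
})

test_that("reference-phantom normalization cancels shared spectra exactly", {
  f <- seq(4e6, 9e6, by = 0.5e6)
  s <- PowerSpectrum(f, rnorm(length(f)), depth = 0.02)
  n <- normalizeSpectrum(s, s, refAttenuation = 0.7, sampleAttenuation = 0.7)
  expect_equal(powerDb(n), rep(0, length(f)))
  ## attenuation compensation term: 2*(dAlpha)*fMHz*zCm dB
  n2 <- normalizeSpectrum(s, s, refAttenuation = 0.5, sampleAttenuation = 0.9)
  expect_equal(powerDb(n2), 2 * 0.4 * (f / 1e6) * 2)
  bad <- PowerSpectrum(f + 1e5, powerDb(s), depth = 0.02)
  expect_error(normalizeSpectrum(s, bad), "frequency grid")
})

test_that("the spectral fit is exact on a linear spectrum and MBF is the midband value", {
  f <- seq(4e6, 9e6, by = 0.25e6)
  ps <- PowerSpectrum(f, 2 * (f / 1e6) + 5)
  fit <- fitSpectralParameters(ps, c(4e6, 9e6))
  expect_equal(fit$SS, 2, tolerance = 1e-10)
  expect_equal(fit$SI, 5, tolerance = 1e-10)
  expect_equal(fit$MBF, 5 + 2 * 6.5, tolerance = 1e-10)
  expect_error(fitSpectralParameters(PowerSpectrum(c(4e6, 9e6), c(0, 1)),
                                     c(4e6, 9e6)), "at least 3")
})

test_that("spectral-difference ACE is exact on analytic attenuated spectra", {
  depths <- c(0.015, 0.02, 0.025, 0.03)
  for (alpha in c(0.3, 0.576, 1.0)) {
    pairs <- attenSpectrumPair(alpha, 0.576, depths)
    est <- estimateACE(lapply(pairs, `[[`, "sample"),
                       lapply(pairs, `[[`, "reference"),
                       refAttenuation = 0.576, band = c(4e6, 9e6))
    expect_equal(est$ACE, alpha, tolerance = 1e-9)
    expect_false(est$flagged)
  }
})

test_that("ACE flags non-physical estimates and rejects single-depth input", {
  depths <- c(0.015, 0.02, 0.025)
  pairs <- attenSpectrumPair(-1, 0.576, depths)   # implies ACE = -1
  est <- estimateACE(lapply(pairs, `[[`, "sample"),
                     lapply(pairs, `[[`, "reference"))
  expect_true(est$flagged)
  one <- attenSpectrumPair(0.7, 0.576, 0.02)
  expect_error(estimateACE(lapply(one, `[[`, "sample"),
                           lapply(one, `[[`, "reference")),
               "at least two depths")
})

test_that("ACE recovers the simulated attenuation from paired-seed phantoms", {
  ## identical scatterer fields (same seed) so speckle cancels in the ratio
  sample <- simulatePhantomRF(
    PhantomSpec(attenuationSlope = 1.0, extent = c(20, 3)), acq, seed = 9)
  ref <- simulatePhantomRF(
    PhantomSpec(attenuationSlope = 0.576, extent = c(20, 3)), acq, seed = 9)
  d <- dim(rfSamples(sample))
  tiles <- tileROI(sample, c(1, 1, d[1], d[2]), overlap = 0.8)
  refTiles <- tileROI(ref, c(1, 1, d[1], d[2]), overlap = 0.8)
  sSpec <- lapply(tiles$blocks, blockPowerSpectrum, acq = acq)
  rSpec <- lapply(refTiles$blocks, blockPowerSpectrum, acq = acq)
  est <- estimateACE(sSpec, rSpec, refAttenuation = 0.576, band = acq@band)
  expect_lt(abs(est$ACE - 1.0), 0.05)
  expect_gt(est$fitQuality, 0.9)
})

test_that("QUS maps cover the window grid and mask failed cells", {
  tumor <- simulatePhantomRF(
    PhantomSpec(effectiveRadius = 60, numberDensity = 300,
                attenuationSlope = 0.9, extent = c(10, 4)),
    acq, seed = 21)
  ref <- simulatePhantomRF(referencePhantom(extent = c(10, 4)), acq, seed = 22)
  d <- dim(rfSamples(tumor))
  cfg <- qusConfig(ref, referencePhantom(extent = c(10, 4)), overlap = 0.8)
  maps <- computeQusMaps(tumor, c(1, 1, d[1], d[2]),
                         c("MBF", "SS", "SI", "ACE"), cfg)
  expect_named(maps, c("MBF", "SS", "SI", "ACE"))
  tiles <- tileROI(tumor, c(1, 1, d[1], d[2]), overlap = 0.8)
  for (m in maps) {
    expect_equal(dim(mapValues(m)), c(tiles$grid$nAxial, tiles$grid$nLateral))
    expect_true(all(is.finite(mapValues(m)[mapMask(m)])))
  }
  ## MBF = SI + SS * f_mid cell by cell
  mid <- mean(acq@band) / 1e6
  expect_equal(mapValues(maps$MBF),
               mapValues(maps$SI) + mapValues(maps$SS) * mid,
               tolerance = 1e-9)
  ## mapMean honours the mask
  expect_equal(mapMean(maps$MBF),
               mean(mapValues(maps$MBF)[mapMask(maps$MBF)]))
})
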