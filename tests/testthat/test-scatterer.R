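acq <- AcquisitionConfig()
band <- c(4e6, 9e6)

test_that("the spherical Gaussian model reduces to f^4 in the Rayleigh limit", {
  f <- seq(4e6, 9e6, by = 0.25e6)
  b <- modelBSC(f, asdUm = 0, aacDb = 0)
  expect_equal(b$bsc, (f / 1e6)^4)
  ## AAC scales the BSC linearly in power
  b10 <- modelBSC(f, asdUm = 0, aacDb = 10)
  expect_equal(b10$bsc, 10 * b$bsc)
})

test_that("the SGM fit inverts the model exactly (noise-free round trip)", {
  f <- seq(4e6, 9e6, by = 0.1e6)
  for (asd in c(50, 100, 160)) {
    est <- fitSGM(modelBSC(f, asdUm = asd, aacDb = 40), band)
    expect_equal(est$ASD, asd, tolerance = 1e-9)
    expect_equal(est$AAC, 40, tolerance = 1e-9)
    expect_false(est$flagged)
  }
})

test_that("a frequency-flat form factor yields ASD = 0 and a growing one is flagged", {
  f <- seq(4e6, 9e6, by = 0.25e6)
  flat <- fitSGM(modelBSC(f, asdUm = 0, aacDb = 25), band)
  expect_equal(flat$ASD, 0)
  expect_equal(flat$AAC, 25, tolerance = 1e-9)
  expect_false(flat$flagged)
  growing <- structure(list(frequencies = f, bsc = (f / 1e6)^4 * exp(f^2 * 1e-15)),
                       class = "BackscatterCoefficient")
  est <- fitSGM(growing, band)
  expect_equal(est$ASD, 0)
  expect_true(est$flagged)
  few <- structure(list(frequencies = c(4e6, 5e6, 6e6), bsc = c(1, 2, 3)),
                   class = "BackscatterCoefficient")
  expect_error(fitSGM(few, band), "at least 4")
})

test_that("estimateBSC rescales the reference BSC by the normalized power ratio", {
  f <- seq(4e6, 9e6, by = 0.5e6)
  refB <- modelBSC(f, asdUm = 35, aacDb = 20)
  zero <- PowerSpectrum(f, rep(0, length(f)))
  expect_equal(estimateBSC(zero, refB)$bsc, refB$bsc)
  ten <- PowerSpectrum(f, rep(10, length(f)))
  expect_equal(estimateBSC(ten, refB)$bsc, 10 * refB$bsc)
  other <- modelBSC(f + 1e5, asdUm = 35, aacDb = 20)
  expect_error(estimateBSC(zero, other), "frequency grid")
})

test_that("peak spacing converts to scatterer spacing via c/(2*deltaF)", {
  expect_equal(sasFromPeakSpacing(c(5.00e6, 6.54e6), 1540), 0.5)
  ## median spacing of a regular comb
  expect_equal(sasFromPeakSpacing(seq(4e6, 9e6, by = 0.77e6), 1540),
               1540 / (2 * 0.77e6) * 1e3)
  expect_error(sasFromPeakSpacing(5e6, 1540), "at least two")
})

test_that("SAS round trip on a periodic lattice at zero and small jitter", {
  fr0 <- simulatePeriodicPhantom(1.0, 0, acq, seed = 2)
  est0 <- estimateSAS(rfSamples(fr0)[1:800, ], acq)
  expect_true(est0$defined)
  expect_lt(abs(est0$SAS - 1.0), 0.05)
  fr <- simulatePeriodicPhantom(0.5, 0.02, acq, seed = 3)
  est <- estimateSAS(rfSamples(fr)[1:800, ], acq)
  expect_true(est$defined)
  expect_lt(abs(est$SAS - 0.5), 0.025)
})

test_that("SAS is undefined on diffuse media and invariant to amplitude scaling", {
  fr <- simulatePhantomRF(PhantomSpec(extent = c(20, 3)), acq, seed = 5)
  est <- estimateSAS(rfSamples(fr)[1:800, ], acq)
  expect_false(est$defined)
  expect_true(is.na(est$SAS))
  per <- simulatePeriodicPhantom(1.0, 0.01, acq, seed = 4)
  x <- rfSamples(per)[1:800, ]
  e1 <- estimateSAS(x, acq)
  e2 <- estimateSAS(x * 37.5, acq)
  expect_equal(e1$SAS, e2$SAS)
})

test_that("SAS rejects invalid model orders and too-short blocks", {
  x <- matrix(rnorm(200), 100, 2)
  expect_error(estimateSAS(x, acq, arOrder = 1), "arOrder")
  expect_error(estimateSAS(matrix(rnorm(60), 30, 2), acq, arOrder = 40),
               "at least")
  expect_error(estimateSAS(x, acq, minPeaks = 1), "minPeaks")
})

test_that("the planar reference spectrum peaks at the pulse centre frequency", {
  ps <- planarReferenceSpectrum(acq)
  fPeak <- spectrumFrequencies(ps)[which.max(powerDb(ps))]
  expect_lt(abs(fPeak - acq@centerFrequency), 0.1e6)
})
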