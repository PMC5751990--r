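acq <- AcquisitionConfig()

test_that("the transmit pulse is a Gaussian band-pass centred in the band", {
  f <- seq(0.1e6, 20e6, by = 0.05e6)
  a <- pulseAmplitudeSpectrum(f, acq)
  fPeak <- f[which.max(a)]
  expect_gte(fPeak, acq@band[1])
  expect_lte(fPeak, acq@band[2])
  ## -40 dB amplitude support of a Gaussian: |f - fc| <= sigma*sqrt(2*ln 1e4)
  sigma <- acq@pulseBandwidthFraction * acq@centerFrequency /
    (2 * sqrt(2 * log(2)))
  half <- sigma * sqrt(2 * log(1e4))
  far <- abs(f - acq@centerFrequency) > half
  expect_true(all(a[far] <= max(a) * 1e-2))
})

test_that("simulated frames are deterministic under the seed", {
  spec <- PhantomSpec(extent = c(8, 3))
  f1 <- simulatePhantomRF(spec, acq, seed = 11)
  f2 <- simulatePhantomRF(spec, acq, seed = 11)
  expect_identical(rfSamples(f1), rfSamples(f2))
  f3 <- simulatePhantomRF(spec, acq, seed = 12)
  expect_false(identical(rfSamples(f1), rfSamples(f3)))
})

test_that("frame geometry follows extent, sampling step and line pitch", {
  spec <- PhantomSpec(extent = c(8, 3))
  fr <- simulatePhantomRF(spec, acq, seed = 1)
  d <- dim(rfSamples(fr))
  expect_equal(d[1], round(8e-3 / axialSampleStep(acq)))
  expect_equal(d[2], round(3e-3 / acq@linePitch))
  expect_equal(axialSampleStep(acq), acq@soundSpeed / (2 * acq@samplingRate))
})

test_that("higher attenuation lowers deep-window spectra at every band frequency", {
  lo <- simulatePhantomRF(PhantomSpec(attenuationSlope = 0.576, extent = c(20, 3)),
                          acq, seed = 5)
  hi <- simulatePhantomRF(PhantomSpec(attenuationSlope = 1.0, extent = c(20, 3)),
                          acq, seed = 5)
  ## same seed -> identical scatterer field; only the attenuation differs
  n <- nrow(rfSamples(lo))
  rows <- (n - 299):n                     # deepest windows
  sLo <- blockPowerSpectrum(rfSamples(lo)[rows, ], acq)
  sHi <- blockPowerSpectrum(rfSamples(hi)[rows, ], acq)
  band <- spectrumFrequencies(sLo) >= acq@band[1] &
          spectrumFrequencies(sLo) <= acq@band[2]
  expect_true(all(powerDb(sHi)[band] < powerDb(sLo)[band]))
})

test_that("frame spectral energy is confined to the pulse band", {
  fr <- simulatePhantomRF(PhantomSpec(extent = c(10, 3)), acq, seed = 3)
  sp <- blockPowerSpectrum(rfSamples(fr), acq)
  f <- spectrumFrequencies(sp)
  inBand <- f >= acq@band[1] & f <= acq@band[2]
  far <- f < 0.5e6 | f > 16e6
  expect_gt(min(powerDb(sp)[inBand]) - max(powerDb(sp)[far]), 15)
})

test_that("a phantom smaller than one analysis window is rejected", {
  expect_error(simulatePhantomRF(PhantomSpec(extent = c(1, 1)), acq, seed = 1),
               "smaller than one")
})

test_that("periodic phantom envelope autocovariance peaks at the lattice lag", {
  fr <- simulatePeriodicPhantom(1.0, 0, acq, seed = 2)
  x <- rfSamples(fr)
  dz <- axialSampleStep(acq)
  expectLag <- 1.0e-3 / dz                # samples per lattice period
  lags <- integer(0)
  for (j in seq_len(ncol(x))) {
    env <- envelopeFFT(x[, j])
    ac <- stats::acf(env, lag.max = 120, plot = FALSE)$acf[-1]
    ## dominant non-zero-lag peak away from the mainlobe around lag 0
    ac[1:20] <- -Inf
    lags <- c(lags, which.max(ac))
  }
  expect_lt(abs(stats::median(lags) - expectLag), 3)
})

test_that("periodic phantom rejects out-of-range jitter and unresolvable spacing", {
  expect_error(simulatePeriodicPhantom(1.0, 0.5, acq, seed = 1),
               "out of supported range")
  dz <- axialSampleStep(acq)
  expect_error(simulatePeriodicPhantom(dz * 1e3 / 2, 0, acq, seed = 1),
               "spacing")
  ## 0.1 mm spacing -> peak spacing 7.7 MHz exceeds the 5 MHz band span
  expect_error(simulatePeriodicPhantom(0.12, 0, acq, seed = 1),
               "not resolvable")
})

test_that("periodic phantom frames are reproducible under the seed", {
  a <- simulatePeriodicPhantom(0.5, 0.02, acq, seed = 3)
  b <- simulatePeriodicPhantom(0.5, 0.02, acq, seed = 3)
  expect_identical(rfSamples(a), rfSamples(b))
})

test_that("feature-name ledger counts are 7 + 24 + 7 + 24 + 3", {
  expect_length(qusParameterNames(), 7)
  expect_length(texturedParameterNames(), 6)
  expect_length(textureFeatureNames(), 24)
  expect_length(scanFeatureNames(), 31)
  nm <- featureVectorNames()
  expect_length(nm, 65)
  expect_false(anyDuplicated(nm) > 0)
  expect_identical(tail(nm, 3), c("ER", "PR", "HER2"))
  expect_length(grep("^d", nm), 31)       # 31 deltas (dASD etc.)
})

test_that("simulated cohorts honour group sizes, size rules and hazards", {
  spec <- CohortSpec(groupSizes = c(CR = 6L, PR = 9L, NR = 5L))
  co <- simulateCohort(spec, seed = 7)
  p <- co$patients
  expect_equal(as.vector(table(factor(p$label, c("CR", "PR", "NR")))),
               c(6, 9, 5))
  expect_equal(nrow(co$features), 4 * nrow(p))
  ## labels must be re-derivable from the clinical/pathological fields
  relabel <- mapply(classifyResponse, p$preSize, p$postSize,
                    p$invasiveResidual, p$cellularityDecreased,
                    p$clinicalTumorEvidence)
  expect_identical(unname(relabel), p$label)
  ## CR group has zero hazard: all censored at the horizon
  cr <- p[p$label == "CR", ]
  expect_true(all(!cr$event))
  expect_true(all(cr$recurrenceMonths == spec@followupHorizon))
  expect_true(all(p$recurrenceMonths <= spec@followupHorizon))
  ## determinism
  co2 <- simulateCohort(spec, seed = 7)
  expect_identical(co$features, co2$features)
})

test_that("non-responder feature trajectories stay flat on average", {
  co <- simulateCohort(CohortSpec(groupSizes = c(CR = 10L, PR = 10L, NR = 40L)),
                       seed = 3)
  f <- co$features
  nr <- f[f$id %in% co$patients$id[co$patients$label == "NR"], ]
  d <- mean(nr$MBF[nr$scanTime == "week8"]) -
       mean(nr$MBF[nr$scanTime == "week0"])
  expect_lt(abs(d), 1)                    # no systematic drift
  cr <- f[f$id %in% co$patients$id[co$patients$label == "CR"], ]
  dcr <- mean(cr$MBF[cr$scanTime == "week8"]) -
         mean(cr$MBF[cr$scanTime == "week0"])
  expect_gt(dcr, 3)                       # planted responder shift (6 dBr)
})
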