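## Sliding-window spectral estimation with reference-phantom normalization:
## midband fit (MBF), spectral slope (SS), 0-MHz intercept (SI), attenuation
## (ACE) via the spectral difference method, and parametric-map construction.
##
## dB convention: 10*log10 of power. Attenuation slope alpha is in
## dB/(cm*MHz), one-way amplitude loss alpha*f*z dB, so the round-trip power
## spectrum carries -2*alpha*f*z dB (f in MHz, z in cm).

#' Analysis-window side length in samples and lines
#'
#' The window side is `windowLambdas` wavelengths in physical units; axially
#' one sample spans `c/(2*fs)` of depth, laterally one line spans the pitch.
#'
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param windowLambdas window side in wavelengths (default 10).
#' @param mediumSpeed sound speed used for the wavelength, m/s.
#' @return named integer vector `c(axial=, lateral=)`.
#' @export
windowSideSamples <- function(acq, windowLambdas = 10,
                              mediumSpeed = acq@soundSpeed) {
  side <- windowLambdas * mediumSpeed / acq@centerFrequency
  c(axial = max(2L, as.integer(round(side / axialSampleStep(acq, mediumSpeed)))),
    lateral = max(2L, as.integer(round(side / acq@linePitch))))
}

## 1-D sliding-window start positions: hop = (1-overlap)*W rounded to whole
## samples, never zero; count = floor((L-W)/hop) + 1.
#' @noRd
windowStarts <- function(L, W, overlap) {
  if (W > L) stopf("window (%d) larger than extent (%d)", W, L)
  hop <- max(1L, as.integer(round((1 - overlap) * W)))
  seq.int(1L, by = hop, length.out = (L - W) %/% hop + 1L)
}

#' Tile a region of interest into overlapping analysis windows
#'
#' Lays a regular grid of `windowLambdas x windowLambdas` (in wavelengths)
#' window blocks over the ROI with the requested fractional overlap. The hop
#' is `(1 - overlap) * window side` rounded to whole samples/lines, minimum 1;
#' the number of windows along an axis is `floor((L - W)/hop) + 1`.
#'
#' @param frame an \linkS4class{RFFrame}.
#' @param roi integer vector `c(sample0, line0, nSamples, nLines)` (1-based).
#' @param windowLambdas window side in wavelengths.
#' @param overlap fractional overlap in both directions, in [0, 1).
#' @return list with `blocks` (list of window blocks: samples, axialIndex,
#'   lateralIndex, depth) and `grid` (window-grid geometry).
#' @export
tileROI <- function(frame, roi, windowLambdas = 10, overlap = 0.94) {
  stopifnot(is(frame, "RFFrame"))
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  roi <- as.integer(roi)
  d <- dim(frame@samples)
  if (length(roi) != 4L || roi[1] < 1L || roi[2] < 1L ||
      roi[1] + roi[3] - 1L > d[1] || roi[2] + roi[4] - 1L > d[2])
    stopf("roi must be c(sample0, line0, nSamples, nLines) inside the frame")
  acq <- frame@acquisition
  win <- windowSideSamples(acq, windowLambdas)
  if (roi[3] < win["axial"] || roi[4] < win["lateral"])
    stopf("roi (%d x %d) smaller than one %d x %d analysis window",
          roi[3], roi[4], win["axial"], win["lateral"])
  axStarts <- roi[1] - 1L + windowStarts(roi[3], win[["axial"]], overlap)
  latStarts <- roi[2] - 1L + windowStarts(roi[4], win[["lateral"]], overlap)
  dz <- axialSampleStep(acq)
  blocks <- vector("list", length(axStarts) * length(latStarts))
  idx <- 1L
  for (jl in seq_along(latStarts)) {
    for (ja in seq_along(axStarts)) {
      a0 <- axStarts[ja]; l0 <- latStarts[jl]
      blocks[[idx]] <- list(
        samples = frame@samples[a0:(a0 + win[["axial"]] - 1L),
                                l0:(l0 + win[["lateral"]] - 1L), drop = FALSE],
        axialIndex = ja, lateralIndex = jl,
        depth = frame@originDepth + (a0 - 1L + win[["axial"]] / 2) * dz)
      idx <- idx + 1L
    }
  }
  list(blocks = blocks,
       grid = list(nAxial = length(axStarts), nLateral = length(latStarts),
                   window = win, axStarts = axStarts, latStarts = latStarts,
                   windowLambdas = windowLambdas, overlap = overlap))
}

#' Averaged power spectrum of a window block
#'
#' Per-line Hann-tapered periodograms (FFT length: next power of two at or
#' above the window length) averaged across the block's lines, in dB.
#'
#' @param block a window block from [tileROI()], or a numeric matrix
#'   (samples x lines).
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @return a \linkS4class{PowerSpectrum} (positive frequencies, DC excluded).
#' @export
blockPowerSpectrum <- function(block, acq) {
  x <- if (is.list(block)) block$samples else block
  depth <- if (is.list(block)) block$depth else NA_real_
  x <- as.matrix(x)
  if (all(apply(x, 2, stats::sd) == 0))
    stopf("constant (zero-variance) block: spectrum undefined")
  n <- nrow(x)
  nfft <- nextPow2(n)
  w <- hannWindow(n)
  fs <- acq@samplingRate
  nf <- nfft %/% 2L
  acc <- numeric(nf)
  for (j in seq_len(ncol(x))) {
    X <- stats::fft(c(x[, j] * w, numeric(nfft - n)))
    acc <- acc + (Mod(X[2:(nf + 1L)])^2) / n
  }
  freqs <- seq_len(nf) * fs / nfft
  PowerSpectrum(freqs, toDb(pmax(acc / ncol(x), .Machine$double.xmin)),
                nLinesAveraged = ncol(x), depth = depth)
}

#' Reference-phantom normalization of a power spectrum
#'
#' Subtracts the reference-phantom spectrum (same window geometry and depth)
#' in dB, cancelling the system response, and adds back the attenuation
#' difference `2*(sampleAttenuation - refAttenuation)*f*depth` dB (f in MHz,
#' depth in cm, round-trip power convention) so the result reflects
#' backscatter alone.
#'
#' @param sample,reference \linkS4class{PowerSpectrum} objects on the same
#'   frequency grid.
#' @param depth window-center depth in m; defaults to the sample's depth.
#' @param refAttenuation,sampleAttenuation attenuation slopes, dB/(cm*MHz).
#' @return a \linkS4class{PowerSpectrum} of normalized power in dBr.
#' @export
normalizeSpectrum <- function(sample, reference, depth = spectrumDepth(sample),
                              refAttenuation = 0.576, sampleAttenuation = refAttenuation) {
  if (!isTRUE(all.equal(sample@frequencies, reference@frequencies)))
    stopf("sample and reference must share a frequency grid")
  comp <- if (is.na(depth)) 0 else
    2 * (sampleAttenuation - refAttenuation) *
      (sample@frequencies / 1e6) * (depth * 100)
  PowerSpectrum(sample@frequencies,
                sample@powerDb - reference@powerDb + comp,
                nLinesAveraged = sample@nLinesAveraged, depth = depth)
}

#' Linear spectral fit: midband fit, slope and intercept
#'
#' Ordinary least squares of normalized power (dB) against frequency (MHz) on
#' the analysis band. The slope is SS (dBr/MHz), the 0-MHz intercept is SI
#' (dBr) and MBF is the fitted value at the band midpoint, so
#' `MBF = SI + SS * f_mid` holds as an algebraic identity.
#'
#' @param normalized a \linkS4class{PowerSpectrum} of normalized power.
#' @param band analysis band `c(f_lo, f_hi)`, Hz.
#' @return a list of class `SpectralFit`: `MBF`, `SS`, `SI`, `band`.
#' @examples
#' ps <- PowerSpectrum(seq(4e6, 9e6, by = 0.25e6),
#'                     2 * seq(4, 9, by = 0.25) + 5)
#' fitSpectralParameters(ps, c(4e6, 9e6))
#' @export
fitSpectralParameters <- function(normalized, band) {
  sel <- normalized@frequencies >= band[1] & normalized@frequencies <= band[2]
  if (sum(sel) < 3L) stopf("need at least 3 frequency bins inside the band")
  fMHz <- normalized@frequencies[sel] / 1e6
  y <- normalized@powerDb[sel]
  if (any(!is.finite(y))) stopf("non-finite power inside the band")
  co <- stats::coef(stats::lm(y ~ fMHz))
  si <- unname(co[1]); ss <- unname(co[2])
  mid <- mean(band) / 1e6
  structure(list(MBF = si + ss * mid, SS = ss, SI = si, band = band),
            class = "SpectralFit")
}

#' @export
print.SpectralFit <- function(x, ...) {
  cat(sprintf("SpectralFit: MBF = %.2f dBr, SS = %.3f dBr/MHz, SI = %.2f dBr (%.1f-%.1f MHz)\n",
              x$MBF, x$SS, x$SI, x$band[1] / 1e6, x$band[2] / 1e6))
  invisible(x)
}

#' Attenuation coefficient estimate via the spectral difference method
#'
#' At each band frequency the sample-minus-reference log spectrum is regressed
#' against window depth; the per-frequency depth slopes (dB/cm) are then
#' regressed against frequency (MHz), whose slope equals
#' `-2 * (ACE - refAttenuation)` in the round-trip dB convention, and ACE is
#' solved for.
#'
#' @param sampleSpectra list of \linkS4class{PowerSpectrum} with depths set,
#'   covering at least two distinct depths.
#' @param referenceSpectra matched reference-phantom spectra (same grids and
#'   depths).
#' @param refAttenuation reference attenuation slope, dB/(cm*MHz).
#' @param band analysis band, Hz.
#' @param physicalRange range outside which the estimate is flagged.
#' @return a list of class `AttenuationEstimate`: `ACE` (dB/(cm*MHz)),
#'   `fitQuality` (R^2 of the frequency regression), `flagged`.
#' @export
estimateACE <- function(sampleSpectra, referenceSpectra, refAttenuation = 0.576,
                        band = NULL, physicalRange = c(0, 3)) {
  if (length(sampleSpectra) < 2L)
    stopf("need spectra from at least two depths")
  if (length(sampleSpectra) != length(referenceSpectra))
    stopf("sample and reference spectrum lists must match")
  f <- sampleSpectra[[1]]@frequencies
  depths <- vapply(sampleSpectra, spectrumDepth, numeric(1))
  if (any(is.na(depths)) || length(unique(round(depths, 9))) < 2L)
    stopf("spectra must carry at least two distinct depths")
  diffDb <- vapply(seq_along(sampleSpectra), function(i) {
    if (!isTRUE(all.equal(sampleSpectra[[i]]@frequencies, f)))
      stopf("mismatched frequency grids")
    sampleSpectra[[i]]@powerDb - referenceSpectra[[i]]@powerDb
  }, numeric(length(f)))                       # nFreq x nDepth
  sel <- if (is.null(band)) rep(TRUE, length(f)) else
    f >= band[1] & f <= band[2]
  zCm <- depths * 100
  zc <- zCm - mean(zCm)
  ## per-frequency depth slope (dB/cm), closed-form OLS
  beta <- as.vector(diffDb[sel, , drop = FALSE] %*% zc) / sum(zc^2)
  fMHz <- f[sel] / 1e6
  fit <- stats::lm(beta ~ fMHz)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope)) {
    return(structure(list(ACE = NA_real_, fitQuality = NA_real_,
                          flagged = TRUE), class = "AttenuationEstimate"))
  }
  ace <- refAttenuation - slope / 2
  ## R^2 computed directly (summary.lm warns on numerically perfect fits)
  ssTot <- sum((beta - mean(beta))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  structure(list(ACE = ace, fitQuality = r2,
                 flagged = ace < physicalRange[1] | ace > physicalRange[2]),
            class = "AttenuationEstimate")
}

#' @export
print.AttenuationEstimate <- function(x, ...) {
  cat(sprintf("ACE = %.3f dB/(cm*MHz) (R^2 = %.3f%s)\n", x$ACE, x$fitQuality,
              if (x$flagged) ", flagged" else ""))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Parametric maps

#' Default configuration for QUS map construction
#'
#' @param referenceFrame an \linkS4class{RFFrame} of the reference phantom,
#'   acquired with the same geometry as the sample frame.
#' @param refSpec the \linkS4class{PhantomSpec} of the reference phantom
#'   (attenuation slope and scatterer properties for the BSC model).
#' @param band analysis band, Hz; defaults to the acquisition band.
#' @param windowLambdas,overlap windowing controls (see [tileROI()]).
#' @param arOrder autoregressive model order for SAS.
#' @param sampleAttenuation optional known sample attenuation used in
#'   normalization; when NULL the ACE estimated from the frame is used.
#' @return a list of class `QusConfig`.
#' @export
qusConfig <- function(referenceFrame, refSpec = referencePhantom(),
                      band = NULL, windowLambdas = 10, overlap = 0.94,
                      arOrder = 40, sampleAttenuation = NULL) {
  structure(list(referenceFrame = referenceFrame, refSpec = refSpec,
                 band = band, windowLambdas = windowLambdas,
                 overlap = overlap, arOrder = arOrder,
                 sampleAttenuation = sampleAttenuation),
            class = "QusConfig")
}

#' Compute QUS parametric maps over a region of interest
#'
#' Tiles the ROI (identically in the sample and the reference frame),
#' estimates ACE first via the spectral difference method, then computes the
#' requested parameters per window: MBF/SS/SI from the spectral fit of the
#' attenuation-compensated normalized spectrum, ASD/AAC from the spherical
#' Gaussian model fit to the backscatter coefficient, SAS from autoregressive
#' spectral peak spacing. Failed windows are masked.
#'
#' @param frame the sample \linkS4class{RFFrame}.
#' @param roi `c(sample0, line0, nSamples, nLines)`.
#' @param parameters character vector of parameter names to compute.
#' @param config a [qusConfig()] list.
#' @return named list of \linkS4class{ParametricMap} objects.
#' @export
computeQusMaps <- function(frame, roi,
                           parameters = c("MBF", "SS", "SI", "ACE", "SAS", "ASD", "AAC"),
                           config) {
  stopifnot(inherits(config, "QusConfig"))
  acq <- frame@acquisition
  band <- if (is.null(config$band)) acq@band else config$band
  tiles <- tileROI(frame, roi, config$windowLambdas, config$overlap)
  refTiles <- tileROI(config$referenceFrame, roi, config$windowLambdas, config$overlap)
  g <- tiles$grid
  specs <- lapply(tiles$blocks, function(b)
    tryCatch(blockPowerSpectrum(b, acq), error = function(e) NULL))
  refSpecs <- lapply(refTiles$blocks, function(b)
    tryCatch(blockPowerSpectrum(b, acq), error = function(e) NULL))
  refAtt <- config$refSpec@attenuationSlope
  blockAt <- function(ja, jl) (jl - 1L) * g$nAxial + ja

  ## ACE per lateral column (depth series along the axial window direction),
  ## plus the column-average spectra for a global estimate.
  aceCols <- rep(NA_real_, g$nLateral)
  if (g$nAxial >= 2L) {
    for (jl in seq_len(g$nLateral)) {
      ii <- vapply(seq_len(g$nAxial), blockAt, integer(1), jl = jl)
      ok <- !vapply(specs[ii], is.null, logical(1)) &
            !vapply(refSpecs[ii], is.null, logical(1))
      if (sum(ok) >= 2L) {
        est <- tryCatch(
          estimateACE(specs[ii][ok], refSpecs[ii][ok], refAtt, band),
          error = function(e) NULL)
        if (!is.null(est) && is.finite(est$ACE)) aceCols[jl] <- est$ACE
      }
    }
  }
  globalAce <- if (any(is.finite(aceCols))) stats::median(aceCols, na.rm = TRUE)
               else refAtt
  sampleAtt <- if (is.null(config$sampleAttenuation)) globalAce
               else config$sampleAttenuation

  needSpectral <- any(parameters %in% c("MBF", "SS", "SI", "ASD", "AAC"))
  emptyMap <- function() matrix(NA_real_, g$nAxial, g$nLateral)
  vals <- lapply(parameters, function(p) emptyMap())
  names(vals) <- parameters

  refBsc <- if (any(parameters %in% c("ASD", "AAC"))) {
    rs <- config$refSpec
    refAac <- toDb(rs@numberDensity * rs@impedanceContrastVariance * 1e3)  # per cm^3
    modelBSC(specs[[which(!vapply(specs, is.null, logical(1)))[1]]]@frequencies,
             asdUm = 2 * rs@effectiveRadius, aacDb = refAac,
             soundSpeed = rs@soundSpeed)
  } else NULL

  planar <- if ("SAS" %in% parameters) planarReferenceSpectrum(acq) else NULL

  for (jl in seq_len(g$nLateral)) {
    for (ja in seq_len(g$nAxial)) {
      i <- blockAt(ja, jl)
      s <- specs[[i]]; r <- refSpecs[[i]]
      if (needSpectral && !is.null(s) && !is.null(r)) {
        norm <- tryCatch(
          normalizeSpectrum(s, r, refAttenuation = refAtt,
                            sampleAttenuation = sampleAtt),
          error = function(e) NULL)
        if (!is.null(norm)) {
          if (any(c("MBF", "SS", "SI") %in% parameters)) {
            fit <- tryCatch(fitSpectralParameters(norm, band),
                            error = function(e) NULL)
            if (!is.null(fit)) {
              if ("MBF" %in% parameters) vals$MBF[ja, jl] <- fit$MBF
              if ("SS" %in% parameters) vals$SS[ja, jl] <- fit$SS
              if ("SI" %in% parameters) vals$SI[ja, jl] <- fit$SI
            }
          }
          if (any(c("ASD", "AAC") %in% parameters)) {
            bsc <- tryCatch(estimateBSC(norm, refBsc), error = function(e) NULL)
            if (!is.null(bsc)) {
              sg <- tryCatch(
                fitSGM(bsc, band, soundSpeed = config$refSpec@soundSpeed),
                error = function(e) NULL)
              if (!is.null(sg) && !sg$flagged) {
                if ("ASD" %in% parameters) vals$ASD[ja, jl] <- sg$ASD
                if ("AAC" %in% parameters) vals$AAC[ja, jl] <- sg$AAC
              }
            }
          }
        }
      }
      if ("SAS" %in% parameters) {
        sas <- tryCatch(
          estimateSAS(tiles$blocks[[i]], acq, planar, arOrder = config$arOrder),
          error = function(e) NULL)
        if (!is.null(sas) && sas$defined) vals$SAS[ja, jl] <- sas$SAS
      }
      if ("ACE" %in% parameters) vals$ACE[ja, jl] <- aceCols[jl]
    }
  }
  maps <- lapply(parameters, function(p) {
    m <- vals[[p]]
    if (!any(is.finite(m)))
      stopf("all %s window estimates invalid over this ROI", p)
    ParametricMap(m, p, gridGeometry = g)
  })
  names(maps) <- parameters
  maps
}

#' Build one QUS parametric map
#'
#' Convenience wrapper around [computeQusMaps()] for a single parameter.
#'
#' @inheritParams computeQusMaps
#' @param parameterName one of MBF, SS, SI, ACE, SAS, ASD, AAC.
#' @return a \linkS4class{ParametricMap}.
#' @export
buildParametricMap <- function(frame, roi, parameterName, config) {
  computeQusMaps(frame, roi, parameterName, config)[[parameterName]]
}
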