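## Backscatter-coefficient parameters: average scatterer diameter (ASD) and
## average acoustic concentration (AAC) via the spherical Gaussian scatterer
## model, and scatterer spacing (SAS) via autoregressive spectral analysis.

#' Spherical Gaussian model backscatter coefficient
#'
#' Model BSC on a relative scale:
#' `bsc(f) = 10^(AAC/10) * (f/MHz)^4 * exp(-0.827 * k^2 * a_eff^2)` with
#' `k = 2*pi*f/c` and `a_eff = ASD/2`. AAC is the acoustic concentration in
#' dB/cm^3; in the Rayleigh limit (`a_eff -> 0`) the BSC is proportional to
#' `f^4`.
#'
#' @param freqHz frequency grid, Hz.
#' @param asdUm average scatterer diameter, micrometers.
#' @param aacDb average acoustic concentration, dB/cm^3.
#' @param soundSpeed sound speed, m/s.
#' @return a list of class `BackscatterCoefficient`: `frequencies`, `bsc`.
#' @export
modelBSC <- function(freqHz, asdUm, aacDb, soundSpeed = 1540) {
  aEff <- asdUm / 2 * 1e-6
  bsc <- fromDb(aacDb) * (freqHz / 1e6)^4 *
    gaussianFormFactor(freqHz, aEff, soundSpeed)
  structure(list(frequencies = as.numeric(freqHz), bsc = bsc),
            class = "BackscatterCoefficient")
}

#' Backscatter coefficient from a normalized spectrum
#'
#' With the system response and attenuation removed by reference-phantom
#' normalization, the sample BSC equals the reference phantom's (known) BSC
#' times the linear power ratio implied by the normalized spectrum.
#'
#' @param normalized a \linkS4class{PowerSpectrum} of normalized power (dBr).
#' @param referenceBsc a `BackscatterCoefficient` of the reference phantom on
#'   the same frequency grid (see [modelBSC()]).
#' @return a `BackscatterCoefficient` for the sample.
#' @export
estimateBSC <- function(normalized, referenceBsc) {
  if (!isTRUE(all.equal(normalized@frequencies, referenceBsc$frequencies)))
    stopf("normalized spectrum and reference BSC must share a frequency grid")
  if (any(referenceBsc$bsc <= 0))
    stopf("reference BSC must be positive")
  structure(list(frequencies = referenceBsc$frequencies,
                 bsc = referenceBsc$bsc * fromDb(normalized@powerDb)),
            class = "BackscatterCoefficient")
}

#' Fit the spherical Gaussian scatterer model
#'
#' Linearized fit: `ln(bsc) - 4*ln(f)` is regressed on `f^2`; the slope maps
#' to the effective radius through the Gaussian form-factor exponent
#' (`slope = -0.827 * (2*pi/c)^2 * a_eff^2`), giving ASD = 2 a_eff, and the
#' intercept gives AAC in dB/cm^3. A nonnegative slope (no frequency
#' dependence beyond f^4, the Rayleigh limit) yields ASD = 0.
#'
#' @param bsc a `BackscatterCoefficient`.
#' @param band analysis band, Hz (needs >= 4 bins).
#' @param soundSpeed sound speed, m/s.
#' @return a list of class `ScattererEstimate`: `ASD` (um), `AAC` (dB/cm^3),
#'   `fitResidual`, `flagged`.
#' @examples
#' f <- seq(4e6, 9e6, by = 0.1e6)
#' fitSGM(modelBSC(f, asdUm = 100, aacDb = 40), c(4e6, 9e6))
#' @export
fitSGM <- function(bsc, band, soundSpeed = 1540) {
  sel <- bsc$frequencies >= band[1] & bsc$frequencies <= band[2]
  if (sum(sel) < 4L) stopf("need at least 4 frequency bins inside the band")
  b <- bsc$bsc[sel]
  f <- bsc$frequencies[sel]
  if (any(!is.finite(b)) || any(b <= 0))
    stopf("BSC must be positive and finite on the band")
  y <- log(b) - 4 * log(f / 1e6)
  x <- f^2
  co <- stats::coef(fit <- stats::lm(y ~ x))
  slope <- unname(co[2]); icept <- unname(co[1])
  if (!all(is.finite(c(slope, icept))))
    return(structure(list(ASD = NA_real_, AAC = NA_real_,
                          fitResidual = NA_real_, flagged = TRUE),
                     class = "ScattererEstimate"))
  res <- sum(stats::residuals(fit)^2)
  if (slope >= 0) {
    ## Rayleigh limit; flag only a slope that grows materially across the
    ## band (beyond float noise of an exactly frequency-flat form factor)
    growthDb <- slope * diff(range(x))
    return(structure(list(ASD = 0, AAC = 10 * icept / log(10),
                          fitResidual = res,
                          flagged = growthDb > 1e-9 * max(1, max(abs(y)))),
                     class = "ScattererEstimate"))
  }
  aEff <- sqrt(-slope / FORM_FACTOR_CONST) * soundSpeed / (2 * pi)
  structure(list(ASD = 2 * aEff * 1e6, AAC = 10 * icept / log(10),
                 fitResidual = res, flagged = FALSE),
            class = "ScattererEstimate")
}

#' @export
print.ScattererEstimate <- function(x, ...) {
  cat(sprintf("ScattererEstimate: ASD = %.1f um, AAC = %.1f dB/cm^3%s\n",
              x$ASD, x$AAC, if (x$flagged) " (flagged)" else ""))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Scatterer spacing (SAS)

#' Planar-reflector reference spectrum
#'
#' Emulates the planar-reflector calibration spectrum used to normalize
#' spectra for spacing estimation: in simulation this is the transmit pulse's
#' power spectrum itself.
#'
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param nBins number of frequency bins from 0 to Nyquist.
#' @return a \linkS4class{PowerSpectrum}.
#' @export
planarReferenceSpectrum <- function(acq, nBins = 512L) {
  f <- seq_len(nBins) * (acq@samplingRate / 2) / nBins
  PowerSpectrum(f, toDb(pmax(pulseAmplitudeSpectrum(f, acq)^2,
                             .Machine$double.xmin)))
}

## AR power spectrum (Burg coefficients) on an arbitrary frequency grid.
#' @noRd
arPowerSpectrum <- function(arCoefs, varPred, freqHz, fs) {
  z <- exp(-2i * pi * outer(freqHz / fs, seq_along(arCoefs)))
  denom <- Mod(1 - as.vector(z %*% arCoefs))^2
  varPred / pmax(denom, .Machine$double.xmin)
}

## Local maxima of y with prominence: height above the higher of the deepest
## valleys separating the peak from a higher peak (or the series edge).
#' @noRd
findPeaks <- function(y) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(idx)) return(data.frame(index = integer(), prominence = numeric()))
  prom <- vapply(idx, function(i) {
    leftMin <- min(y[1:i]); rightMin <- min(y[i:n])
    higherLeft <- which(y[1:i] > y[i])
    if (length(higherLeft)) leftMin <- min(y[max(higherLeft):i])
    higherRight <- which(y[i:n] > y[i])
    if (length(higherRight)) rightMin <- min(y[i:(i - 1 + min(higherRight))])
    y[i] - max(leftMin, rightMin)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Scatterer spacing from spectral peak frequencies
#'
#' Converts a set of regularly spaced spectral peak frequencies to a spacing:
#' `SAS = c / (2 * median(diff(peaks)))`.
#'
#' @param peakFreqHz increasing peak frequencies, Hz (>= 2).
#' @param soundSpeed sound speed, m/s.
#' @return spacing in millimeters.
#' @examples
#' sasFromPeakSpacing(c(5.00e6, 6.54e6), 1540)  # 0.5 mm
#' @export
sasFromPeakSpacing <- function(peakFreqHz, soundSpeed) {
  if (length(peakFreqHz) < 2L) stopf("need at least two peak frequencies")
  dF <- stats::median(diff(sort(peakFreqHz)))
  soundSpeed / (2 * dF) * 1e3
}

#' Scatterer spacing via autoregressive spectral analysis
#'
#' Per RF line of the window block: the (Hann-tapered) echo segment is
#' modelled as an autoregressive signal (Burg method), the AR power spectrum
#' is normalized by the planar-reflector reference, and the spacing between
#' the prominent, regularly spaced spectral peaks inside the analysis band
#' gives `SAS = c/(2*deltaF)`. The block value is the median across lines;
#' absence of a prominent regular comb in most lines yields an undefined,
#' flagged result.
#'
#' @param block a window block from [tileROI()] or a samples matrix.
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param planarReference planar-reflector \linkS4class{PowerSpectrum}; NULL
#'   uses [planarReferenceSpectrum()].
#' @param arOrder autoregressive model order (>= 2).
#' @param minProminenceDb minimum peak prominence in dB of the normalized AR
#'   spectrum for a peak to count.
#' @param maxSpacingCv maximum coefficient of variation of the peak spacings
#'   for a line to be considered periodic.
#' @param minPeaks minimum number of prominent, regularly spaced peaks a line
#'   must show to be considered periodic (>= 2); a genuine spacing comb
#'   produces several band peaks, whereas diffuse speckle rarely does.
#' @return a list of class `SpacingEstimate`: `SAS` (mm, NA when undefined),
#'   `peakProminence`, `arOrder`, `defined`, `nLinesDefined`.
#' @export
estimateSAS <- function(block, acq, planarReference = NULL, arOrder = 40,
                        minProminenceDb = 3, maxSpacingCv = 0.25,
                        minPeaks = 3L) {
  if (arOrder < 2) stopf("arOrder must be >= 2")
  if (minPeaks < 2) stopf("minPeaks must be >= 2")
  x <- if (is.list(block)) block$samples else as.matrix(block)
  if (nrow(x) < arOrder + 10L)
    stopf("block must have at least arOrder + 10 samples per line")
  if (is.null(planarReference)) planarReference <- planarReferenceSpectrum(acq)
  fs <- acq@samplingRate
  band <- acq@band
  fGrid <- seq(band[1], band[2], length.out = 256L)
  refDb <- stats::approx(planarReference@frequencies, planarReference@powerDb,
                         fGrid, rule = 2)$y
  w <- hannWindow(nrow(x))
  sasLines <- rep(NA_real_, ncol(x))
  promLines <- rep(NA_real_, ncol(x))
  for (j in seq_len(ncol(x))) {
    seg <- x[, j] * w
    if (stats::sd(seg) == 0) next
    fit <- tryCatch(stats::ar.burg(seg, aic = FALSE, order.max = arOrder,
                                   demean = TRUE),
                    error = function(e) NULL)
    if (is.null(fit) || !length(fit$ar)) next
    sDb <- toDb(arPowerSpectrum(fit$ar, fit$var.pred, fGrid, fs)) - refDb
    pk <- findPeaks(sDb)
    pk <- pk[pk$prominence >= minProminenceDb, , drop = FALSE]
    if (nrow(pk) < minPeaks) next
    dF <- diff(fGrid[pk$index])
    cv <- if (length(dF) > 1L) stats::sd(dF) / mean(dF) else 0
    if (!is.finite(cv) || cv > maxSpacingCv) next
    sasLines[j] <- sasFromPeakSpacing(fGrid[pk$index], acq@soundSpeed)
    promLines[j] <- mean(pk$prominence)
  }
  nDef <- sum(is.finite(sasLines))
  defined <- nDef >= max(1L, ceiling(ncol(x) / 2))
  structure(list(
    SAS = if (defined) stats::median(sasLines, na.rm = TRUE) else NA_real_,
    peakProminence = if (nDef) mean(promLines, na.rm = TRUE) else NA_real_,
    arOrder = arOrder, defined = defined, nLinesDefined = nDef),
    class = "SpacingEstimate")
}

#' @export
print.SpacingEstimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("SpacingEstimate: SAS = %.3f mm (AR order %d, %d lines)\n",
                x$SAS, x$arOrder, x$nLinesDefined))
  else
    cat("SpacingEstimate: undefined (no prominent regular spectral comb)\n")
  invisible(x)
}
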