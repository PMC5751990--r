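#' @import methods
NULL

#' Acquisition configuration for an RF ultrasound frame
#'
#' Describes the transducer and digitizer settings that produced (or will
#' produce, for simulation) a radio-frequency frame: sampling rate, pulse
#' center frequency, usable analysis band, assumed sound speed, lateral line
#' pitch and the fractional -6 dB bandwidth of the transmit pulse.
#'
#' @slot samplingRate sampling frequency in Hz.
#' @slot centerFrequency pulse center frequency in Hz.
#' @slot band numeric length-2, analysis band `[f_lo, f_hi]` in Hz.
#' @slot soundSpeed assumed propagation speed in m/s.
#' @slot linePitch lateral spacing between adjacent RF lines in m.
#' @slot pulseBandwidthFraction fractional -6 dB bandwidth of the pulse
#'   (bandwidth / center frequency), dimensionless.
#'
#' @examples
#' acq <- AcquisitionConfig()
#' centerFrequency(acq)
#' @export
setClass("AcquisitionConfig",
  representation(
    samplingRate = "numeric",
    centerFrequency = "numeric",
    band = "numeric",
    soundSpeed = "numeric",
    linePitch = "numeric",
    pulseBandwidthFraction = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  for (s in c("samplingRate", "centerFrequency", "soundSpeed", "linePitch",
              "pulseBandwidthFraction")) {
    v <- slot(object, s)
    if (!isScalarNumber(v) || v <= 0) msg <- c(msg, paste0(s, " must be a positive number"))
  }
  b <- object@band
  if (length(b) != 2L || any(!is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
    msg <- c(msg, "band must be increasing positive [f_lo, f_hi]")
  else {
    if (!(b[1] < object@centerFrequency && object@centerFrequency < b[2]))
      msg <- c(msg, "center frequency must lie inside the band")
    if (object@samplingRate <= 2 * b[2])
      msg <- c(msg, "sampling rate must exceed twice the band upper edge")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionConfig
#'
#' Defaults mirror a clinical linear-array breast acquisition: 7 MHz center
#' frequency, a 4--9 MHz analysis band and a 40 MHz digitizer.
#'
#' @param samplingRate sampling frequency, Hz.
#' @param centerFrequency pulse center frequency, Hz.
#' @param band analysis band `c(f_lo, f_hi)`, Hz.
#' @param soundSpeed sound speed, m/s.
#' @param linePitch lateral line spacing, m.
#' @param pulseBandwidthFraction fractional -6 dB pulse bandwidth.
#' @return an \linkS4class{AcquisitionConfig} object.
#' @export
AcquisitionConfig <- function(samplingRate = 40e6,
                              centerFrequency = 7e6,
                              band = c(4e6, 9e6),
                              soundSpeed = 1540,
                              linePitch = 2e-4,
                              pulseBandwidthFraction = (band[2] - band[1]) / centerFrequency) {
  new("AcquisitionConfig",
      samplingRate = samplingRate, centerFrequency = centerFrequency,
      band = as.numeric(band), soundSpeed = soundSpeed, linePitch = linePitch,
      pulseBandwidthFraction = pulseBandwidthFraction)
}

#' Specification of a diffuse (optionally periodic) scattering phantom
#'
#' @slot effectiveRadius effective scatterer radius in micrometers.
#' @slot numberDensity scatterers per cubic millimeter.
#' @slot impedanceContrastVariance variance of the per-scatterer relative
#'   impedance contrast (dimensionless).
#' @slot attenuationSlope attenuation coefficient slope, dB/(cm*MHz).
#' @slot soundSpeed sound speed inside the phantom, m/s.
#' @slot extent numeric length-2, axial x lateral extent in millimeters.
#' @slot latticeSpacing axial spacing of a periodic scatterer lattice in
#'   millimeters, or `NA_real_` for a purely diffuse medium.
#' @slot latticeJitterFraction fractional positional jitter of lattice
#'   scatterers, in `[0, 1)`.
#' @export
setClass("PhantomSpec",
  representation(
    effectiveRadius = "numeric",
    numberDensity = "numeric",
    impedanceContrastVariance = "numeric",
    attenuationSlope = "numeric",
    soundSpeed = "numeric",
    extent = "numeric",
    latticeSpacing = "numeric",
    latticeJitterFraction = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!isScalarNumber(object@effectiveRadius) || object@effectiveRadius < 0)
    msg <- c(msg, "effectiveRadius must be >= 0")
  if (!isScalarNumber(object@numberDensity) || object@numberDensity <= 0)
    msg <- c(msg, "numberDensity must be > 0")
  if (!isScalarNumber(object@impedanceContrastVariance) || object@impedanceContrastVariance <= 0)
    msg <- c(msg, "impedanceContrastVariance must be > 0")
  if (!isScalarNumber(object@attenuationSlope) || object@attenuationSlope < 0)
    msg <- c(msg, "attenuationSlope must be >= 0")
  if (!isScalarNumber(object@soundSpeed) || object@soundSpeed <= 0)
    msg <- c(msg, "soundSpeed must be > 0")
  if (length(object@extent) != 2L || any(object@extent <= 0))
    msg <- c(msg, "extent must be positive axial x lateral mm")
  if (length(object@latticeSpacing) != 1L ||
      (!is.na(object@latticeSpacing) && object@latticeSpacing <= 0))
    msg <- c(msg, "latticeSpacing must be positive or NA")
  j <- object@latticeJitterFraction
  if (!is.numeric(j) || length(j) != 1L || is.na(j) || j < 0 || j >= 1)
    msg <- c(msg, "latticeJitterFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param effectiveRadius effective scatterer radius, micrometers.
#' @param numberDensity scatterer number density, mm^-3.
#' @param impedanceContrastVariance variance of scatterer impedance contrast.
#' @param attenuationSlope attenuation slope, dB/(cm*MHz).
#' @param soundSpeed sound speed, m/s.
#' @param extent axial x lateral extent, mm.
#' @param latticeSpacing axial lattice spacing in mm, or NA for diffuse-only.
#' @param latticeJitterFraction fractional jitter of lattice positions, [0,1).
#' @return a \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(effectiveRadius = 25,
                        numberDensity = 200,
                        impedanceContrastVariance = 1,
                        attenuationSlope = 0.576,
                        soundSpeed = 1540,
                        extent = c(25, 13),
                        latticeSpacing = NA_real_,
                        latticeJitterFraction = 0) {
  new("PhantomSpec",
      effectiveRadius = effectiveRadius, numberDensity = numberDensity,
      impedanceContrastVariance = impedanceContrastVariance,
      attenuationSlope = attenuationSlope, soundSpeed = soundSpeed,
      extent = as.numeric(extent), latticeSpacing = latticeSpacing,
      latticeJitterFraction = latticeJitterFraction)
}

#' Reference phantom specification
#'
#' Returns the specification of the calibration phantom used for
#' reference-phantom spectral normalization: glass-bead scatterers in a
#' homogeneous background with attenuation 0.576 dB/(cm*MHz) and sound speed
#' 1488 m/s.
#'
#' @param extent axial x lateral extent in mm (geometry should match the
#'   sample frames being normalized).
#' @return a \linkS4class{PhantomSpec}.
#' @export
referencePhantom <- function(extent = c(25, 13)) {
  PhantomSpec(effectiveRadius = 17.5, numberDensity = 200,
              impedanceContrastVariance = 1, attenuationSlope = 0.576,
              soundSpeed = 1488, extent = extent)
}

#' Raw radio-frequency ultrasound frame
#'
#' The pipeline's input container: a 2-D array of RF samples (axial samples in
#' rows, lateral lines in columns) plus the acquisition settings and the depth
#' of the first sample.
#'
#' @slot samples numeric matrix, axial samples x lines.
#' @slot acquisition an \linkS4class{AcquisitionConfig}.
#' @slot originDepth depth of the first axial sample, m.
#' @export
setClass("RFFrame",
  representation(
    samples = "matrix",
    acquisition = "AcquisitionConfig",
    originDepth = "numeric"
  )
)

setValidity("RFFrame", function(object) {
  msg <- character()
  if (!is.numeric(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be a finite numeric matrix")
  if (!isScalarNumber(object@originDepth) || object@originDepth < 0)
    msg <- c(msg, "originDepth must be a nonnegative number")
  if (length(msg)) msg else TRUE
})

#' Construct an RFFrame
#' @param samples numeric matrix (axial samples x lines).
#' @param acquisition an \linkS4class{AcquisitionConfig}.
#' @param originDepth depth of the first sample, m.
#' @return an \linkS4class{RFFrame}.
#' @export
RFFrame <- function(samples, acquisition, originDepth = 0.01) {
  new("RFFrame", samples = samples, acquisition = acquisition,
      originDepth = originDepth)
}

#' Averaged power spectrum of a window block
#'
#' @slot frequencies strictly increasing frequency grid, Hz.
#' @slot powerDb power in dB (10*log10 of linear power).
#' @slot nLinesAveraged number of RF lines averaged.
#' @slot depth depth of the window center, m (NA when not applicable).
#' @export
setClass("PowerSpectrum",
  representation(
    frequencies = "numeric",
    powerDb = "numeric",
    nLinesAveraged = "integer",
    depth = "numeric"
  )
)

setValidity("PowerSpectrum", function(object) {
  msg <- character()
  f <- object@frequencies
  if (length(f) < 2L || any(diff(f) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing, length >= 2")
  if (length(object@powerDb) != length(f))
    msg <- c(msg, "powerDb must match frequencies in length")
  if (length(msg)) msg else TRUE
})

#' Construct a PowerSpectrum
#' @param frequencies frequency grid, Hz.
#' @param powerDb power values, dB.
#' @param nLinesAveraged number of lines averaged into the estimate.
#' @param depth window-center depth in m (NA if not tied to a depth).
#' @return a \linkS4class{PowerSpectrum}.
#' @export
PowerSpectrum <- function(frequencies, powerDb, nLinesAveraged = 1L,
                          depth = NA_real_) {
  new("PowerSpectrum", frequencies = as.numeric(frequencies),
      powerDb = as.numeric(powerDb),
      nLinesAveraged = as.integer(nLinesAveraged), depth = depth)
}

#' Spatial map of a QUS parameter over the analysis-window grid
#'
#' @slot values numeric matrix on the window grid (axial x lateral windows).
#' @slot parameterName one of MBF, SS, SI, ACE, SAS, ASD, AAC.
#' @slot mask logical matrix, TRUE where the estimate is valid.
#' @slot units unit string for the parameter.
#' @slot gridGeometry list describing the window grid (window size, hop,
#'   origin) for traceability.
#' @export
setClass("ParametricMap",
  representation(
    values = "matrix",
    parameterName = "character",
    mask = "matrix",
    units = "character",
    gridGeometry = "list"
  )
)

setValidity("ParametricMap", function(object) {
  msg <- character()
  if (!all(dim(object@values) == dim(object@mask)))
    msg <- c(msg, "mask must have the same shape as values")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (!object@parameterName %in% c("MBF", "SS", "SI", "ACE", "SAS", "ASD", "AAC"))
    msg <- c(msg, "parameterName must be one of MBF/SS/SI/ACE/SAS/ASD/AAC")
  if (length(msg)) msg else TRUE
})

#' Construct a ParametricMap
#' @param values numeric matrix of per-window parameter values.
#' @param parameterName parameter name (MBF, SS, SI, ACE, SAS, ASD or AAC).
#' @param mask logical validity matrix; defaults to finite entries of values.
#' @param units unit string.
#' @param gridGeometry optional list of window-grid metadata.
#' @return a \linkS4class{ParametricMap}.
#' @export
ParametricMap <- function(values, parameterName,
                          mask = is.finite(values),
                          units = defaultUnits(parameterName),
                          gridGeometry = list()) {
  new("ParametricMap", values = values, parameterName = parameterName,
      mask = mask, units = units, gridGeometry = gridGeometry)
}

#' @noRd
defaultUnits <- function(parameterName) {
  switch(parameterName,
         MBF = "dBr", SS = "dBr/MHz", SI = "dBr",
         ACE = "dB/(cm*MHz)", SAS = "mm", ASD = "um", AAC = "dB/cm^3",
         "")
}

#' Synthetic patient-cohort specification
#'
#' Defines the three response groups (CR/PR/NR), their molecular-marker
#' positivity rates, the per-group treatment trajectories of the QUS/texture
#' features, per-feature noise, and exponential recurrence hazards.
#'
#' @slot groupSizes named integer vector, counts for CR, PR, NR.
#' @slot molecularRates 3x3 numeric matrix, rows CR/PR/NR, columns
#'   ER/PR/HER2: probability that the marker is positive in that group.
#' @slot trajectoryEffects named list (CR, PR, NR), each a feature-by-week
#'   matrix of additive mean shifts at weeks 0/1/4/8 (columns).
#' @slot noiseScales named numeric vector of per-feature dispersions.
#' @slot recurrenceRates named numeric vector of per-group exponential
#'   recurrence hazards, events per month.
#' @slot followupHorizon administrative censoring time, months.
#' @export
setClass("CohortSpec",
  representation(
    groupSizes = "integer",
    molecularRates = "matrix",
    trajectoryEffects = "list",
    noiseScales = "numeric",
    recurrenceRates = "numeric",
    followupHorizon = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  gs <- object@groupSizes
  if (length(gs) != 3L || is.null(names(gs)) ||
      !identical(sort(names(gs)), sort(c("CR", "PR", "NR"))))
    msg <- c(msg, "groupSizes must be named CR, PR, NR")
  else if (any(gs < 0))
    msg <- c(msg, "group sizes must be >= 0")
  else if (sum(gs) == 0)
    msg <- c(msg, "at least one group must be nonempty")
  mr <- object@molecularRates
  if (!all(dim(mr) == c(3L, 3L)) || any(mr < 0) || any(mr > 1))
    msg <- c(msg, "molecularRates must be a 3x3 matrix of probabilities")
  if (any(object@recurrenceRates < 0))
    msg <- c(msg, "recurrence hazards must be >= 0")
  if (!isScalarNumber(object@followupHorizon) || object@followupHorizon <= 0)
    msg <- c(msg, "followupHorizon must be positive")
  if (length(msg)) msg else TRUE
})
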