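#' Accessors for qusrm S4 containers
#'
#' Slot access goes through these accessors rather than `@`.
#'
#' @param object a qusrm S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rfSamples", function(object) standardGeneric("rfSamples"))
#' @rdname accessors
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))
#' @rdname accessors
#' @export
setGeneric("originDepth", function(object) standardGeneric("originDepth"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("centerFrequency", function(object) standardGeneric("centerFrequency"))
#' @rdname accessors
#' @export
setGeneric("analysisBand", function(object) standardGeneric("analysisBand"))
#' @rdname accessors
#' @export
setGeneric("soundSpeed", function(object) standardGeneric("soundSpeed"))
#' @rdname accessors
#' @export
setGeneric("linePitch", function(object) standardGeneric("linePitch"))
#' @rdname accessors
#' @export
setGeneric("spectrumFrequencies", function(object) standardGeneric("spectrumFrequencies"))
#' @rdname accessors
#' @export
setGeneric("powerDb", function(object) standardGeneric("powerDb"))
#' @rdname accessors
#' @export
setGeneric("spectrumDepth", function(object) standardGeneric("spectrumDepth"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("mapMask", function(object) standardGeneric("mapMask"))
#' @rdname accessors
#' @export
setGeneric("parameterName", function(object) standardGeneric("parameterName"))
#' @rdname accessors
#' @export
setGeneric("mapUnits", function(object) standardGeneric("mapUnits"))

#' @rdname accessors
#' @export
setMethod("rfSamples", "RFFrame", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("acquisition", "RFFrame", function(object) object@acquisition)
#' @rdname accessors
#' @export
setMethod("originDepth", "RFFrame", function(object) object@originDepth)

#' @rdname accessors
#' @export
setMethod("samplingRate", "AcquisitionConfig", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("centerFrequency", "AcquisitionConfig", function(object) object@centerFrequency)
#' @rdname accessors
#' @export
setMethod("analysisBand", "AcquisitionConfig", function(object) object@band)
#' @rdname accessors
#' @export
setMethod("soundSpeed", "AcquisitionConfig", function(object) object@soundSpeed)
#' @rdname accessors
#' @export
setMethod("linePitch", "AcquisitionConfig", function(object) object@linePitch)

#' @rdname accessors
#' @export
setMethod("spectrumFrequencies", "PowerSpectrum", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("powerDb", "PowerSpectrum", function(object) object@powerDb)
#' @rdname accessors
#' @export
setMethod("spectrumDepth", "PowerSpectrum", function(object) object@depth)

#' @rdname accessors
#' @export
setMethod("mapValues", "ParametricMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("mapMask", "ParametricMap", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("parameterName", "ParametricMap", function(object) object@parameterName)
#' @rdname accessors
#' @export
setMethod("mapUnits", "ParametricMap", function(object) object@units)

#' Acoustic wavelength at the pulse center frequency
#'
#' @param object an \linkS4class{AcquisitionConfig}.
#' @return wavelength in meters, `soundSpeed / centerFrequency`.
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))
#' @rdname wavelength
#' @export
setMethod("wavelength", "AcquisitionConfig",
          function(object) object@soundSpeed / object@centerFrequency)

#' Mean of the unmasked cells of a parametric map
#'
#' This is the "mean QUS value" feature: the arithmetic mean over valid
#' window-grid cells.
#'
#' @param object a \linkS4class{ParametricMap}.
#' @return a single number, or NA if no cell is valid.
#' @export
setGeneric("mapMean", function(object) standardGeneric("mapMean"))
#' @rdname mapMean
#' @export
setMethod("mapMean", "ParametricMap", function(object) {
  v <- object@values[object@mask]
  if (!length(v)) return(NA_real_)
  mean(v)
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig:",
      sprintf("fc = %.2f MHz, band = %.1f-%.1f MHz, fs = %.1f MHz",
              object@centerFrequency / 1e6, object@band[1] / 1e6,
              object@band[2] / 1e6, object@samplingRate / 1e6), "\n")
  cat(sprintf("  c = %.0f m/s, pitch = %.3f mm, fractional BW = %.2f\n",
              object@soundSpeed, object@linePitch * 1e3,
              object@pulseBandwidthFraction))
})

setMethod("show", "RFFrame", function(object) {
  d <- dim(object@samples)
  cat(sprintf("RFFrame: %d samples x %d lines, origin depth %.1f mm\n",
              d[1], d[2], object@originDepth * 1e3))
  show(object@acquisition)
})

setMethod("show", "PowerSpectrum", function(object) {
  f <- object@frequencies
  cat(sprintf("PowerSpectrum: %d bins, %.2f-%.2f MHz, %d line(s) averaged\n",
              length(f), min(f) / 1e6, max(f) / 1e6, object@nLinesAveraged))
})

setMethod("show", "ParametricMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ParametricMap[%s]: %d x %d windows, %d valid, mean %.3g %s\n",
              object@parameterName, d[1], d[2], sum(object@mask),
              mapMean(object), object@units))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: a_eff = %.1f um, density = %.0f /mm^3, alpha = %.3f dB/(cm*MHz), c = %.0f m/s\n",
    object@effectiveRadius, object@numberDensity, object@attenuationSlope,
    object@soundSpeed))
  if (!is.na(object@latticeSpacing))
    cat(sprintf("  axial lattice: %.2f mm spacing, %.1f%% jitter\n",
                object@latticeSpacing, 100 * object@latticeJitterFraction))
})

setMethod("show", "CohortSpec", function(object) {
  gs <- object@groupSizes
  cat(sprintf("CohortSpec: CR = %d, PR = %d, NR = %d; follow-up %.0f months\n",
              gs[["CR"]], gs[["PR"]], gs[["NR"]], object@followupHorizon))
})
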