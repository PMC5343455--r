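#' Accessors for uvholo containers
#'
#' Small accessor layer so user code never reaches into slots:
#' \code{fieldValues} (complex grid), \code{pitch}, \code{wavelength},
#' \code{amplitude}, \code{phase}, \code{coverage}, \code{shiftTable} and
#' \code{frames}.
#'
#' @param object one of the package's containers.
#' @param ... for \code{shiftTable} on a [FrameStack-class]:
#'   \code{which = "nominal"} or \code{"estimated"}.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("fieldValues", "ComplexField", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("fieldValues", "HighResHologram", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("pitch", "ComplexField", function(object) object@pitch)

#' @rdname accessors
#' @export
setMethod("pitch", "HighResHologram", function(object) object@pitch)

#' @rdname accessors
#' @export
setMethod("pitch", "FrameStack", function(object) object@pitch)

#' @rdname accessors
#' @export
setMethod("pitch", "Reconstruction", function(object) object@pitch)

#' @rdname accessors
#' @export
setMethod("wavelength", "ComplexField", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("wavelength", "HighResHologram", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("wavelength", "FrameStack", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("wavelength", "Reconstruction", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("amplitude", "ComplexField", function(object) Mod(object@values))

#' @rdname accessors
#' @export
setMethod("amplitude", "Reconstruction", function(object) object@amplitude)

#' @rdname accessors
#' @export
setMethod("phase", "ComplexField", function(object) Arg(object@values))

#' @rdname accessors
#' @export
setMethod("phase", "Reconstruction", function(object) object@phase)

#' @rdname accessors
#' @export
setMethod("coverage", "HighResHologram", function(object) object@coverage)

#' @rdname accessors
#' @export
setMethod("shiftTable", "AcquisitionPattern", function(object, ...)
  object@shifts)

#' @rdname accessors
#' @export
setMethod("shiftTable", "FrameStack",
  function(object, which = c("nominal", "estimated")) {
    which <- match.arg(which)
    if (which == "nominal") object@nominalShifts else object@estimatedShifts
  })

#' @rdname accessors
#' @export
setMethod("frames", "FrameStack", function(object) object@frames)

#' @rdname accessors
#' @export
setMethod("length", "AcquisitionPattern", function(x) nrow(x@shifts))

#' @rdname accessors
#' @export
setMethod("length", "FrameStack", function(x) length(x@frames))

#' @rdname accessors
#' @export
setMethod("dim", "ComplexField", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("dim", "HighResHologram", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("dim", "Reconstruction", function(x) dim(x@amplitude))

setMethod("show", "ComplexField", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ComplexField: %d x %d grid, pitch %.4g um, lambda %.4g um (n = %g)\n",
    d[1], d[2], object@pitch, object@wavelength, object@mediumIndex))
})

setMethod("show", "AcquisitionPattern", function(object) {
  k <- table(factor(object@shifts$kind,
                    levels = c("rectangular", "circular")))
  cat(sprintf(
    "AcquisitionPattern: %d positions (%d rectangular, %d circular)\n",
    nrow(object@shifts), k[["rectangular"]], k[["circular"]]))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf(
    "FrameStack: %d frames of %d x %d (%s), pitch %.3g um%s\n",
    length(object@frames), d[1], d[2], object@bayer, object@pitch,
    if (nrow(object@estimatedShifts)) ", shifts estimated" else ""))
})

setMethod("show", "HighResHologram", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "HighResHologram: %d x %d grid, pitch %.3g um, %s-valued\n",
    d[1], d[2], object@pitch,
    if (is.complex(object@values)) "complex" else "real"))
})

setMethod("show", "Reconstruction", function(object) {
  d <- dim(object@amplitude)
  cat(sprintf(
    "Reconstruction at z2 = %.4g um: %d x %d grid, pitch %.3g um\n",
    object@z2, d[1], d[2], object@pitch))
})

setMethod("show", "FocusCurve", function(object) {
  cat(sprintf(
    "FocusCurve: %d heights in [%.4g, %.4g] um, peak phase %.4g at %.4g um\n",
    length(object@z), min(object@z), max(object@z),
    max(object@peakPhase), object@z[which.max(object@peakPhase)]))
})

setMethod("show", "SensorModel", function(object) {
  cat(sprintf(
    "SensorModel: %.3g um pitch, %s, %d-bit, gain %g, read sigma %g%s\n",
    object@pixelPitch, object@bayer, object@bitDepth, object@gain,
    object@readNoiseSigma, if (object@shotNoise) ", shot noise" else ""))
})

setMethod("show", "NoiseScene", function(object) {
  cat(sprintf(
    "NoiseScene: %d parasitic plane(s), speckle contrast %g (corr %g um)\n",
    nrow(object@parasitic), object@speckleContrast,
    object@speckleCorrLength))
})
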