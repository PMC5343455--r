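#' @import methods
NULL

#' ComplexField: a sampled 2D complex optical field
#'
#' Container for a scalar complex field sampled on a regular rectangular
#' grid, together with the metadata needed to propagate it: grid pitch,
#' vacuum wavelength and the (real) refractive index of the propagation
#' medium. All lateral lengths are in micrometres.
#'
#' @slot values complex matrix of field amplitudes (dimensionless).
#' @slot pitch grid spacing in micrometres.
#' @slot wavelength vacuum wavelength in micrometres (0.266 for the deep-UV
#'   platform this package models).
#' @slot mediumIndex real refractive index of the uniform medium between the
#'   planes of interest (default 1, air).
#'
#' @seealso [ComplexField()], [propagate()]
#' @exportClass ComplexField
setClass("ComplexField",
  representation(
    values = "matrix",
    pitch = "numeric",
    wavelength = "numeric",
    mediumIndex = "numeric"
  ),
  prototype(pitch = 1.12, wavelength = 0.266, mediumIndex = 1)
)

setValidity("ComplexField", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.complex(v) && !is.numeric(v))
    msgs <- c(msgs, "'values' must be a numeric or complex matrix")
  if (length(dim(v)) != 2L || any(dim(v) < 2L))
    msgs <- c(msgs, "field grid must be at least 2x2")
  if (length(object@pitch) != 1L || !is.finite(object@pitch) ||
      object@pitch <= 0)
    msgs <- c(msgs, "'pitch' must be a single positive number")
  if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msgs <- c(msgs, "'wavelength' must be a single positive number")
  if (length(object@mediumIndex) != 1L || !is.finite(object@mediumIndex) ||
      object@mediumIndex < 1)
    msgs <- c(msgs, "'mediumIndex' must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ComplexField
#'
#' @param values numeric or complex matrix; numeric input is promoted to
#'   complex with zero imaginary part.
#' @param pitch grid spacing, micrometres.
#' @param wavelength vacuum wavelength, micrometres.
#' @param mediumIndex real refractive index (>= 1).
#' @return A [ComplexField-class] object.
#' @examples
#' f <- ComplexField(matrix(1 + 0i, 8, 8), pitch = 0.28)
#' dim(f)
#' @export
ComplexField <- function(values, pitch = 1.12, wavelength = 0.266,
                         mediumIndex = 1) {
  if (is.numeric(values)) storage.mode(values) <- "complex"
  new("ComplexField", values = values, pitch = pitch,
      wavelength = wavelength, mediumIndex = mediumIndex)
}

#' AcquisitionPattern: ordered lateral hologram shifts
#'
#' An ordered table of target hologram displacements on the sensor, each
#' tagged \code{"rectangular"} (sub-pixel shifts that build resolution) or
#' \code{"circular"} (concentric-circle shifts whose accumulation smears
#' coherent noise that does not co-move with the sample plane).
#'
#' @slot shifts data.frame with columns \code{dx}, \code{dy} (micrometres)
#'   and \code{kind} (\code{"rectangular"} or \code{"circular"}).
#' @seealso [makePattern()]
#' @exportClass AcquisitionPattern
setClass("AcquisitionPattern", representation(shifts = "data.frame"))

setValidity("AcquisitionPattern", function(object) {
  s <- object@shifts
  if (!all(c("dx", "dy", "kind") %in% names(s)))
    return("'shifts' needs columns dx, dy, kind")
  if (!all(s$kind %in% c("rectangular", "circular")))
    return("'kind' must be 'rectangular' or 'circular'")
  if (any(!is.finite(s$dx)) || any(!is.finite(s$dy)))
    return("shift entries must be finite")
  TRUE
})

#' SensorModel: CMOS sensor parameters
#'
#' @slot pixelPitch pixel pitch, micrometres (default 1.12).
#' @slot bayer \code{"RGGB"} or \code{"mono"}.
#' @slot bitDepth ADC bit depth, one of 8, 10, 12, 16.
#' @slot readNoiseSigma read-noise standard deviation, counts.
#' @slot shotNoise logical; Poisson photon noise on/off.
#' @slot gain counts per unit optical intensity.
#' @slot rbResponse relative response of red/blue Bayer sites to the
#'   illumination (0 by default: at 266 nm only the green channel responds).
#' @seealso [sensorModel()]
#' @exportClass SensorModel
setClass("SensorModel",
  representation(
    pixelPitch = "numeric", bayer = "character", bitDepth = "numeric",
    readNoiseSigma = "numeric", shotNoise = "logical", gain = "numeric",
    rbResponse = "numeric"
  )
)

setValidity("SensorModel", function(object) {
  msgs <- character()
  if (object@pixelPitch <= 0) msgs <- c(msgs, "pixelPitch must be > 0")
  if (!object@bayer %in% c("RGGB", "mono"))
    msgs <- c(msgs, "bayer must be 'RGGB' or 'mono'")
  if (!object@bitDepth %in% c(8, 10, 12, 16))
    msgs <- c(msgs, "bitDepth must be one of 8, 10, 12, 16")
  if (object@readNoiseSigma < 0) msgs <- c(msgs, "readNoiseSigma must be >= 0")
  if (object@gain <= 0) msgs <- c(msgs, "gain must be > 0")
  if (object@rbResponse < 0 || object@rbResponse > 1)
    msgs <- c(msgs, "rbResponse must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SensorModel
#'
#' Defaults describe the 1.12-um-pitch RGGB CMOS sensor of the UV platform:
#' 16-bit readout, only the green Bayer sites responsive to 266-nm light.
#'
#' @param pixelPitch pixel pitch, micrometres.
#' @param bayer \code{"RGGB"} or \code{"mono"}.
#' @param bitDepth ADC bit depth (8, 10, 12 or 16).
#' @param readNoiseSigma read noise, counts.
#' @param shotNoise logical, Poisson shot noise.
#' @param gain counts per unit intensity (sets the background level on the
#'   ADC scale; the default puts a unit-intensity background near 30% of
#'   the 16-bit full scale).
#' @param rbResponse relative red/blue response in [0, 1].
#' @return A [SensorModel-class] object.
#' @export
sensorModel <- function(pixelPitch = 1.12, bayer = c("RGGB", "mono"),
                        bitDepth = 16, readNoiseSigma = 2,
                        shotNoise = TRUE, gain = 20000, rbResponse = 0) {
  bayer <- match.arg(bayer)
  new("SensorModel", pixelPitch = pixelPitch, bayer = bayer,
      bitDepth = bitDepth, readNoiseSigma = readNoiseSigma,
      shotNoise = shotNoise, gain = gain, rbResponse = rbResponse)
}

#' NoiseScene: coherent background noise of the illumination train
#'
#' Describes coherent noise that a highly coherent laser source produces in
#' an on-chip geometry: parasitic interference fringes from reflections at
#' planes far from the sample, and a frozen speckle field. Because these
#' planes sit at heights different from the sample height, tilting the
#' illumination displaces them by different amounts than the object
#' holograms, which is exactly what circular-averaging pixel
#' super-resolution exploits.
#'
#' @slot parasitic data.frame with columns \code{height} (um),
#'   \code{amplitude} (relative to the unit background field),
#'   \code{orientation} (degrees) and \code{period} (um) of the fringe.
#' @slot speckleContrast relative amplitude of the frozen speckle field
#'   (0 disables it).
#' @slot speckleCorrLength speckle correlation length, micrometres.
#' @slot speckleHeight height of the plane carrying the speckle, um.
#' @slot speckleSeed integer seed freezing the speckle realization, so that
#'   it is identical across the frames of one stack.
#' @seealso [noiseScene()]
#' @exportClass NoiseScene
setClass("NoiseScene",
  representation(
    parasitic = "data.frame", speckleContrast = "numeric",
    speckleCorrLength = "numeric", speckleHeight = "numeric",
    speckleSeed = "numeric"
  )
)

setValidity("NoiseScene", function(object) {
  p <- object@parasitic
  msgs <- character()
  if (nrow(p)) {
    if (!all(c("height", "amplitude", "orientation", "period") %in% names(p)))
      return("'parasitic' needs columns height, amplitude, orientation, period")
    if (any(p$amplitude < 0)) msgs <- c(msgs, "fringe amplitudes must be >= 0")
    if (any(p$height <= 0)) msgs <- c(msgs, "parasitic heights must be > 0")
    if (any(p$period <= 0)) msgs <- c(msgs, "fringe periods must be > 0")
  }
  if (object@speckleContrast < 0) msgs <- c(msgs, "speckleContrast >= 0")
  if (object@speckleCorrLength <= 0) msgs <- c(msgs, "speckleCorrLength > 0")
  if (object@speckleHeight <= 0) msgs <- c(msgs, "speckleHeight > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a NoiseScene
#'
#' The defaults model two oblique parasitic reflections (1 mm and 5 mm above
#' the sensor) plus a weak frozen speckle field, strong enough that a
#' rectangular-only super-resolved hologram retains visible background
#' structure which circular averaging then suppresses.
#'
#' @param parasitic data.frame(height, amplitude, orientation, period); pass
#'   a zero-row data.frame to disable fringes.
#' @param speckleContrast relative speckle amplitude (0 disables).
#' @param speckleCorrLength correlation length, um.
#' @param speckleHeight speckle plane height, um.
#' @param speckleSeed integer freezing the speckle realization.
#' @return A [NoiseScene-class] object.
#' @export
noiseScene <- function(parasitic = data.frame(
                         height = c(1000, 5000),
                         amplitude = c(0.03, 0.02),
                         orientation = c(25, 115),
                         period = c(9, 5.5)),
                       speckleContrast = 0.04, speckleCorrLength = 5,
                       speckleHeight = 2000, speckleSeed = 421) {
  new("NoiseScene", parasitic = parasitic, speckleContrast = speckleContrast,
      speckleCorrLength = speckleCorrLength, speckleHeight = speckleHeight,
      speckleSeed = speckleSeed)
}

#' Quiet noise scene (no fringes, no speckle)
#' @return A [NoiseScene-class] with all coherent noise disabled.
#' @export
quietScene <- function() {
  noiseScene(parasitic = data.frame(height = numeric(), amplitude = numeric(),
                                    orientation = numeric(),
                                    period = numeric()),
             speckleContrast = 0)
}

#' FrameStack: raw low-resolution intensity frames with their shifts
#'
#' @slot frames list of equally sized numeric matrices (raw sensor counts).
#' @slot nominalShifts data.frame(dx, dy) of intended hologram displacements
#'   on the sensor, micrometres; one row per frame.
#' @slot estimatedShifts data.frame(dx, dy) filled by [estimateShifts()]
#'   (zero rows until then).
#' @slot pitch native sensor pitch, micrometres.
#' @slot wavelength vacuum wavelength, micrometres (carried along so that
#'   downstream holograms can be reconstructed without extra bookkeeping).
#' @slot bayer Bayer pattern of the frames (\code{"RGGB"} or \code{"mono"}).
#' @exportClass FrameStack
setClass("FrameStack",
  representation(
    frames = "list", nominalShifts = "data.frame",
    estimatedShifts = "data.frame", pitch = "numeric",
    wavelength = "numeric", bayer = "character"
  ),
  prototype(estimatedShifts = data.frame(dx = numeric(), dy = numeric()),
            wavelength = 0.266, bayer = "mono")
)

setValidity("FrameStack", function(object) {
  fr <- object@frames
  if (!length(fr)) return("stack contains no frames")
  d <- dim(fr[[1]])
  if (!all(vapply(fr, function(m) identical(dim(m), d), logical(1))))
    return("all frames must share the same shape")
  if (nrow(object@nominalShifts) != length(fr))
    return("nominalShifts must have one row per frame")
  if (nrow(object@estimatedShifts) &&
      nrow(object@estimatedShifts) != length(fr))
    return("estimatedShifts must be empty or one row per frame")
  if (object@pitch <= 0) return("pitch must be > 0")
  TRUE
})

#' Construct a FrameStack
#' @param frames list of numeric matrices.
#' @param nominalShifts data.frame(dx, dy), micrometres.
#' @param pitch native pixel pitch, micrometres.
#' @param wavelength vacuum wavelength, micrometres.
#' @param bayer \code{"RGGB"} or \code{"mono"}.
#' @return A [FrameStack-class].
#' @export
FrameStack <- function(frames, nominalShifts = NULL, pitch = 1.12,
                       wavelength = 0.266, bayer = "mono") {
  if (is.null(nominalShifts))
    nominalShifts <- data.frame(dx = numeric(length(frames)),
                                dy = numeric(length(frames)))
  new("FrameStack", frames = frames, nominalShifts = nominalShifts,
      pitch = pitch, wavelength = wavelength, bayer = bayer)
}

#' HighResHologram: super-resolved in-line hologram
#'
#' Output of shift-and-add pixel super-resolution (real-valued intensity),
#' or of digital object peeling (complex-valued field).
#'
#' @slot values numeric or complex matrix on the fine grid.
#' @slot pitch effective pitch = native pitch / upsampling factor, um.
#' @slot coverage integer matrix of per-cell accumulation counts (cells that
#'   received no frame sample and were interpolated carry a 0).
#' @slot wavelength vacuum wavelength, um.
#' @exportClass HighResHologram
setClass("HighResHologram",
  representation(values = "matrix", pitch = "numeric", coverage = "matrix",
                 wavelength = "numeric"),
  prototype(wavelength = 0.266)
)

setValidity("HighResHologram", function(object) {
  if (length(dim(object@values)) != 2L) return("values must be a matrix")
  if (object@pitch <= 0) return("pitch must be > 0")
  if (length(object@coverage) &&
      !identical(dim(object@coverage), dim(object@values)))
    return("coverage must match values in shape")
  TRUE
})

#' Construct a HighResHologram
#' @param values numeric or complex matrix.
#' @param pitch effective pitch, micrometres.
#' @param coverage per-cell accumulation counts (optional).
#' @param wavelength vacuum wavelength, micrometres.
#' @return A [HighResHologram-class].
#' @export
HighResHologram <- function(values, pitch, coverage = NULL,
                            wavelength = 0.266) {
  if (is.null(coverage))
    coverage <- matrix(1L, nrow(values), ncol(values))
  new("HighResHologram", values = values, pitch = pitch,
      coverage = coverage, wavelength = wavelength)
}

#' Reconstruction: amplitude and phase of a back-propagated hologram
#'
#' @slot amplitude non-negative real matrix.
#' @slot phase real matrix, radians in (-pi, pi].
#' @slot z2 reconstruction height above the sensor, micrometres.
#' @slot pitch grid pitch, micrometres.
#' @slot wavelength vacuum wavelength, micrometres.
#' @exportClass Reconstruction
setClass("Reconstruction",
  representation(amplitude = "matrix", phase = "matrix", z2 = "numeric",
                 pitch = "numeric", wavelength = "numeric")
)

setValidity("Reconstruction", function(object) {
  if (!identical(dim(object@amplitude), dim(object@phase)))
    return("amplitude and phase must share a shape")
  if (any(object@amplitude < 0)) return("amplitude must be >= 0")
  TRUE
})

#' FocusCurve: peak compensated phase versus reconstruction height
#'
#' @slot z heights, micrometres; strictly increasing with uniform step.
#' @slot peakPhase peak compensated-phase value in the candidate window at
#'   each height (dimensionless; background sits near 1).
#' @exportClass FocusCurve
setClass("FocusCurve", representation(z = "numeric", peakPhase = "numeric"))

setValidity("FocusCurve", function(object) {
  if (length(object@z) != length(object@peakPhase))
    return("z and peakPhase must have equal length")
  if (length(object@z) > 1) {
    dz <- diff(object@z)
    if (any(dz <= 0)) return("z must be strictly increasing")
    if (diff(range(dz)) > 1e-9 * max(dz)) return("z step must be uniform")
  }
  TRUE
})
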