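#' Propagate a field by a signed distance
#'
#' Free-space scalar propagation by the angular spectrum method. Positive
#' \code{dz} moves from the sensor toward the sample; reconstruction of a
#' recorded hologram therefore uses a negative \code{dz}
#' (see [backpropagate()]).
#'
#' @param field a [ComplexField-class].
#' @param dz signed propagation distance, micrometres.
#' @param ... further arguments (\code{pad}, a zero-padding factor for the
#'   FFT window; default 1, i.e. periodic boundary).
#' @return A [ComplexField-class] with the same grid.
#' @export
setGeneric("propagate", function(field, dz, ...) standardGeneric("propagate"))

#' Gaussian low-pass filter in the frequency domain
#'
#' Multiplies the 2D spectrum by a Gaussian of standard deviation
#' \code{cutoff} (cycles per micrometre). The DC component, and hence the
#' image mean, is preserved exactly.
#'
#' @param x real matrix, [ComplexField-class] or [HighResHologram-class].
#' @param cutoff filter standard deviation, 1/um; must be positive.
#' @param ... further arguments; for plain matrices, \code{pitch} (um).
#' @return Same type as the input.
#' @export
setGeneric("lowpass", function(x, cutoff, ...) standardGeneric("lowpass"))

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(object) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setGeneric("pitch", function(object) standardGeneric("pitch"))

#' @rdname accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname accessors
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))

#' @rdname accessors
#' @export
setGeneric("phase", function(object) standardGeneric("phase"))

#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setGeneric("shiftTable", function(object, ...) standardGeneric("shiftTable"))

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
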