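#' Build the acquisition pattern of target hologram shifts
#'
#' The platform's acquisition combines a rectangular sub-pixel grid of
#' shifts (which raises the sampling rate of the super-resolved hologram)
#' with frames shifted on concentric circles (whose accumulation smears out
#' coherent noise that originates away from the sample plane). The default
#' arguments reproduce the instrument's recipe: a 14-per-side grid at
#' ~0.16 um plus 12 circles at 0.3 um radial spacing with 30 positions per
#' circle at equal angular intervals -- 556 positions in total.
#'
#' @param rectN positions per side of the rectangular grid (rectN^2 total),
#'   centred on zero shift.
#' @param rectStep rectangular grid step, micrometres.
#' @param nCircles number of concentric circles.
#' @param radialStep radial spacing between circles, micrometres (circle k
#'   has radius \code{k * radialStep}).
#' @param perCircle positions per circle, equally spaced starting at 0
#'   degrees.
#' @return An [AcquisitionPattern-class] with
#'   \code{rectN^2 + nCircles * perCircle} entries, rectangular first.
#' @examples
#' p <- makePattern()
#' length(p)  # 556
#' @export
makePattern <- function(rectN = 14, rectStep = 0.16, nCircles = 12,
                        radialStep = 0.3, perCircle = 30) {
  if (rectN < 0 || nCircles < 0 || perCircle < 0)
    stop("counts must be non-negative")
  if (rectN > 0 && rectStep <= 0)
    stop("'rectStep' must be positive when rectN > 0")
  if (nCircles > 0 && (radialStep <= 0 || perCircle <= 0))
    stop("'radialStep' and 'perCircle' must be positive when nCircles > 0")
  rect <- if (rectN > 0) {
    pos <- (seq_len(rectN) - (rectN + 1) / 2) * rectStep
    g <- expand.grid(dx = pos, dy = pos)
    data.frame(dx = g$dx, dy = g$dy, kind = "rectangular",
               stringsAsFactors = FALSE)
  } else data.frame(dx = numeric(), dy = numeric(), kind = character())
  circ <- if (nCircles > 0 && perCircle > 0) {
    ang <- 2 * pi * (seq_len(perCircle) - 1) / perCircle
    do.call(rbind, lapply(seq_len(nCircles), function(k) {
      r <- k * radialStep
      data.frame(dx = r * cos(ang), dy = r * sin(ang), kind = "circular",
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(dx = numeric(), dy = numeric(), kind = character())
  new("AcquisitionPattern", shifts = rbind(rect, circ))
}

#' Illumination tilt producing a given hologram shift
#'
#' In the on-chip geometry a tilt of the incident beam displaces an object's
#' in-line hologram on the sensor by \code{z2 * tan(theta)} per axis, so the
#' tilt required for a target shift is \code{theta = atan(shift / z2)}.
#'
#' @param shift numeric length-2, target hologram shift (dx, dy) in
#'   micrometres.
#' @param z2 sample-to-sensor distance, micrometres; must be positive.
#' @return Numeric length-2 tilt (theta_x, theta_y) in degrees.
#' @examples
#' tiltForShift(c(0.16, 0), 500)  # ~0.0183 degrees in x
#' @export
tiltForShift <- function(shift, z2) {
  if (length(z2) != 1L || !is.finite(z2) || z2 <= 0)
    stop("'z2' must be a single positive height in micrometres")
  stopifnot(length(shift) == 2L, all(is.finite(shift)))
  atan(shift / z2) * 180 / pi
}

#' Hologram shift produced by an illumination tilt
#' @param tilt numeric length-2 tilt (theta_x, theta_y), degrees.
#' @param z2 sample-to-sensor distance, micrometres.
#' @return Numeric length-2 shift (dx, dy), micrometres.
#' @export
shiftForTilt <- function(tilt, z2) {
  if (z2 <= 0) stop("'z2' must be positive")
  z2 * tan(tilt * pi / 180)
}

#' Calibrate the tilt-to-shift map from reference observations
#'
#' A one-time calibration: a few frames are captured at predefined mirror
#' tilts (up to ~0.2 degrees) and the resulting hologram shifts are measured
#' on a visible mark at the sample plane. A through-origin least-squares
#' slope (micrometres per degree) is fitted per axis; the full acquisition
#' shift table is then generated by inverting the map for each target shift.
#'
#' @param observations data.frame with columns \code{tilt_x}, \code{tilt_y}
#'   (degrees) and \code{shift_x}, \code{shift_y} (micrometres); at least 3
#'   rows, not all tilts identical.
#' @return An object of class \code{"shiftCalibration"}: list with per-axis
#'   slopes (um/deg).
#' @examples
#' obs <- data.frame(tilt_x = c(0, 0.1, 0.2), tilt_y = c(0, 0.1, 0.2),
#'                   shift_x = c(0, 0.87, 1.74), shift_y = c(0, 0.87, 1.74))
#' calibrateShiftMap(obs)
#' @export
calibrateShiftMap <- function(observations) {
  need <- c("tilt_x", "tilt_y", "shift_x", "shift_y")
  if (!all(need %in% names(observations)))
    stop("'observations' needs columns ", paste(need, collapse = ", "))
  if (nrow(observations) < 3L)
    stop("at least 3 calibration observations are required")
  slope1 <- function(t, s) {
    if (sum(t^2) == 0) stop("degenerate calibration: all tilts are zero")
    sum(t * s) / sum(t^2)
  }
  if (all(observations$tilt_x == observations$tilt_x[1]) &&
      all(observations$tilt_y == observations$tilt_y[1]))
    stop("degenerate calibration: tilts do not vary")
  out <- list(slope_x = slope1(observations$tilt_x, observations$shift_x),
              slope_y = slope1(observations$tilt_y, observations$shift_y))
  class(out) <- "shiftCalibration"
  out
}

#' @export
print.shiftCalibration <- function(x, ...) {
  cat(sprintf("shiftCalibration: slope_x = %.4g, slope_y = %.4g um/deg\n",
              x$slope_x, x$slope_y))
  invisible(x)
}

#' Mirror tilts realizing an acquisition pattern
#'
#' Inverts a [calibrateShiftMap()] fit for each target shift of a pattern.
#'
#' @param cal a \code{"shiftCalibration"}.
#' @param pattern an [AcquisitionPattern-class].
#' @return data.frame(tilt_x, tilt_y) in degrees, one row per position.
#' @export
patternTilts <- function(cal, pattern) {
  s <- shiftTable(pattern)
  data.frame(tilt_x = s$dx / cal$slope_x, tilt_y = s$dy / cal$slope_y)
}
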