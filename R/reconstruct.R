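#' Back-propagate a hologram to the object plane
#'
#' Lifts the measured hologram to a complex field (square root of the
#' non-negative intensity with zero phase, or the complex values themselves
#' after digital peeling) and propagates it by \code{-z2} with the angular
#' spectrum method, yielding the amplitude and phase images of the sample.
#'
#' @param holo a [HighResHologram-class].
#' @param z2 reconstruction height above the sensor, micrometres (> 0).
#' @return A [Reconstruction-class].
#' @export
backpropagate <- function(holo, z2) {
  if (length(z2) != 1L || !is.finite(z2) || z2 <= 0)
    stop("'z2' must be a single positive height in micrometres")
  v <- .pistonNormalize(propagate(hologramField(holo), -z2)@values)
  new("Reconstruction", amplitude = Mod(v), phase = Arg(v),
      z2 = z2, pitch = holo@pitch, wavelength = holo@wavelength)
}

#' Autofocus: find the reconstruction height of best focus
#'
#' Scans reconstructions over a height range and returns the height where
#' a particle comes to focus: for absorbing objects the windowed minimum
#' amplitude is smallest, and equivalently the windowed maximum phase is
#' largest, at the true height. Ties break toward the smaller height. If
#' the metric is flat over the scan (empty field), the lower bound is
#' returned with a flatness flag.
#'
#' @param holo a [HighResHologram-class].
#' @param zMin,zMax scan bounds, micrometres (zMin < zMax).
#' @param step scan step, micrometres (> 0).
#' @param criterion \code{"min_amplitude"} or \code{"max_phase"}.
#' @param window list(rows =, cols =) restricting the metric to a window
#'   (e.g. around one particle), or NULL for the whole field.
#' @return list with \code{z2} (best height), \code{z} and \code{metric}
#'   (the scanned curve), \code{criterion} and \code{flat} (logical flag).
#' @export
autofocus <- function(holo, zMin, zMax, step = 1,
                      criterion = c("min_amplitude", "max_phase"),
                      window = NULL) {
  criterion <- match.arg(criterion)
  if (!(zMin < zMax) || step <= 0)
    stop("need zMin < zMax and a positive step")
  if (!is.null(window)) {
    d <- dim(holo)
    if (min(window$rows) < 1 || max(window$rows) > d[1] ||
        min(window$cols) < 1 || max(window$cols) > d[2])
      stop("focus window lies outside the grid")
  }
  zs <- seq(zMin, zMax, by = step)
  f0 <- hologramField(holo)
  metric <- vapply(zs, function(z) {
    v <- .pistonNormalize(propagate(f0, -z)@values)
    v <- if (criterion == "min_amplitude") Mod(v) else Arg(v)
    if (!is.null(window)) v <- v[window$rows, window$cols, drop = FALSE]
    if (criterion == "min_amplitude") min(v) else max(v)
  }, numeric(1))
  flat <- diff(range(metric)) <= 1e-12 * max(abs(metric), 1e-300)
  best <- if (flat) 1L else if (criterion == "min_amplitude")
    which.min(metric) else which.max(metric)
  list(z2 = zs[best], z = zs, metric = metric, criterion = criterion,
       flat = flat)
}

#' Digital object peeling / twin-image elimination
#'
#' Large objects in the field of view cast twin-image ripples that can bury
#' nearby weak particles. Peeling propagates the hologram field to the twin
#' plane (and optionally the object plane), masks the large objects by
#' thresholding the phase deviation from the background median, dilates the
#' mask, and replaces amplitude and phase inside it with the local
#' background estimate (median over an annulus around each masked
#' component). The field is then propagated back to the sensor and returned
#' as a complex hologram.
#'
#' @param holo a [HighResHologram-class].
#' @param z2 object height, micrometres.
#' @param phaseThreshold absolute phase deviation (radians) above which a
#'   cell belongs to a large object.
#' @param planes \code{"twin"}, \code{"object"} or \code{"both"}: where to
#'   peel. In the sensor-to-sample sign convention used here the object
#'   reconstruction lives at propagation distance \code{-z2}, its twin at
#'   \code{+z2}.
#' @param dilate mask dilation half-width, fine cells.
#' @param annulusWidth width of the background annulus, fine cells.
#' @param maxMaskFraction refuse to peel if the dilated mask covers more
#'   than this fraction of the field (background undefined).
#' @return A complex-valued [HighResHologram-class].
#' @export
peelObjects <- function(holo, z2, phaseThreshold,
                        planes = c("twin", "object", "both"),
                        dilate = 3, annulusWidth = 10,
                        maxMaskFraction = 0.5) {
  planes <- match.arg(planes)
  dz <- switch(planes, twin = z2, object = -z2, both = c(z2, -z2))
  f <- hologramField(holo)
  for (d in dz) {
    plane <- propagate(f, d)
    v <- plane@values
    ph <- Arg(v)
    dev <- abs(wrapPhase(ph - stats::median(ph)))
    mask <- dev > phaseThreshold
    if (!any(mask)) { next }
    mdil <- dilateMask(mask, dilate)
    if (mean(mdil) > maxMaskFraction)
      stop("peeling mask covers more than ", round(100 * maxMaskFraction),
           "% of the field; background undefined")
    lab <- EBImage::bwlabel(mdil)
    amp <- Mod(v)
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      ring <- dilateMask(comp, annulusWidth) & !comp & !mdil
      if (!any(ring)) ring <- !mdil
      bgAmp <- stats::median(amp[ring])
      bgPh <- stats::median(ph[ring])
      v[comp] <- bgAmp * exp(1i * bgPh)
    }
    f <- propagate(initialize(plane, values = v), -d)
  }
  initialize(holo, values = f@values)
}
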