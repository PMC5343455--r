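#' Describe a set of point-like scatterers on the sample plane
#'
#' A scene is a data.frame of sub-micron scatterers sitting on a single
#' sample plane a few hundred micrometres above the sensor. Each scatterer
#' perturbs the unit transmission of the plane by
#' \code{strength * nanolensGain} over a disk of the given diameter: the
#' magnitude of \code{strength} encodes absorption, its argument the optical
#' path delay. \code{nanolensGain} is a phenomenological gain (>= 1)
#' standing in for the signal boost of a self-assembled nanolens around the
#' particle.
#'
#' @param x,y lateral positions, micrometres (origin at the top-left grid
#'   corner, x rightward along columns, y downward along rows).
#' @param z2 height above the sensor, micrometres (one common value).
#' @param diameter particle diameter, nanometres.
#' @param strength complex transmission perturbation, \code{Mod(strength)
#'   <= 1}.
#' @param nanolensGain real gain >= 1.
#' @return data.frame of class \code{"scatterScene"}.
#' @examples
#' sc <- scatterers(x = 30, y = 25, diameter = 250,
#'                  strength = 0.6 * exp(0.6i))
#' @export
scatterers <- function(x, y, z2 = 400, diameter = 200,
                       strength = 0.5 + 0i, nanolensGain = 1) {
  d <- data.frame(x = x, y = y, z2 = z2, diameter = diameter,
                  nanolensGain = nanolensGain)
  d$strength <- rep_len(as.complex(strength), nrow(d))
  if (any(d$z2 <= 0)) stop("z2 must be positive")
  if (any(d$diameter <= 0)) stop("diameter must be positive")
  if (any(Mod(d$strength) > 1 + 1e-12)) stop("|strength| must be <= 1")
  if (any(d$nanolensGain < 1)) stop("nanolensGain must be >= 1")
  class(d) <- c("scatterScene", "data.frame")
  d
}

#' An empty scene (background illumination only)
#' @param z2 nominal sample height, micrometres.
#' @return A zero-row \code{"scatterScene"} carrying the height as an
#'   attribute.
#' @export
emptyScene <- function(z2 = 400) {
  d <- scatterers(x = numeric(), y = numeric(), z2 = numeric(),
                  diameter = numeric(), strength = complex(0),
                  nanolensGain = numeric())
  attr(d, "z2") <- z2
  d
}

.sceneZ2 <- function(scene) {
  if (nrow(scene) == 0)
    return(if (!is.null(attr(scene, "z2"))) attr(scene, "z2") else 400)
  z2 <- unique(scene$z2)
  if (length(z2) != 1L)
    stop("unsupported scene: all scatterers must share one z2 plane")
  z2
}

# Sample-plane complex transmission on the fine grid. Disk coverage per
# cell is a linear edge ramp, renormalized so that very small particles
# keep an area-faithful integrated perturbation.
.sceneTransmission <- function(scene, nFine, finePitch) {
  tm <- matrix(1 + 0i, nFine[1], nFine[2])
  for (i in seq_len(nrow(scene))) {
    rad <- scene$diameter[i] / 2000  # nm -> um
    halo <- ceiling(rad / finePitch) + 2L
    cc <- round(scene$x[i] / finePitch + 0.5)
    cr <- round(scene$y[i] / finePitch + 0.5)
    rows <- max(1L, cr - halo):min(nFine[1], cr + halo)
    cols <- max(1L, cc - halo):min(nFine[2], cc + halo)
    yv <- (rows - 0.5) * finePitch - scene$y[i]
    xv <- (cols - 0.5) * finePitch - scene$x[i]
    dist <- sqrt(outer(yv^2, xv^2, "+"))
    cov <- pmin(pmax(0.5 + (rad - dist) / finePitch, 0), 1)
    s <- sum(cov)
    if (s > 0) {
      area <- pi * rad^2 / finePitch^2
      if (s > area) cov <- cov * (area / s)
      tm[rows, cols] <- tm[rows, cols] -
        scene$strength[i] * scene$nanolensGain[i] * cov
    }
  }
  tm
}

# Frozen speckle field on the fine grid (unit-RMS amplitude scaled to the
# requested contrast), deterministic in the NoiseScene's own seed.
.speckleField <- function(noise, nFine, finePitch) {
  withSeed(noise@speckleSeed, {
    g <- matrix(complex(real = stats::rnorm(prod(nFine)),
                        imaginary = stats::rnorm(prod(nFine))),
                nFine[1], nFine[2])
    cut <- 1 / (2 * pi * noise@speckleCorrLength)
    sm <- .gaussLowpass(g, cut, finePitch)
    sm / sqrt(mean(Mod(sm)^2)) * noise@speckleContrast
  })
}

# Constituent fields, each given AT ITS OWN PLANE (unpropagated) and tagged
# with the height of that plane above the sensor.
.constituentFields <- function(scene, sensor, noise, nPixels, supersample,
                               wavelength) {
  ss <- as.integer(supersample)
  fp <- sensor@pixelPitch / ss
  nFine <- nPixels * ss
  z2 <- .sceneZ2(scene)
  fields <- list(list(field = .sceneTransmission(scene, nFine, fp),
                      height = z2, bandLimit = TRUE))
  par <- noise@parasitic
  for (i in seq_len(nrow(par))) {
    th <- par$orientation[i] * pi / 180
    u <- cos(th) / par$period[i]; v <- sin(th) / par$period[i]
    xs <- (seq_len(nFine[2]) - 0.5) * fp
    ys <- (seq_len(nFine[1]) - 0.5) * fp
    pw <- par$amplitude[i] * exp(2i * pi * outer(ys * v, xs * u, "+"))
    fields[[length(fields) + 1L]] <-
      list(field = pw, height = par$height[i], bandLimit = FALSE)
  }
  if (noise@speckleContrast > 0) {
    fields[[length(fields) + 1L]] <-
      list(field = .speckleField(noise, nFine, fp),
           height = noise@speckleHeight, bandLimit = FALSE)
  }
  list(fields = fields, finePitch = fp, nFine = nFine, z2 = z2)
}

# Intensity on the fine grid -> digitized sensor frame.
.readout <- function(intensity, sensor, supersample, seed) {
  frame <- blockMean(intensity, as.integer(supersample))
  if (sensor@bayer == "RGGB") {
    nr <- nrow(frame); nc <- ncol(frame)
    green <- outer(seq_len(nr), seq_len(nc), function(r, c)
      (r + c) %% 2 == 1)
    frame[!green] <- frame[!green] * sensor@rbResponse
  }
  counts <- frame * sensor@gain
  stochastic <- sensor@shotNoise || sensor@readNoiseSigma > 0
  if (stochastic) {
    if (is.null(seed))
      stop("a seed is required when shot or read noise is enabled")
    counts <- withSeed(seed, {
      x <- counts
      if (sensor@shotNoise)
        x <- matrix(stats::rpois(length(x), as.vector(x)),
                    nrow(x), ncol(x))
      if (sensor@readNoiseSigma > 0)
        x <- x + matrix(stats::rnorm(length(x), 0, sensor@readNoiseSigma),
                        nrow(x), ncol(x))
      x
    })
  }
  pmin(pmax(round(counts), 0), 2^sensor@bitDepth - 1)
}

#' Simulate one raw sensor frame
#'
#' Full forward model of a single acquisition: the sample-plane transmission
#' is built on a grid \code{supersample} times finer than the sensor pitch,
#' multiplied by the tilted illumination plane wave, propagated to the
#' sensor by the scene height; parasitic fringe fields and the frozen
#' speckle field are propagated from their own planes and added coherently;
#' the summed intensity is integrated over the pixel aperture, Bayer-masked,
#' and digitized with gain, shot noise, read noise and quantization.
#'
#' @param scene a \code{"scatterScene"} (see [scatterers()]); all entries
#'   must share one z2.
#' @param tilt illumination tilt (theta_x, theta_y), degrees.
#' @param sensor a [SensorModel-class].
#' @param noise a [NoiseScene-class]; [quietScene()] disables coherent
#'   noise.
#' @param nPixels sensor frame size c(rows, cols).
#' @param supersample fine-grid factor relative to the sensor pitch
#'   (default 4; sub-pixel objects and the pixel aperture are resolved
#'   explicitly).
#' @param wavelength vacuum wavelength, micrometres.
#' @param seed integer seed for shot/read noise; required when either is
#'   enabled.
#' @return Numeric matrix of quantized sensor counts.
#' @export
simulateFrame <- function(scene, tilt = c(0, 0), sensor = sensorModel(),
                          noise = quietScene(), nPixels = c(64, 64),
                          supersample = 4, wavelength = 0.266,
                          seed = NULL) {
  con <- .constituentFields(scene, sensor, noise, nPixels, supersample,
                            wavelength)
  fp <- con$finePitch; nFine <- con$nFine
  # the tilted illumination rides every plane's envelope as one common
  # carrier exp(2i*pi*f0.x); it is treated exactly by shifting the
  # propagation transfer function to H(f + f0), and drops out of the
  # intensity since all constituents share it
  f0 <- sin(tilt * pi / 180) / wavelength
  total <- matrix(0 + 0i, nFine[1], nFine[2])
  for (cf in con$fields) {
    total <- total + .angularSpectrum(cf$field, fp, wavelength, 1,
                                      cf$height, fOffset = f0,
                                      bandLimit = cf$bandLimit)
  }
  .readout(Mod(total)^2, sensor, supersample, seed)
}

#' Simulate a full sub-pixel-shifted frame stack
#'
#' Efficient generator for a whole acquisition: the zero-tilt sensor-plane
#' field of every constituent plane (sample, parasitic reflections,
#' speckle) is computed once; each frame's tilt is then applied as the
#' lateral displacement it produces -- \code{z * tan(theta)} for a plane at
#' height z, i.e. the pattern's target shift scaled by \code{z / z2} --
#' via Fourier phase ramps, followed by one inverse FFT, pixel-aperture
#' integration and sensor readout per frame. For the sub-0.5-degree tilts
#' used here this shift model agrees with the full per-frame physics of
#' [simulateFrame()] to well below the sensor quantization.
#'
#' @param scene a \code{"scatterScene"}.
#' @param pattern an [AcquisitionPattern-class] of target hologram shifts.
#' @param sensor a [SensorModel-class].
#' @param noise a [NoiseScene-class].
#' @param nPixels frame size c(rows, cols).
#' @param supersample fine-grid factor.
#' @param wavelength vacuum wavelength, micrometres.
#' @param seed integer; expanded deterministically into one readout seed
#'   per frame. Required when shot/read noise is enabled.
#' @return A [FrameStack-class] whose nominal shifts are the pattern
#'   entries.
#' @export
simulateStack <- function(scene, pattern, sensor = sensorModel(),
                          noise = quietScene(), nPixels = c(64, 64),
                          supersample = 4, wavelength = 0.266,
                          seed = NULL) {
  con <- .constituentFields(scene, sensor, noise, nPixels, supersample,
                            wavelength)
  fp <- con$finePitch; nFine <- con$nFine; z2 <- con$z2
  spectra <- lapply(con$fields, function(cf)
    fft2(.angularSpectrum(cf$field, fp, wavelength, 1, cf$height,
                          bandLimit = cf$bandLimit)))
  heights <- vapply(con$fields, `[[`, numeric(1), "height")
  fy <- fftFreq(nFine[1], fp)
  fx <- fftFreq(nFine[2], fp)
  shifts <- shiftTable(pattern)
  out <- vector("list", nrow(shifts))
  for (f in seq_len(nrow(shifts))) {
    sx <- shifts$dx[f]; sy <- shifts$dy[f]
    F <- matrix(0 + 0i, nFine[1], nFine[2])
    for (ci in seq_along(spectra)) {
      sc <- heights[ci] / z2
      if (sx == 0 && sy == 0) {
        F <- F + spectra[[ci]]
      } else {
        ey <- exp(-2i * pi * fy * (sy * sc))
        ex <- exp(-2i * pi * fx * (sx * sc))
        F <- F + spectra[[ci]] * outer(ey, ex)
      }
    }
    I <- Mod(ifft2(F))^2
    out[[f]] <- .readout(I, sensor, supersample,
                         if (is.null(seed)) NULL else
                           deriveSeed(seed, "noise") + f)
  }
  new("FrameStack", frames = out,
      nominalShifts = data.frame(dx = shifts$dx, dy = shifts$dy),
      estimatedShifts = data.frame(dx = numeric(), dy = numeric()),
      pitch = sensor@pixelPitch, wavelength = wavelength,
      bayer = sensor@bayer)
}

#' Reference scene: nanolens-enhanced beads plus a registration fiducial
#'
#' The packaged study scene: \code{n} phase-dominant 400-nm particles with
#' a strong nanolens gain, laid out on a jittered grid across the field of
#' view, plus one large absorbing dust particle near the corner that serves
#' as the sample-plane registration fiducial (the "visible mark" that
#' shift estimation locks onto). Positions are drawn deterministically from
#' the seed.
#'
#' @param n number of nanoparticles (0 gives the fiducial-only noise
#'   scene).
#' @param fov lateral field of view, micrometres (set it to
#'   \code{nPixels * pixel pitch} of the planned acquisition).
#' @param z2 sample height, micrometres.
#' @param seed integer; fixes the jittered positions.
#' @param diameter particle diameter, nm.
#' @param strength complex particle strength (absorption + phase delay).
#' @param nanolensGain phenomenological nanolens signal gain.
#' @return A \code{"scatterScene"}; the particle rows (excluding the
#'   fiducial) are flagged in the \code{fiducial} column.
#' @export
demoScene <- function(n = 20, fov = 143.36, z2 = 400, seed = 5,
                      diameter = 400, strength = 0.6 * exp(-1.3i),
                      nanolensGain = 32) {
  pos <- withSeed(seed, {
    if (n > 0) {
      ncol_ <- ceiling(sqrt(n * 1.25))
      nrow_ <- ceiling(n / ncol_)
      gx <- rep(seq(0.14 * fov, 0.87 * fov, length.out = ncol_), nrow_)
      gy <- rep(seq(0.24 * fov, 0.87 * fov, length.out = nrow_),
                each = ncol_)
      jit <- 0.028 * fov
      data.frame(x = gx[seq_len(n)] + stats::runif(n, -jit, jit),
                 y = gy[seq_len(n)] + stats::runif(n, -jit, jit))
    } else data.frame(x = numeric(), y = numeric())
  })
  sc <- scatterers(
    x = c(0.1 * fov, pos$x), y = c(0.1 * fov, pos$y), z2 = z2,
    diameter = c(4000, rep(diameter, n)),
    strength = c(0.95 + 0i, rep(as.complex(strength), n)),
    nanolensGain = c(1, rep(nanolensGain, n)))
  sc$fiducial <- c(TRUE, rep(FALSE, n))
  sc
}
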