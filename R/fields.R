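#' @describeIn propagate Angular-spectrum propagation of a sampled field.
#'
#' The spectrum is multiplied by the transfer function
#' \code{exp(2i * pi * dz * sqrt((n/lambda)^2 - fx^2 - fy^2))}. Evanescent
#' components (\code{fx^2 + fy^2 > (n/lambda)^2}) are attenuated with the
#' corresponding real exponential decay \code{exp(-2 * pi * |dz| * q)}
#' rather than zeroed, which avoids hard-edge ringing; the magnitude of
#' \code{dz} is used there so that back-propagation attenuates rather than
#' amplifies them. Pitch and grid shape are preserved. With \code{pad > 1}
#' the field is zero-padded by that factor before the FFT (suppressing
#' wrap-around at the cost of energy leaving the window); the default
#' \code{pad = 1} keeps the periodic boundary.
#' @export
setMethod("propagate", "ComplexField", function(field, dz, pad = 1) {
  if (length(dz) != 1L || !is.finite(dz))
    stop("'dz' must be a single finite distance in micrometres")
  validObject(field)
  if (dz == 0 && pad == 1) return(field)
  out <- .angularSpectrum(field@values, field@pitch, field@wavelength,
                          field@mediumIndex, dz, pad = pad)
  initialize(field, values = out)
})

# Angular-spectrum kernel. fOffset = c(f0x, f0y) shifts the transfer
# function to H(f + f0): the exact periodic treatment of a tilted
# illumination carrier exp(2i*pi*(f0x*x + f0y*y)) riding on the sampled
# envelope (the carrier itself is not representable on the periodic grid
# and is carried analytically; intensities of a sum of fields sharing one
# carrier are unaffected by it).
.angularSpectrum <- function(v, pitch, lambda, n0, dz, fOffset = c(0, 0),
                             pad = 1, bandLimit = FALSE) {
  nr0 <- nrow(v); nc0 <- ncol(v)
  if (pad > 1) {
    nr <- nr0 * pad; nc <- nc0 * pad
    vp <- matrix(0 + 0i, nr, nc)
    vp[seq_len(nr0), seq_len(nc0)] <- v
    v <- vp
  }
  nr <- nrow(v); nc <- ncol(v)
  fy <- fftFreq(nr, pitch) + fOffset[2]
  fx <- fftFreq(nc, pitch) + fOffset[1]
  kz2 <- (n0 / lambda)^2 - outer(fy^2, fx^2, "+")
  H <- matrix(0 + 0i, nr, nc)
  prop <- kz2 >= 0
  H[prop] <- exp(2i * pi * dz * sqrt(kz2[prop]))
  H[!prop] <- exp(-2 * pi * abs(dz) * sqrt(-kz2[!prop]))
  if (bandLimit && dz != 0) {
    # band-limited angular spectrum: keep only frequencies whose rays stay
    # inside the simulation window over the distance dz, so that a compact
    # object's diffraction pattern does not wrap around the periodic
    # boundary (a smooth cos^2 rolloff over the outer 15% avoids ringing)
    flimy <- 1 / (lambda / n0 * sqrt((2 * abs(dz) / (nr * pitch))^2 + 1))
    flimx <- 1 / (lambda / n0 * sqrt((2 * abs(dz) / (nc * pitch))^2 + 1))
    # the limit is applied on the envelope (grid) frequencies, not the
    # carrier-offset ones, so that tilted frames share one passband
    gy <- fftFreq(nr, pitch); gx <- fftFreq(nc, pitch)
    rho <- sqrt(outer((gy / flimy)^2, (gx / flimx)^2, "+"))
    w <- matrix(0, nr, nc)
    w[rho <= 0.85] <- 1
    tap <- rho > 0.85 & rho < 1
    w[tap] <- cos(pi / 2 * (rho[tap] - 0.85) / 0.15)^2
    H <- H * w
  }
  out <- ifft2(fft2(v) * H)
  out[seq_len(nr0), seq_len(nc0), drop = FALSE]
}

.gaussLowpass <- function(m, cutoff, pitch) {
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0)
    stop("'cutoff' must be a single positive spatial frequency (1/um)")
  fy <- fftFreq(nrow(m), pitch)
  fx <- fftFreq(ncol(m), pitch)
  H <- exp(-outer(fy^2, fx^2, "+") / (2 * cutoff^2))
  out <- ifft2(fft2(m) * H)
  if (is.complex(m)) out else Re(out)
}

#' @describeIn lowpass On a plain matrix; \code{pitch} gives the grid
#'   spacing in micrometres.
#' @param pitch grid spacing in micrometres (matrix method only).
#' @export
setMethod("lowpass", "matrix", function(x, cutoff, pitch = 1) {
  .gaussLowpass(x, cutoff, pitch)
})

#' @describeIn lowpass On a [ComplexField-class]; filters the complex
#'   values, keeping metadata.
#' @export
setMethod("lowpass", "ComplexField", function(x, cutoff) {
  initialize(x, values = .gaussLowpass(x@values, cutoff, x@pitch))
})

#' @describeIn lowpass On a [HighResHologram-class]; used to isolate the
#'   low-frequency background (large dust, illumination modulation) before
#'   phase background compensation.
#' @export
setMethod("lowpass", "HighResHologram", function(x, cutoff) {
  initialize(x, values = .gaussLowpass(x@values, cutoff, x@pitch))
})

#' Lift a recorded hologram to a complex field
#'
#' Real-valued (intensity) holograms are lifted with a zero-phase square
#' root of the non-negative intensity, the standard single-shot in-line
#' treatment; small negative excursions from float noise are clamped to 0.
#' Complex-valued holograms (after digital object peeling) are passed
#' through unchanged.
#'
#' @param holo a [HighResHologram-class].
#' @return A [ComplexField-class] at the hologram pitch.
#' @export
hologramField <- function(holo) {
  v <- holo@values
  if (!is.complex(v)) {
    v <- sqrt(pmax(v, 0))
    storage.mode(v) <- "complex"
  }
  ComplexField(v, pitch = holo@pitch, wavelength = holo@wavelength)
}

#' Serialize a complex field to paired float TIFFs
#'
#' Writes amplitude and phase as two 32-bit float TIFF pages plus a JSON
#' sidecar carrying pitch, wavelength and an optional height tag.
#'
#' @param field a [ComplexField-class].
#' @param path output TIFF path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @param z optional height tag, micrometres.
#' @return \code{path}, invisibly.
#' @export
writeField <- function(field, path, z = NA_real_) {
  amp <- Mod(field@values)
  ph <- Arg(field@values)
  sc <- .tiffScale(list(amp, ph))
  tiff::writeTIFF(sc$pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pitch = field@pitch, wavelength = field@wavelength,
         mediumIndex = field@mediumIndex, z = z,
         pages = c("amplitude", "phase"),
         offset = sc$offset, scale = sc$scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# TIFF pages must live in [0, 1]; keep the affine map in the sidecar.
.tiffScale <- function(pages) {
  offset <- vapply(pages, min, numeric(1))
  scale <- vapply(pages, function(p) max(max(p) - min(p), 1e-300),
                  numeric(1))
  list(pages = Map(function(p, o, s) (p - o) / s, pages, offset, scale),
       offset = offset, scale = scale)
}

.tiffUnscale <- function(pages, meta) {
  Map(function(p, o, s) p * s + o, pages, meta$offset, meta$scale)
}

#' Read a complex field written by [writeField()]
#' @param path TIFF path with its JSON sidecar alongside.
#' @return A [ComplexField-class].
#' @export
readField <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- .tiffUnscale(tiff::readTIFF(path, all = TRUE), meta)
  amp <- pages[[1]]; ph <- pages[[2]]
  ComplexField(amp * exp(1i * ph), pitch = meta$pitch,
               wavelength = meta$wavelength,
               mediumIndex = if (!is.null(meta$mediumIndex))
                 meta$mediumIndex else 1)
}

# Remove the global piston phase of a propagated field: the angular-spectrum
# kernel advances the DC (background) component by 2*pi*dz*n/lambda, an
# arbitrary-looking constant modulo 2*pi that would put the wrapped
# background phase anywhere in (-pi, pi]. Rotating the field so the mean
# phasor points along +1 pins the background phase near 0, making phase
# images at different heights comparable.
.pistonNormalize <- function(v) {
  m <- mean(v)
  if (Mod(m) == 0) return(v)
  v * Conj(m) / Mod(m)
}
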