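#' Forward-scattering radar cross section of a PEC nanosphere
#'
#' Mie-series forward-scattering radar cross section (RCS) of a sphere
#' idealized as a perfect electric conductor (PEC), the standard
#' wavelength-scaling model for comparing nanoparticle detectability across
#' illumination wavelengths. With size parameter \code{x = pi * d / lambda},
#' the PEC Mie coefficients are \code{a_n = j_n(x) / h_n(x)} and
#' \code{b_n = [x j_n(x)]' / [x h_n(x)]'} (spherical Bessel / outgoing
#' Hankel functions), the forward scattering amplitude is
#' \code{S(0) = 1/2 * sum_n (2n + 1) (a_n + b_n)}, and
#' \code{RCS = (lambda^2 / pi) * |S(0)|^2 = 4 * pi * |S(0)|^2 / k^2}.
#' The series is truncated at \code{ceiling(x + 4 * x^(1/3) + 2)} terms
#' unless more are requested.
#'
#' @param diameter sphere diameter(s), nanometres; vectorized.
#' @param wavelength vacuum wavelength, nanometres.
#' @param nTerms optional series order; values below the size-parameter
#'   minimum are raised to it.
#' @return Forward-scattering RCS in nm^2 (vector along \code{diameter}).
#' @examples
#' pecForwardRCS(250, 532)
#' @seealso [equivalentDiameter()], [rcsCurve()]
#' @export
pecForwardRCS <- function(diameter, wavelength, nTerms = NULL) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("'diameter' must be positive (nm)")
  if (length(wavelength) != 1L || !is.finite(wavelength) || wavelength <= 0)
    stop("'wavelength' must be a single positive value (nm)")
  vapply(diameter, function(d) {
    x <- pi * d / wavelength
    (wavelength^2 / pi) * Mod(.pecS0(x, nTerms))^2
  }, numeric(1))
}

# spherical Bessel functions of the first and second kind via half-integer
# cylindrical Bessel functions
.sphj <- function(n, x) sqrt(pi / (2 * x)) * besselJ(x, n + 0.5)
.sphy <- function(n, x) sqrt(pi / (2 * x)) * besselY(x, n + 0.5)
.sphh <- function(n, x) complex(real = .sphj(n, x), imaginary = .sphy(n, x))

# forward scattering amplitude S(0) of a PEC sphere with size parameter x
.pecS0 <- function(x, nTerms = NULL) {
  nMin <- ceiling(x + 4 * x^(1 / 3) + 2)
  N <- max(nMin, if (is.null(nTerms)) 0 else nTerms)
  n <- seq_len(N)
  jn <- .sphj(n, x); jn1 <- .sphj(n - 1, x)
  hn <- .sphh(n, x); hn1 <- .sphh(n - 1, x)
  an <- jn / hn
  bn <- (x * jn1 - n * jn) / (x * hn1 - n * hn)  # Ricatti-Bessel derivatives
  0.5 * sum((2 * n + 1) * (an + bn))
}

#' Equivalent-diameter solver across illumination wavelengths
#'
#' Finds the sphere diameter at \code{lambdaTarget} whose forward-scattering
#' RCS equals that of a \code{dRef}-diameter sphere at \code{lambdaRef},
#' by bisection of the monotone RCS-versus-diameter curve to 0.1 nm.
#' This is how a detection limit measured at one wavelength is translated
#' to another: e.g. a 250 nm limit under 532 nm green illumination maps to
#' roughly a 180 nm particle under 266 nm UV.
#'
#' @param dRef reference diameter, nm.
#' @param lambdaRef reference wavelength, nm.
#' @param lambdaTarget target wavelength, nm.
#' @param interval search interval for the diameter, nm.
#' @param tol solver tolerance, nm.
#' @return Equivalent diameter at \code{lambdaTarget}, nm.
#' @examples
#' equivalentDiameter(250, 532, 266)  # ~180 nm
#' @export
equivalentDiameter <- function(dRef, lambdaRef, lambdaTarget,
                               interval = c(1, 2000), tol = 0.1) {
  stopifnot(dRef > 0, lambdaRef > 0, lambdaTarget > 0)
  if (lambdaTarget == lambdaRef) return(dRef)
  target <- pecForwardRCS(dRef, lambdaRef)
  f <- function(d) pecForwardRCS(d, lambdaTarget) - target
  flo <- f(interval[1]); fhi <- f(interval[2])
  if (sign(flo) == sign(fhi))
    stop("no bracketing interval in [", interval[1], ", ", interval[2],
         "] nm for the target RCS")
  lo <- interval[1]; hi <- interval[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' RCS-versus-diameter curve at a fixed wavelength
#'
#' @param diameters increasing diameters, nm.
#' @param wavelength vacuum wavelength, nm.
#' @param nTerms optional series order passed to [pecForwardRCS()].
#' @return data.frame(diameter_nm, rcs_nm2).
#' @export
rcsCurve <- function(diameters, wavelength, nTerms = NULL) {
  if (any(diff(diameters) <= 0)) stop("'diameters' must be increasing")
  data.frame(diameter_nm = diameters,
             rcs_nm2 = pecForwardRCS(diameters, wavelength, nTerms))
}

#' Forward-scattering RCS of a dielectric sphere
#'
#' Companion to [pecForwardRCS()] for a homogeneous sphere with a (possibly
#' complex) refractive index, using the standard Mie coefficients; provided
#' for realism when a material model is preferred over the PEC idealization.
#'
#' @param diameter diameter(s), nm.
#' @param wavelength vacuum wavelength, nm.
#' @param m complex refractive index of the sphere relative to the medium.
#' @return Forward-scattering RCS in nm^2.
#' @export
dielectricForwardRCS <- function(diameter, wavelength, m) {
  stopifnot(all(diameter > 0), wavelength > 0)
  vapply(diameter, function(d) {
    x <- pi * d / wavelength
    mx <- m * x
    N <- ceiling(x + 4 * x^(1 / 3) + 2)
    n <- seq_len(N)
    jx <- .sphj(n, x); jx1 <- .sphj(n - 1, x)
    hx <- .sphh(n, x); hx1 <- .sphh(n - 1, x)
    jm <- .csphj(n, mx); jm1 <- .csphj(n - 1, mx)
    dpsi_x <- x * jx1 - n * jx      # psi_n'(x)
    dxi_x <- x * hx1 - n * hx       # xi_n'(x)
    dpsi_m <- mx * jm1 - n * jm
    psi_x <- x * jx; xi_x <- x * hx; psi_m <- mx * jm
    an <- (m * psi_m * dpsi_x - psi_x * dpsi_m) /
          (m * psi_m * dxi_x - xi_x * dpsi_m)
    bn <- (psi_m * dpsi_x - m * psi_x * dpsi_m) /
          (psi_m * dxi_x - m * xi_x * dpsi_m)
    S0 <- 0.5 * sum((2 * n + 1) * (an + bn))
    (wavelength^2 / pi) * Mod(S0)^2
  }, numeric(1))
}

# complex-argument spherical Bessel j_n by downward recurrence
.csphj <- function(n, z) {
  nmax <- max(n)
  nstart <- nmax + ceiling(10 + Mod(z))
  jp <- 0 + 0i; j <- 1e-30 + 0i
  out <- complex(nmax + 1)
  for (k in nstart:0) {
    jm <- (2 * k + 3) / z * j - jp
    if (k <= nmax) out[k + 1] <- jm
    jp <- j; j <- jm
  }
  scale <- (sin(z) / z) / out[1]
  (out * scale)[n + 1]
}
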