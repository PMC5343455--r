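# Internal numerical helpers shared across modules.

# DFT sample frequencies (cycles per unit), matching the layout of fft().
fftFreq <- function(n, d) {
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * d)
}

fft2 <- function(m) stats::fft(m)

ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Run code with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed expansion from one global seed.
deriveSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 101L, speckle = 211L, superres = 307L,
               reconstruct = 401L, detect = 503L, noise = 601L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage))
  as.integer(((as.numeric(seed) %% 1000003) * 977 + off) %% 2147483647)
}

# Sub-cell lateral translation of a periodic field via a Fourier phase ramp.
# s = c(sx, sy) in micrometres; positive values move content toward larger
# x (columns) and y (rows).
fourierShift <- function(m, s, pitch) {
  if (all(s == 0)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  fy <- fftFreq(nr, pitch); fx <- fftFreq(nc, pitch)
  ramp <- exp(-2i * pi * (outer(fy * s[2], fx * s[1], "+")))
  ifft2(fft2(m) * ramp)
}

# Mean over non-overlapping k x k blocks (pixel-aperture integration).
blockMean <- function(m, k) {
  if (k == 1L) return(m)
  nr <- nrow(m) %/% k; nc <- ncol(m) %/% k
  m <- m[seq_len(nr * k), seq_len(nc * k), drop = FALSE]
  s <- colSums(array(m, c(k, nr, nc * k)))       # fold rows -> nr x (nc*k)
  t(colSums(array(t(s), c(k, nc, nr)))) / (k * k) # fold columns
}

# Binary dilation with a square structuring element of half-width r.
dilateMask <- function(mask, r) {
  if (r <= 0) return(mask)
  m <- mask
  for (i in seq_len(r)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    m <- m | up | dn | lf | rt |
      rbind(cbind(m[-1, -1, drop = FALSE], FALSE), FALSE) |
      rbind(FALSE, cbind(m[-nrow(m), -1, drop = FALSE], FALSE)) |
      rbind(cbind(FALSE, m[-1, -ncol(m), drop = FALSE]), FALSE) |
      rbind(FALSE, cbind(FALSE, m[-nrow(m), -ncol(m), drop = FALSE]))
  }
  m
}

# Wrap angles into (-pi, pi].
wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Sub-pixel displacement of image `b` relative to image `a` (in pixels),
# by FFT cross-correlation with local matrix-multiply DFT refinement
# (single-step upsampled cross-correlation). Returns c(dx, dy): b looks
# like a translated by +d.
# `expect` (pixels) with `maxResidual` restricts the integer peak search to
# a neighbourhood of an expected displacement (e.g. the nominal galvo
# shift), which keeps the lock on the sample plane when stronger structure
# from other planes moves by different amounts. `whiten` applies regularized
# phase correlation (cross-spectrum divided by |.| + q*mean|.|): a few
# strong periodic-fringe bins then cannot outweigh the broadband hologram
# signature of a sample-plane object.
registerTranslation <- function(a, b, upsample = 100, expect = NULL,
                                maxResidual = Inf, whiten = TRUE,
                                q = 3) {
  stopifnot(identical(dim(a), dim(b)))
  nr <- nrow(a); nc <- ncol(a)
  A <- fft2(a - mean(a)); B <- fft2(b - mean(b))
  CR0 <- B * Conj(A)
  if (whiten) {
    W <- Mod(CR0)
    CR0 <- CR0 / (W + q * mean(W))
  }
  cc <- Re(ifft2(CR0))
  if (!is.null(expect) && is.finite(maxResidual)) {
    sy <- c(0:(nr - 1)); sy[sy > nr / 2] <- sy[sy > nr / 2] - nr
    sx <- c(0:(nc - 1)); sx[sx > nc / 2] <- sx[sx > nc / 2] - nc
    allowed <- outer(abs(sy - expect[2]) <= maxResidual,
                     abs(sx - expect[1]) <= maxResidual, "&")
    cc[!allowed] <- -Inf
  }
  pk <- which.max(cc) - 1L
  py <- pk %% nr; px <- pk %/% nr
  if (py > nr / 2) py <- py - nr
  if (px > nc / 2) px <- px - nc
  if (upsample <= 1) return(c(dx = px, dy = py))
  # refine on a 1.5-pixel neighbourhood at `upsample` resolution
  half <- ceiling(1.5 * upsample)
  CR <- CR0
  fy <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1)
  fx <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1)
  sy <- py + (-half:half) / upsample
  sx <- px + (-half:half) / upsample
  Ey <- exp(2i * pi * outer(sy, fy) / nr)            # |sy| x nr
  Ex <- exp(2i * pi * outer(fx, sx) / nc)            # nc x |sx|
  ccu <- Re(Ey %*% CR %*% Ex)
  pk <- which(ccu == max(ccu), arr.ind = TRUE)[1, ]
  c(dx = sx[pk[2]], dy = sy[pk[1]])
}

# Fill zero-coverage cells by iterative neighbour averaging; `filled` marks
# the cells that held data.
fillHoles <- function(values, filled) {
  while (any(!filled)) {
    hol <- which(!filled, arr.ind = TRUE)
    nr <- nrow(values); nc <- ncol(values)
    acc <- numeric(nrow(hol)); cnt <- numeric(nrow(hol))
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      rr <- hol[, 1] + d[1]; cc <- hol[, 2] + d[2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      ok[ok] <- filled[cbind(rr[ok], cc[ok])]
      idx <- cbind(rr[ok], cc[ok])
      acc[ok] <- acc[ok] + values[idx]
      cnt[ok] <- cnt[ok] + 1
    }
    ready <- cnt > 0
    if (!any(ready)) break
    values[hol[ready, , drop = FALSE]] <- acc[ready] / cnt[ready]
    filled[hol[ready, , drop = FALSE]] <- TRUE
  }
  values
}
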