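test_that("zero-distance propagation is the identity", {
  f <- randomField(32)
  expect_identical(fieldValues(propagate(f, 0)), fieldValues(f))
})

test_that("propagation round-trips and conserves energy for propagating fields", {
  f <- randomField(64, fmax = 0.45 / 0.266)
  fwd <- propagate(f, 300)
  back <- propagate(fwd, -300)
  peak <- max(Mod(fieldValues(f)))
  expect_lt(max(Mod(fieldValues(back) - fieldValues(f))) / peak, 1e-8)
  e0 <- sum(Mod(fieldValues(f))^2)
  e1 <- sum(Mod(fieldValues(fwd))^2)
  expect_lt(abs(e1 - e0) / e0, 1e-10)
})

test_that("propagation is linear and shift-equivariant", {
  f1 <- randomField(32, seed = 1)
  f2 <- randomField(32, seed = 2)
  a <- 1.7; b <- -0.4 + 0.2i
  lhs <- propagate(initialize(f1,
    values = a * fieldValues(f1) + b * fieldValues(f2)), 120)
  rhs <- a * fieldValues(propagate(f1, 120)) +
    b * fieldValues(propagate(f2, 120))
  expect_lt(max(Mod(fieldValues(lhs) - rhs)), 1e-12 * max(Mod(rhs)))
  # whole-cell translation commutes with propagation (periodic grid)
  roll <- function(m, k) m[c((nrow(m) - k + 1):nrow(m), 1:(nrow(m) - k)), ]
  shifted <- propagate(initialize(f1, values = roll(fieldValues(f1), 5)), 120)
  expect_lt(max(Mod(fieldValues(shifted) -
                    roll(fieldValues(propagate(f1, 120)), 5))), 1e-10)
})

test_that("evanescent components decay under propagation in either direction", {
  n <- 32; pitch <- 0.1  # Nyquist 5/um >> 1/lambda: evanescent band exists
  v <- matrix(0 + 0i, n, n)
  v[13, 13] <- 1  # spectral line at |f| = 5.3/um > 1/lambda = 3.76/um
  f <- ComplexField(stats::fft(v, inverse = TRUE) / (n * n), pitch = pitch)
  for (dz in c(2, -2)) {
    out <- propagate(f, dz)
    expect_lt(sum(Mod(fieldValues(out))^2), sum(Mod(fieldValues(f))^2))
  }
})

test_that("back-propagation matches a direct Rayleigh-Sommerfeld summation", {
  # sensor-plane hologram of an on-axis point source at z = 300 um,
  # generated with the first Rayleigh-Sommerfeld impulse response and
  # apodized so the aperture field is self-contained in the window
  n <- 128; pitch <- 0.28; lam <- 0.266; z <- 300; k <- 2 * pi / lam
  ic <- n / 2 + 1
  xs <- (seq_len(n) - ic) * pitch
  r <- sqrt(outer(xs^2, xs^2, "+") + z^2)
  E <- (1 / (2 * pi)) * (z / r) * (1 / r - 1i * k) * exp(1i * k * r) / r *
    pitch^2
  tuk <- function(m, a = 0.3) {
    t <- seq(0, 1, length.out = m); w <- rep(1, m)
    lo <- t < a / 2; hi <- t > 1 - a / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / a - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / a - 2 / a + 1)))
    w
  }
  E <- E * outer(tuk(n), tuk(n))
  back <- propagate(ComplexField(E, pitch = pitch, wavelength = lam), -z,
                    pad = 2)
  # brute-force RS back-summation on the central 40 x 40 cells
  ctr <- (ic - 20):(ic + 19)
  sy <- rep(xs, times = n); sx <- rep(xs, each = n)
  Ev <- as.vector(E)
  oracle <- matrix(0 + 0i, 40, 40)
  for (jj in seq_len(40)) {
    tx <- xs[ctr[jj]]
    for (ii in seq_len(40)) {
      ty <- xs[ctr[ii]]
      rr <- sqrt((sx - tx)^2 + (sy - ty)^2 + z^2)
      hk <- Conj((1 / (2 * pi)) * (z / rr) * (1 / rr - 1i * k) *
                   exp(1i * k * rr) / rr) * pitch^2
      oracle[ii, jj] <- sum(Ev * hk)
    }
  }
  peak <- max(Mod(oracle))
  expect_lt(max(Mod(fieldValues(back)[ctr, ctr] - oracle)) / peak, 0.01)
  # and the energy concentrates at the point's lateral location
  pk <- which(Mod(fieldValues(back)) == max(Mod(fieldValues(back))),
              arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(ic, ic))
})

test_that("propagate rejects invalid arguments", {
  f <- randomField(16)
  expect_error(propagate(f, NaN), "finite")
  expect_error(propagate(f, c(1, 2)), "finite")
  expect_error(ComplexField(matrix(1 + 0i, 1, 5)), "2x2")
  expect_error(ComplexField(matrix(1 + 0i, 4, 4), pitch = -1), "pitch")
})

test_that("gaussian lowpass preserves the mean and kills fine structure", {
  m <- matrix(2.5, 32, 32)
  expect_equal(lowpass(m, 0.1, pitch = 1), m, tolerance = 1e-12)
  # pure sinusoid at 10x cutoff attenuated by > 100x
  n <- 64; pitch <- 1; cutoff <- 0.04
  x <- outer(rep(1, n), seq_len(n))
  s <- sin(2 * pi * 10 * cutoff * x)
  out <- lowpass(s, cutoff, pitch = pitch)
  expect_lt(max(abs(out)), max(abs(s)) / 100)
  # a slow ramp survives fine fringes riding on it
  ramp <- outer(rep(1, n), seq_len(n)) / n
  ramp <- lowpass(ramp, 0.02, pitch = pitch)   # make it band-limited & periodic
  fringes <- 0.5 * sin(2 * pi * 0.4 * x)
  rec <- lowpass(ramp + fringes, cutoff, pitch = pitch)
  expect_lt(sqrt(mean((rec - ramp)^2)) / sqrt(mean(ramp^2)), 0.05)
  expect_error(lowpass(m, -0.1, pitch = 1), "cutoff")
})

test_that("complex fields survive the paired-TIFF serialization", {
  f <- randomField(16)
  path <- tempfile(fileext = ".tif")
  writeField(f, path, z = 400)
  g <- readField(path)
  expect_equal(pitch(g), pitch(f))
  expect_equal(wavelength(g), wavelength(f))
  expect_lt(max(Mod(fieldValues(g) - fieldValues(f))),
            1e-6 * max(Mod(fieldValues(f))))
})
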