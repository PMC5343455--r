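test_that("green fill reproduces constants, linear ramps and the 4-neighbour mean", {
  n <- 16
  green <- outer(1:n, 1:n, function(r, c) (r + c) %% 2 == 1)
  f <- matrix(runif(n * n, 10, 20), n)
  f[green] <- 7
  out <- greenFill(f)
  expect_equal(out, matrix(7, n, n))
  # a linear ramp in the greens is reproduced exactly at interior sites
  ramp <- outer(rep(1, n), seq_len(n)) + 0.3 * outer(seq_len(n), rep(1, n))
  f2 <- ramp; f2[!green] <- -99
  out2 <- greenFill(f2)
  expect_equal(out2[2:(n - 1), 2:(n - 1)], ramp[2:(n - 1), 2:(n - 1)])
  # random greens: brute-force neighbourhood oracle
  set.seed(1)
  f3 <- matrix(rnorm(n * n), n); f3[!green] <- NA
  out3 <- greenFill(ifelse(is.na(f3), 0, f3))
  for (r in 2:(n - 1)) for (c in 2:(n - 1)) {
    if (!green[r, c]) {
      expect_equal(out3[r, c],
                   mean(c(f3[r - 1, c], f3[r + 1, c], f3[r, c - 1],
                          f3[r, c + 1])))
    }
  }
  expect_error(greenFill(matrix(0, 15, 16)), "even")
})

test_that("frame normalization flattens the illumination envelope", {
  expect_equal(normalizeFrame(matrix(3.7, 32, 32)), matrix(1, 32, 32),
               tolerance = 1e-10)
  # smooth Gaussian-ish envelope: output within 1% of 1 everywhere
  n <- 128; pitch <- 1.12
  xs <- (seq_len(n) - n / 2)^2
  env <- lowpass(exp(-outer(xs, xs, "+") / (2 * (n / 2.5)^2)), 0.004,
                 pitch = pitch)  # band-limited, periodic-compatible
  env <- env - min(env) + 1
  out <- normalizeFrame(env, cutoff = 0.05, pitch = pitch)
  expect_lt(max(abs(out - 1)), 0.01)
  # envelope x (1 + 0.1 fine fringes): fringe amplitude preserved
  x <- outer(rep(1, n), seq_len(n)) * pitch
  fr <- env * (1 + 0.1 * sin(2 * pi * 0.25 * x))
  out2 <- normalizeFrame(fr, cutoff = 0.05, pitch = pitch)
  amp <- (max(out2) - min(out2)) / 2
  expect_equal(amp, 0.1, tolerance = 0.05)
  expect_error(normalizeFrame(matrix(0, 8, 8)), "zero")
})

test_that("identical frames register to zero shift", {
  f <- matrix(runif(64 * 64), 64)
  st <- FrameStack(list(f, f, f), pitch = 1.12, bayer = "mono")
  est <- shiftTable(estimateShifts(st), "estimated")
  expect_equal(est$dx, rep(0, 3), tolerance = 1e-6)
  expect_equal(est$dy, rep(0, 3), tolerance = 1e-6)
})

test_that("shift estimation recovers the full acquisition pattern", {
  st <- estimateShifts(quietStack96())
  est <- shiftTable(st, "estimated")
  nom <- shiftTable(st, "nominal")
  rms <- sqrt(mean((est$dx - nom$dx)^2 + (est$dy - nom$dy)^2))
  expect_lt(rms, 0.03)
})

test_that("registration tracks the sample plane, not a parasitic plane", {
  # one oblique reflection 1000 um up moves 2.5x as fast as the holograms
  noi <- noiseScene(parasitic = data.frame(height = 1000, amplitude = 0.02,
                                           orientation = 35, period = 8),
                    speckleContrast = 0)
  st <- simulateStack(fiducialScene(), makePattern(3, 0.4, 2, 1.5, 8),
                      sensor = quietSensor(), noise = noi,
                      nPixels = c(96, 96))
  st <- estimateShifts(st)
  est <- shiftTable(st, "estimated")
  nom <- shiftTable(st, "nominal")
  expect_lt(max(abs(c(est$dx - nom$dx, est$dy - nom$dy))), 0.05)
})

test_that("a featureless window raises a no-fiducial error", {
  f <- matrix(5, 32, 32)
  st <- FrameStack(list(f, f), pitch = 1.12, bayer = "mono")
  expect_error(estimateShifts(st), "fiducial.*nominal")
})

test_that("shift-and-add reduces to the identity for one unshifted frame", {
  f <- matrix(runif(24 * 24), 24)
  st <- FrameStack(list(f), pitch = 1.12, bayer = "mono")
  h <- shiftAndAdd(st, factor = 1, normalize = FALSE)
  expect_equal(fieldValues(h), f)
  expect_equal(pitch(h), 1.12)
})

test_that("factor-4 super-resolution reports a 0.28 um pitch", {
  h <- quietHolo96()
  expect_identical(pitch(h), 1.12 / 4)
  expect_identical(dim(h), c(384L, 384L))
  expect_true(all(coverage(h) >= 0))
})

test_that("super-resolution beats single-frame bilinear upsampling", {
  # ground truth on the fine grid, observed only through the 196
  # rectangular sub-pixel shifts
  set.seed(3)
  nr <- 64; fct <- 4
  G <- matrix(rnorm(nr * fct * nr * fct), nr * fct)
  GF <- stats::fft(G)
  fr <- uvholo:::fftFreq(nr * fct, 0.28)
  GF[outer(fr^2, fr^2, "+") > 0.35^2] <- 0
  G <- Re(stats::fft(GF, inverse = TRUE)) / length(GF)
  G <- 1 + 0.1 * G / sd(G)
  sh <- shiftTable(makePattern(14, 0.16, 0))
  fr196 <- lapply(seq_len(nrow(sh)), function(i) {
    gs <- Re(uvholo:::fourierShift(G + 0i, c(sh$dx[i], sh$dy[i]), 0.28))
    uvholo:::blockMean(gs, fct)
  })
  st <- FrameStack(fr196, data.frame(dx = sh$dx, dy = sh$dy),
                   pitch = 1.12, bayer = "mono")
  hs <- shiftAndAdd(st, factor = fct, normalize = FALSE)
  # the accumulation grid sits half a fine cell off the pixel centres for
  # even factors; compare against the identically displaced truth
  Ga <- Re(uvholo:::fourierShift(G + 0i, c(0.14, 0.14), 0.28))
  errSR <- sqrt(mean((fieldValues(hs) - Ga)^2))
  ctrIdx <- which(abs(sh$dx) == min(abs(sh$dx)) &
                  abs(sh$dy) == min(abs(sh$dy)))[1]
  bl <- EBImage::resize(fr196[[ctrIdx]], w = nr * fct, h = nr * fct)
  errBL <- sqrt(mean((bl - G)^2))
  expect_lt(errSR, 0.5 * errBL)
})

test_that("accumulation conserves the mean and ignores frame order", {
  st <- quietStack96()
  nrm <- lapply(frames(st), function(m) normalizeFrame(m, pitch = 1.12))
  h <- shiftAndAdd(st)
  expect_equal(mean(fieldValues(h)), mean(unlist(lapply(nrm, mean))),
               tolerance = 1e-3)
  # permuting the frames does not change the result
  idx <- rev(seq_along(frames(st)))
  stp <- FrameStack(frames(st)[idx],
                    shiftTable(st, "nominal")[idx, ],
                    pitch = pitch(st), bayer = "mono")
  hp <- shiftAndAdd(stp)
  expect_equal(fieldValues(hp), fieldValues(h), tolerance = 1e-12)
})
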