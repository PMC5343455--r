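test_that("a uniform hologram reconstructs to a uniform field", {
  h <- HighResHologram(matrix(2, 32, 32), pitch = 0.28)
  rec <- backpropagate(h, 400)
  expect_lt(diff(range(amplitude(rec))), 1e-9)
  expect_lt(diff(range(phase(rec))), 1e-9)
  expect_error(backpropagate(h, -5), "positive")
})

test_that("backpropagation localizes a simulated particle", {
  h <- singleParticleHolo()
  rec <- backpropagate(h, 400)
  idx <- which(amplitude(rec) == min(amplitude(rec)), arr.ind = TRUE)
  x <- (idx[1, 2] - 0.5) * pitch(h)
  y <- (idx[1, 1] - 0.5) * pitch(h)
  expect_lt(sqrt((x - 48)^2 + (y - 34)^2), 1)
  # defocus: the windowed |phase| peak at the true height beats +/- 40 um
  pr <- round(34 / 0.28); pc <- round(48 / 0.28)
  w <- function(rec) max(abs(phase(rec)[(pr - 7):(pr + 7),
                                        (pc - 7):(pc + 7)]))
  pk <- vapply(c(360, 400, 440), function(z) w(backpropagate(h, z)),
               numeric(1))
  expect_gt(pk[2], 2 * pk[1])
  expect_gt(pk[2], 2 * pk[3])
})

test_that("the hologram field round-trips through the object plane", {
  h <- quietHolo96()
  f <- hologramField(h)
  rt <- propagate(propagate(f, -400), 400)
  expect_lt(max(Mod(fieldValues(rt) - fieldValues(f))) /
              max(Mod(fieldValues(f))), 1e-8)
})

test_that("autofocus finds a particle's height and flags empty fields", {
  h <- singleParticleHolo()
  pr <- round(34 / 0.28); pc <- round(48 / 0.28)
  w <- list(rows = (pr - 10):(pr + 10), cols = (pc - 10):(pc + 10))
  af <- autofocus(h, 300, 500, 1, criterion = "max_phase", window = w)
  expect_false(af$flat)
  expect_lt(abs(af$z2 - 400), 2.5)
  # an empty hologram has a flat metric: z_min plus a flatness flag
  h0 <- HighResHologram(matrix(1, 32, 32), pitch = 0.28)
  af0 <- autofocus(h0, 300, 350, 10)
  expect_true(af0$flat)
  expect_identical(af0$z2, 300)
  expect_error(autofocus(h, 300, 500, 1,
                         window = list(rows = 1:9999, cols = 1:2)),
               "window")
  expect_error(autofocus(h, 500, 300, 1), "zMin")
})

test_that("the amplitude and phase focus criteria bracket the true height", {
  # zero-phase lifting of an in-line hologram displaces the
  # minimum-amplitude and maximum-phase foci to opposite sides of the true
  # height (the defocus phase rotation acts on the object's complex
  # strength); their midpoint stays on target
  sc <- scatterers(x = 48, y = 48, z2 = 400, diameter = 1000,
                   strength = 0.9 * exp(-0.5i))
  st <- simulateStack(sc, makePattern(), sensor = quietSensor(),
                      noise = quietScene(), nPixels = c(96, 96))
  h <- shiftAndAdd(st)
  pr <- round(48 / 0.28)
  w <- list(rows = (pr - 10):(pr + 10), cols = (pr - 10):(pr + 10))
  zAmp <- autofocus(h, 350, 450, 1, "min_amplitude", w)$z2
  zPhs <- autofocus(h, 350, 450, 1, "max_phase", w)$z2
  expect_gt(zAmp, 400 - 1e-9)
  expect_lt(zPhs, 400 + 1e-9)
  expect_lt(abs((zAmp + zPhs) / 2 - 400), 2)
  expect_lt(zAmp - zPhs, 20)
})

peelFixture <- function() {
  cached("peelFixture", {
    mk <- function(withBig) {
      if (withBig)
        scatterers(x = c(40, 60), y = c(54, 54), z2 = 400,
                   diameter = c(1500, 300),
                   strength = c(0.85 * exp(-1.2i), 0.5 * exp(-1.2i)),
                   nanolensGain = c(1, 20))
      else
        scatterers(x = 60, y = 54, z2 = 400, diameter = 300,
                   strength = 0.5 * exp(-1.2i), nanolensGain = 20)
    }
    list(
      big = shiftAndAdd(simulateStack(mk(TRUE), makePattern(),
        sensor = quietSensor(), noise = quietScene(),
        nPixels = c(96, 96))),
      free = shiftAndAdd(simulateStack(mk(FALSE), makePattern(),
        sensor = quietSensor(), noise = quietScene(),
        nPixels = c(96, 96))))
  })
}

test_that("peeling with an unreachable threshold is a no-op", {
  h <- peelFixture()$big
  hp <- peelObjects(h, 400, phaseThreshold = 10)
  expect_equal(fieldValues(hp),
               fieldValues(hologramField(h)), tolerance = 1e-12)
})

test_that("peeling the large object halves the twin ripple at a weak neighbour", {
  fx <- peelFixture()
  hp <- peelObjects(fx$big, 400, phaseThreshold = 0.25)
  expect_true(is.complex(fieldValues(hp)))
  recB <- backpropagate(fx$big, 400)
  recP <- backpropagate(hp, 400)
  recF <- backpropagate(fx$free, 400)
  pr <- round(54 / 0.28); pc <- round(60 / 0.28)
  wr <- (pr - 18):(pr + 18); wc <- (pc - 18):(pc + 18)  # 5 um neighbourhood
  rippleBefore <- sqrt(mean((amplitude(recB)[wr, wc] -
                             amplitude(recF)[wr, wc])^2))
  rippleAfter <- sqrt(mean((amplitude(recP)[wr, wc] -
                            amplitude(recF)[wr, wc])^2))
  expect_lt(rippleAfter, 0.5 * rippleBefore)
  # sensor-plane values far from the peeled object stay put (< 1% of the
  # background level at 20 um)
  d <- Mod(fieldValues(hp) - fieldValues(hologramField(fx$big)))
  xs <- (seq_len(384) - 0.5) * 0.28
  dist <- sqrt(outer((xs - 54)^2, (xs - 40)^2, "+"))
  expect_lt(max(d[dist > 20]), 0.01)
})

test_that("peeling at both planes removes the object from its own plane", {
  fx <- peelFixture()
  recB <- backpropagate(fx$big, 400)
  hp2 <- peelObjects(fx$big, 400, phaseThreshold = 0.25, planes = "both",
                     dilate = 6)
  rec2 <- backpropagate(hp2, 400)
  br <- round(54 / 0.28); bc <- round(40 / 0.28)
  wr <- (br - 8):(br + 8); wc <- (bc - 8):(bc + 8)
  dipBefore <- 1 - min(amplitude(recB)[wr, wc])
  dipAfter <- 1 - min(amplitude(rec2)[wr, wc])
  expect_lt(dipAfter, 0.1 * dipBefore)
})

test_that("peeling refuses a mask that swallows the field", {
  h <- peelFixture()$big
  expect_error(peelObjects(h, 400, phaseThreshold = 1e-6), "background")
})
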