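test_that("a purely low-frequency hologram compensates to one", {
  # constant hologram: the background image equals the hologram itself
  h <- HighResHologram(matrix(1.3, 48, 48), pitch = 0.28)
  comp <- compensatePhase(h, c(380, 400, 420))
  expect_lt(max(abs(comp - 1)), 1e-6)
  expect_equal(attr(comp, "z"), c(380, 400, 420))
  expect_error(compensatePhase(h, numeric()), "non-empty")
})

test_that("the 2*pi offset keeps compensation denominators positive", {
  # wrapped phase lives in (-pi, pi]: after adding 2*pi the denominator is
  # at least pi for any field, including ones with extreme wrapped phase
  set.seed(4)
  v <- matrix(exp(1i * runif(32 * 32, -pi, pi)), 32)
  expect_gte(min(Arg(v) + 2 * pi), pi)
  h <- quietHolo96()
  f <- uvholo:::.pistonNormalize(
    propagate(lowpass(hologramField(h), 0.12), -400)@values)
  expect_gt(min(Arg(f) + 2 * pi), pi - 1e-9)
})

test_that("compensation flattens the background and keeps the particle", {
  h <- singleParticleHolo()
  comp <- compensatePhase(h, 400)[, , 1]
  pr <- round(34 / 0.28); pc <- round(48 / 0.28)
  bg <- matrix(TRUE, nrow(comp), ncol(comp))
  bg[(pr - 20):(pr + 20), (pc - 20):(pc + 20)] <- FALSE
  bgDev <- max(abs(comp[bg] - 1))
  pkDev <- max(comp[(pr - 7):(pr + 7), (pc - 7):(pc + 7)]) - 1
  expect_lt(bgDev, 0.02)
  expect_gt(pkDev, 5 * bgDev)
})

test_that("height averaging attenuates uncorrelated noise like 1/sqrt(N)", {
  expect_equal(averageStack(list(diag(4), diag(4))), diag(4))
  expect_equal(averageStack(list(matrix(0, 2, 2) + c(0, 2),
                                 matrix(0, 2, 2) + c(2, 0))),
               matrix(1, 2, 2))
  set.seed(9)
  base <- matrix(1, 64, 64); base[30:32, 30:32] <- 1.2
  stk <- array(rep(base, 41), c(64, 64, 41)) +
    array(rnorm(64 * 64 * 41, 0, 0.05), c(64, 64, 41))
  avg <- averageStack(stk)
  expect_gt(0.05 / sd(avg[1:20, 1:20]), 5)            # 1/sqrt(41) = 6.4
  expect_equal(avg[31, 31] - 1, 0.2, tolerance = 0.2)  # peak retained
  expect_error(averageStack(list(diag(3), diag(4))), "shape")
})

test_that("candidate thresholding is robust, strict and centroid-accurate", {
  expect_identical(nrow(findCandidates(matrix(1, 32, 32), 6)), 0L)
  set.seed(11)
  img <- matrix(rnorm(128 * 128, 1, 0.001), 128)
  at <- list(c(30, 40), c(70, 100), c(100, 20))
  for (p in at) img[p[1] + (-1:1), p[2] + (-1:1)] <-
    img[p[1] + (-1:1), p[2] + (-1:1)] + 0.05
  cand <- findCandidates(img, kSigma = 6, pitch = 0.28)
  expect_identical(nrow(cand), 3L)
  for (p in at) {
    d <- sqrt((cand$row - p[1])^2 + (cand$col - p[2])^2)
    expect_lt(min(d), 1)
  }
  # a value exactly at threshold is excluded (strict inequality): build an
  # image whose median (1) and MAD (0.05) are exact order statistics that
  # a 4-cell insertion cannot move
  # checkerboard background: its median and MAD are order statistics that
  # do not move when 2 x 2 blocks are replaced by large values, so the
  # threshold of the final image can be computed in advance
  board <- outer(1:64, 1:64, function(r, c) 1 + 0.1 * ((r + c) %% 2))
  ins <- function(v) {
    m <- board
    m[20:21, 20:21] <- v            # exactly at threshold: excluded
    m[50:51, 50:51] <- v + 1e-9     # just above: included
    m
  }
  thr2 <- with(list(m = ins(2)), median(m) + 6 * mad(m))
  thr2 <- with(list(m = ins(thr2)), median(m) + 6 * mad(m))  # fixed point
  cand2 <- findCandidates(ins(thr2), 6)
  expect_identical(nrow(cand2), 1L)
  expect_equal(cand2$row, 50.5)
  # raising the threshold never adds candidates
  n6 <- nrow(findCandidates(img, 6))
  n8 <- nrow(findCandidates(img, 8))
  expect_lte(n8, n6)
  expect_error(findCandidates(img, -1), "positive")
})

test_that("focus curves sample 41 heights and peak at the true height", {
  h <- singleParticleHolo()
  pr <- round(34 / 0.28); pc <- round(48 / 0.28)
  crv <- focusCurve(h, pr, pc, 400)
  expect_identical(length(crv@z), 41L)
  expect_equal(diff(crv@z)[1], 2)
  expect_lt(abs(crv@z[which.max(crv@peakPhase)] - 400), 4)
  # a pure-noise location lacks the particle's focal contrast
  ratioP <- max(crv@peakPhase) / median(crv@peakPhase)
  crvN <- focusCurve(h, 40, 40, 400)
  ratioN <- max(crvN@peakPhase) / median(crvN@peakPhase)
  expect_gt(ratioP, ratioN)
  expect_error(focusCurve(h, 2, 2, 400, windowRadius = 5), "window")
  # precomputed stacks must cover the requested heights
  stk <- compensatePhase(h, seq(360, 440, 2))
  crv2 <- focusCurve(h, pr, pc, 400, stack = stk)
  expect_equal(crv2@peakPhase, crv@peakPhase)
  expect_error(focusCurve(h, pr, pc, 300, stack = stk), "heights")
})

test_that("the three focus criteria classify closed-form curves exactly", {
  z2s <- 400
  zs <- seq(360, 440, 2)
  mk <- function(y) new("FocusCurve", z = zs, peakPhase = y)
  # sharply focusing: passes all three
  fit1 <- classifyCandidate(mk(-1e-5 * (zs - z2s)^2 + 1.2), z2s)
  expect_true(fit1$passed)
  expect_equal(fit1$a, -1e-5, tolerance = 1e-9)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit1$z_peak, z2s, tolerance = 1e-6)
  expect_identical(fit1$reasons, "")
  # too shallow: fails the quadratic-coefficient criterion alone
  fit2 <- classifyCandidate(mk(-5e-6 * (zs - z2s)^2 + 1.2), z2s)
  expect_false(fit2$passed)
  expect_identical(fit2$reasons, "quadratic_coefficient")
  # flat: a = 0, R^2 defined as 0, fails all three
  fit3 <- classifyCandidate(mk(rep(1, length(zs))), z2s)
  expect_false(fit3$passed)
  expect_equal(fit3$a, 0)
  expect_equal(fit3$r_squared, 0)
  expect_identical(fit3$reasons,
                   "quadratic_coefficient,r_squared,peak_distance")
  # displaced peak: fails the distance criterion
  fit4 <- classifyCandidate(mk(-1e-5 * (zs - 380)^2 + 1.2), 420)
  expect_false(fit4$passed)
  expect_match(fit4$reasons, "peak_distance")
  expect_error(classifyCandidate(new("FocusCurve", z = c(1, 2),
                                     peakPhase = c(1, 1)), 400), "3 points")
})

test_that("classification is invariant to a constant curve offset", {
  zs <- seq(360, 440, 2)
  set.seed(2)
  y <- -1.2e-5 * (zs - 402)^2 + 1.1 + rnorm(41, 0, 1e-4)
  f1 <- classifyCandidate(new("FocusCurve", z = zs, peakPhase = y), 400)
  f2 <- classifyCandidate(new("FocusCurve", z = zs, peakPhase = y + 5), 400)
  expect_equal(f2$a, f1$a)
  expect_equal(f2$b, f1$b)
  expect_equal(f2$c, f1$c + 5)
  expect_equal(f2$r_squared, f1$r_squared)
  expect_identical(f2$passed, f1$passed)
})

test_that("the contrast metric follows its closed form and clips at zero", {
  img <- matrix(1, 8, 8)
  tgt <- matrix(FALSE, 8, 8); tgt[4:5, 4:5] <- TRUE
  bg <- matrix(FALSE, 8, 8); bg[1:2, ] <- TRUE
  expect_equal(as.numeric(contrastMetric(img, tgt, bg)), 0)
  img2 <- img; img2[4, 4] <- 0
  expect_equal(as.numeric(contrastMetric(img2, tgt, bg)), 1)
  img3 <- img; img3[4, 4] <- 0.4
  expect_equal(as.numeric(contrastMetric(img3, tgt, bg)), 0.6)
  img4 <- img; img4[4:5, 4:5] <- 1.5
  v <- contrastMetric(img4, tgt, bg)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "clipped"))
  expect_error(contrastMetric(img, tgt, tgt), "disjoint")
  expect_error(contrastMetric(img * 0, tgt, bg), "zero")
})
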