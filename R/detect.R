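#' Background-compensated phase images over a height stack
#'
#' For each height z the hologram is back-propagated twice: once as is, and
#' once after a Gaussian low-pass that removes the nanoparticle holograms
#' and keeps only the slowly varying background (large dust, illumination
#' modulation). The compensated image is the element-wise ratio
#' \code{(phase + 2*pi) / (background phase + 2*pi)}: adding 2*pi before
#' the division keeps both terms positive for wrapped phase in (-pi, pi]
#' (the denominator can never drop below +pi), so no divide-by-zero can
#' occur. Background cells sit near 1; particles stand out as positive
#' deviations.
#'
#' @param holo a [HighResHologram-class] (real, or complex after peeling).
#' @param zList reconstruction heights, micrometres (non-empty).
#' @param cutoff background low-pass standard deviation, 1/um; the default
#'   0.12 is wide enough that slow background structure (including
#'   parasitic fringes with periods of several micrometres) lands in the
#'   background image, while nanoparticle holograms stay out of it.
#' @return 3D array (rows x cols x length(zList)) with attribute \code{"z"}.
#' @export
compensatePhase <- function(holo, zList, cutoff = 0.12) {
  if (!length(zList)) stop("'zList' must be non-empty")
  f <- hologramField(holo)
  fbg <- lowpass(f, cutoff)
  d <- dim(holo)
  out <- array(NA_real_, c(d, length(zList)))
  for (i in seq_along(zList)) {
    ph <- Arg(.pistonNormalize(propagate(f, -zList[i])@values))
    phBg <- Arg(.pistonNormalize(propagate(fbg, -zList[i])@values))
    out[, , i] <- (ph + 2 * pi) / (phBg + 2 * pi)
  }
  attr(out, "z") <- zList
  out
}

#' Average a compensated-phase stack over heights
#'
#' Physical particles stay laterally fixed while focusing and defocusing
#' across reconstruction heights, so they survive an element-wise mean over
#' the stack; noise grains wander laterally and average out.
#'
#' @param stack 3D array from [compensatePhase()], or a list of equally
#'   sized matrices.
#' @return Matrix of element-wise means.
#' @export
averageStack <- function(stack) {
  if (is.list(stack)) {
    d <- dim(stack[[1]])
    if (!all(vapply(stack, function(m) identical(dim(m), d), logical(1))))
      stop("stack planes must share one shape")
    stack <- array(unlist(stack), c(d, length(stack)))
  }
  if (length(dim(stack)) != 3L) stop("need a 3D stack")
  rowMeans(stack, dims = 2L)
}

#' Threshold an averaged phase image into particle candidates
#'
#' The threshold is \code{median + kSigma * 1.4826 * MAD}, a robust sigma
#' rule. Cells strictly above threshold are grouped into 8-connected
#' components; components of at least \code{minSize} cells are reported at
#' their intensity-weighted centroid (weights are the deviations above the
#' image median).
#'
#' @param avgImage matrix from [averageStack()].
#' @param kSigma threshold in robust sigmas (> 0); default 6.
#' @param pitch grid pitch, micrometres, to report positions in um.
#' @param minSize minimum component size, cells.
#' @return data.frame(x, y, row, col, peak, size); zero rows when nothing
#'   crosses the threshold.
#' @export
findCandidates <- function(avgImage, kSigma = 6, pitch = 0.28,
                           minSize = 2L) {
  if (kSigma <= 0) stop("'kSigma' must be positive")
  med <- stats::median(avgImage)
  sigma <- stats::mad(avgImage)  # 1.4826 * MAD
  thr <- med + kSigma * sigma
  mask <- avgImage > thr
  empty <- data.frame(x = numeric(), y = numeric(), row = numeric(),
                      col = numeric(), peak = numeric(), size = integer())
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  w <- avgImage - med
  res <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < minSize) return(NULL)
    wk <- w[idx]
    r <- sum(idx[, 1] * wk) / sum(wk)
    c <- sum(idx[, 2] * wk) / sum(wk)
    data.frame(x = (c - 0.5) * pitch, y = (r - 0.5) * pitch,
               row = r, col = c, peak = max(avgImage[idx]),
               size = nrow(idx))
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}

#' Peak-phase focus curve of a candidate
#'
#' Samples the peak compensated phase inside a window around the candidate
#' across a height range centred on its optimal height: z2* +/- halfRange
#' at the given step (41 heights at the defaults).
#'
#' @param holo a [HighResHologram-class].
#' @param row,col candidate position, fine-grid cells (fractional values
#'   are rounded).
#' @param z2Star candidate's optimal height, micrometres.
#' @param halfRange half-extent of the scan, micrometres.
#' @param step scan step, micrometres.
#' @param windowRadius window half-width, fine cells (default 5, i.e.
#'   1.4 um at 0.28 um pitch).
#' @param cutoff background low-pass cutoff for the compensation, 1/um.
#' @param stack optional precomputed [compensatePhase()] array whose
#'   \code{"z"} attribute contains all requested heights; avoids
#'   recomputing reconstructions when classifying many candidates.
#' @return A [FocusCurve-class].
#' @export
focusCurve <- function(holo, row, col, z2Star, halfRange = 40, step = 2,
                       windowRadius = 5, cutoff = 0.12, stack = NULL) {
  zs <- seq(z2Star - halfRange, z2Star + halfRange, by = step)
  d <- dim(holo)
  r0 <- round(row); c0 <- round(col)
  rows <- (r0 - windowRadius):(r0 + windowRadius)
  cols <- (c0 - windowRadius):(c0 + windowRadius)
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 ||
      max(cols) > d[2])
    stop("candidate window lies outside the grid")
  if (is.null(stack)) {
    stack <- compensatePhase(holo, zs, cutoff = cutoff)
    zi <- seq_along(zs)
  } else {
    zi <- match(round(zs, 9), round(attr(stack, "z"), 9))
    if (anyNA(zi))
      stop("precomputed stack does not contain all requested heights")
  }
  pk <- vapply(seq_along(zs), function(i)
    max(stack[rows, cols, zi[i]]), numeric(1))
  new("FocusCurve", z = zs, peakPhase = pk)
}

#' Classify a candidate by its focusing behaviour
#'
#' Fits an ordinary least-squares parabola \code{y = a z^2 + b z + c} to
#' the focus curve and applies the three focus criteria: (1) the quadratic
#' coefficient must be below \code{aMax} (default -9e-6, in
#' compensated-phase units per um^2 -- a genuinely focusing particle has a
#' sharply concave curve), (2) the R-squared goodness of fit must exceed
#' \code{r2Min} (default 0.42 -- noise grains produce erratic curves), and
#' (3) the parabola's peak \code{-b/(2a)} must lie within \code{zTol}
#' (default 15 um) of the candidate's optimal height. A flat curve has
#' R-squared defined as 0 and fails; a non-concave fit (a >= 0) has no
#' peak and fails criterion 3.
#'
#' @param curve a [FocusCurve-class] with at least 3 points.
#' @param z2Star candidate optimal height, micrometres.
#' @param aMax,r2Min,zTol the three thresholds.
#' @return One-row data.frame: a, b, c, r_squared, z_peak, passed, reasons
#'   (comma-separated failed criteria, empty when passed).
#' @export
classifyCandidate <- function(curve, z2Star, aMax = -9e-6, r2Min = 0.42,
                              zTol = 15) {
  z <- curve@z; y <- curve@peakPhase
  if (length(z) < 3L) stop("need at least 3 points to fit a parabola")
  X <- cbind(1, z, z^2)
  beta <- qr.solve(X, y)
  cc <- beta[1]; b <- beta[2]; a <- beta[3]
  ssRes <- sum((y - X %*% beta)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot <= 0) 0 else max(0, min(1, 1 - ssRes / ssTot))
  zPeak <- if (a < 0) -b / (2 * a) else NA_real_
  reasons <- character()
  if (!(a < aMax)) reasons <- c(reasons, "quadratic_coefficient")
  if (!(r2 > r2Min)) reasons <- c(reasons, "r_squared")
  if (is.na(zPeak) || abs(zPeak - z2Star) > zTol)
    reasons <- c(reasons, "peak_distance")
  data.frame(a = a, b = b, c = cc, r_squared = r2, z_peak = zPeak,
             passed = length(reasons) == 0L,
             reasons = paste(reasons, collapse = ","))
}

#' Amplitude contrast of a target against its background
#'
#' The aggregate-contrast metric: the difference between the average
#' background amplitude and the minimum amplitude across the target,
#' divided by the average background amplitude. A perfect absorber scores
#' 1, an invisible target 0; negative values (target brighter than
#' background) are clipped to 0 and flagged.
#'
#' @param amplitudeImage real matrix (e.g. \code{amplitude(rec)}).
#' @param targetRegion,backgroundRegion logical masks or index matrices
#'   selecting disjoint, non-empty cell sets.
#' @return Scalar in [0, 1]; attribute \code{"clipped"} is TRUE when a
#'   negative raw value was clipped.
#' @export
contrastMetric <- function(amplitudeImage, targetRegion, backgroundRegion) {
  tv <- amplitudeImage[targetRegion]
  bv <- amplitudeImage[backgroundRegion]
  if (!length(tv) || !length(bv))
    stop("target and background regions must be non-empty")
  if (is.logical(targetRegion) && is.logical(backgroundRegion) &&
      any(targetRegion & backgroundRegion))
    stop("target and background regions must be disjoint")
  mb <- mean(bv)
  if (mb == 0) stop("background mean amplitude is zero")
  v <- (mb - min(tv)) / mb
  clipped <- v < 0
  v <- max(0, v)
  attr(v, "clipped") <- clipped
  v
}

#' Detect nanoparticles in a super-resolved hologram
#'
#' The full detection chain: global autofocus (unless a height is given),
#' background-compensated phase reconstruction over a neighbourhood of the
#' sample height, multi-height averaging, robust thresholding into
#' candidates, per-candidate refocusing, and parabola focus-criteria
#' validation.
#'
#' @param holo a [HighResHologram-class].
#' @param z2 sample height, micrometres; NULL to autofocus over
#'   \code{zRange}.
#' @param zRange autofocus search interval c(zMin, zMax), um.
#' @param avgHalfRange,avgStep height neighbourhood for the multi-height
#'   average: z2 +/- avgHalfRange at avgStep (defaults 20 and 1: 41
#'   planes).
#' @param kSigma candidate threshold, robust sigmas.
#' @param windowRadius candidate window half-width, fine cells.
#' @param curveHalfRange,curveStep focus-curve extent and step, um.
#' @param aMax,r2Min,zTol focus criteria thresholds
#'   (see [classifyCandidate()]).
#' @param cutoff background low-pass cutoff, 1/um.
#' @return data.frame with one row per candidate: x_um, y_um, z2_star_um,
#'   avg_phase_peak, a, r_squared, z_peak_um, passed, reasons; the
#'   global sample height is attached as attribute \code{"z2"}.
#' @export
detectParticles <- function(holo, z2 = NULL, zRange = c(300, 500),
                            avgHalfRange = 20, avgStep = 1, kSigma = 6,
                            windowRadius = 5, curveHalfRange = 40,
                            curveStep = 2, aMax = -9e-6, r2Min = 0.42,
                            zTol = 15, cutoff = 0.12) {
  if (is.null(z2))
    z2 <- autofocus(holo, zRange[1], zRange[2], step = 1,
                    criterion = "min_amplitude")$z2
  zsAvg <- seq(z2 - avgHalfRange, z2 + avgHalfRange, by = avgStep)
  compAvg <- compensatePhase(holo, zsAvg, cutoff = cutoff)
  avg <- averageStack(compAvg)
  cand <- findCandidates(avg, kSigma = kSigma, pitch = holo@pitch)
  out <- data.frame(x_um = numeric(), y_um = numeric(),
                    z2_star_um = numeric(), avg_phase_peak = numeric(),
                    a = numeric(), r_squared = numeric(),
                    z_peak_um = numeric(), passed = logical(),
                    reasons = character())
  if (nrow(cand)) {
    # shared focus-curve stack on a grid that covers every candidate's
    # +/- curveHalfRange window around its refined height
    zsAll <- seq(z2 - avgHalfRange - curveHalfRange,
                 z2 + avgHalfRange + curveHalfRange, by = curveStep)
    compCurve <- compensatePhase(holo, zsAll, cutoff = cutoff)
    d <- dim(holo)
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      r0 <- round(cand$row[i]); c0 <- round(cand$col[i])
      rr <- max(1, r0 - windowRadius):min(d[1], r0 + windowRadius)
      cc <- max(1, c0 - windowRadius):min(d[2], c0 + windowRadius)
      # per-candidate optimal height: peak compensated phase over the
      # averaging neighbourhood
      prof <- vapply(seq_along(zsAvg), function(k)
        max(compAvg[rr, cc, k]), numeric(1))
      z2Star <- zsAvg[which.max(prof)]
      # snap the curve centre onto the shared grid
      zc <- zsAll[which.min(abs(zsAll - z2Star))]
      crv <- tryCatch(
        focusCurve(holo, r0, c0, zc, halfRange = curveHalfRange,
                   step = curveStep, windowRadius = windowRadius,
                   cutoff = cutoff, stack = compCurve),
        error = function(e) NULL)
      if (is.null(crv)) return(NULL)
      fit <- classifyCandidate(crv, z2Star, aMax = aMax, r2Min = r2Min,
                               zTol = zTol)
      data.frame(x_um = cand$x[i], y_um = cand$y[i], z2_star_um = z2Star,
                 avg_phase_peak = cand$peak[i], a = fit$a,
                 r_squared = fit$r_squared, z_peak_um = fit$z_peak,
                 passed = fit$passed, reasons = fit$reasons)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) out <- do.call(rbind, rows)
  }
  attr(out, "z2") <- z2
  out
}
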