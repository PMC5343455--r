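#' Fill red/blue Bayer sites from the green channel
#'
#' At 266 nm only the green Bayer sites respond appreciably, so each red
#' and blue position is replaced by the mean of its 4-connected green
#' neighbours (edge positions use whatever neighbours exist). Green values
#' are kept untouched.
#'
#' @param frame numeric matrix with even dimensions.
#' @param pattern Bayer layout; only \code{"RGGB"} is supported.
#' @return Numeric matrix of the same shape, fully green-filled.
#' @export
greenFill <- function(frame, pattern = "RGGB") {
  if (!identical(pattern, "RGGB")) stop("unsupported Bayer pattern")
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr %% 2L || nc %% 2L)
    stop("Bayer frames must have even dimensions")
  green <- outer(seq_len(nr), seq_len(nc), function(r, c) (r + c) %% 2 == 1)
  gf <- frame
  gf[!green] <- NA_real_
  pad <- function(m, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad(gf, d[1], d[2])
    hit <- !is.na(nb)
    acc[hit] <- acc[hit] + nb[hit]
    cnt[hit] <- cnt[hit] + 1
  }
  out <- frame
  out[!green] <- (acc / cnt)[!green]
  out
}

#' Flatten the illumination envelope of a raw frame
#'
#' Divides the frame by its own Gaussian low-pass, removing the slowly
#' varying background illumination modulation while preserving the
#' hologram fringes (frequencies well above the cutoff). The result has a
#' spatial mean close to 1.
#'
#' @param frame numeric matrix (raw counts or intensity).
#' @param cutoff low-pass standard deviation, 1/um (default 0.05: removes
#'   the illumination envelope, keeps hologram fringes).
#' @param pitch pixel pitch, micrometres.
#' @return Normalized frame, dimensionless around 1.
#' @export
normalizeFrame <- function(frame, cutoff = 0.05, pitch = 1.12) {
  if (all(frame == 0)) stop("cannot normalize an all-zero frame")
  lp <- .gaussLowpass(frame, cutoff, pitch)
  frame / pmax(lp, .Machine$double.eps)
}

#' Estimate per-frame hologram shifts by sub-pixel registration
#'
#' Registers every frame against the first via upsampled cross-correlation
#' restricted to a fiducial window -- the signature of a visible object
#' (dust, a mark, a strong particle hologram) on the sample plane. Locking
#' onto a sample-plane feature is what makes the later accumulation average
#' away noise from other planes, which moves by different amounts under
#' tilt.
#'
#' @param stack a [FrameStack-class].
#' @param window list(rows =, cols =) index ranges of the fiducial window,
#'   or NULL for the whole frame. A window tightly enclosing the hologram
#'   of a sample-plane object is strongly preferred under coherent noise:
#'   it keeps the registration from locking onto parasitic fringes, which
#'   move by different amounts.
#' @param upsample sub-pixel refinement factor (100 gives 0.01-pixel
#'   granularity).
#' @param preprocess green-fill (Bayer stacks) and envelope-normalize the
#'   frames before registering.
#' @param minVariance relative variance (var/mean^2) below which the window
#'   is declared featureless.
#' @return The stack with \code{estimatedShifts} filled (micrometres,
#'   hologram displacement on the sensor, anchored to frame 1's nominal
#'   shift so the estimated and nominal tables are directly comparable).
#' @export
#' @param prior \code{"nominal"} restricts each frame's correlation-peak
#'   search to within \code{maxResidual} pixels of its nominal shift (the
#'   galvo table with residual correction); \code{"none"} searches freely.
#' @param maxResidual residual search radius, pixels, used with the
#'   nominal prior.
estimateShifts <- function(stack, window = NULL, upsample = 100,
                           preprocess = TRUE,
                           prior = c("nominal", "none"),
                           maxResidual = 2, minVariance = 1e-8) {
  prior <- match.arg(prior)
  nomTab <- shiftTable(stack, "nominal")
  if (!nrow(nomTab)) prior <- "none"
  fr <- frames(stack)
  if (preprocess)
    fr <- lapply(fr, function(m) {
      if (stack@bayer == "RGGB") m <- greenFill(m)
      normalizeFrame(m, pitch = stack@pitch)
    })
  crop <- function(m) {
    if (is.null(window)) m else m[window$rows, window$cols, drop = FALSE]
  }
  ref <- crop(fr[[1]])
  if (stats::var(as.vector(ref)) / mean(ref)^2 < minVariance)
    stop("no fiducial: the registration window has no contrast; ",
         "use the nominal shift table instead")
  n <- length(fr)
  dx <- numeric(n); dy <- numeric(n)
  for (i in seq(2, length.out = n - 1)) {
    expect <- if (prior == "nominal")
      c(nomTab$dx[i] - nomTab$dx[1], nomTab$dy[i] - nomTab$dy[1]) /
        stack@pitch else NULL
    d <- registerTranslation(ref, crop(fr[[i]]), upsample = upsample,
                             expect = expect, maxResidual = maxResidual)
    dx[i] <- d[["dx"]] * stack@pitch
    dy[i] <- d[["dy"]] * stack@pitch
  }
  # registration is relative to frame 1; anchor the table to that frame's
  # nominal shift so estimated and nominal tables share one origin
  nom <- shiftTable(stack, "nominal")
  if (nrow(nom)) {
    dx <- dx + nom$dx[1]
    dy <- dy + nom$dy[1]
  }
  initialize(stack, estimatedShifts = data.frame(dx = dx, dy = dy))
}

#' Shift-and-add pixel super-resolution with circular averaging
#'
#' Places every frame's pixels onto a \code{factor}-times finer grid,
#' displaced by the negated hologram shift (nearest fine cell), and
#' normalizes the accumulated sums by the per-cell coverage. Rectangular
#' and circular frames enter the same accumulation: the rectangular
#' sub-pixel grid raises the effective sampling rate, while the circular
#' frames raise coverage and average out any structure that does not
#' co-move with the sample plane (speckle, parasitic fringes). Fine cells
#' that receive no sample are filled by interpolation from covered
#' neighbours and flagged with a 0 in the coverage map.
#'
#' @param stack a [FrameStack-class].
#' @param shifts data.frame(dx, dy) in micrometres, or NULL to use the
#'   stack's estimated shifts (falling back to nominal ones).
#' @param factor integer upsampling factor >= 1; the default 4 turns the
#'   1.12 um native pitch into an effective pitch of 0.28 um.
#' @param normalize logical; green-fill (for Bayer stacks) and
#'   envelope-normalize each frame before accumulation.
#' @param cutoff normalization low-pass cutoff, 1/um.
#' @return A [HighResHologram-class] with pitch \code{pitch(stack)/factor}.
#' @export
shiftAndAdd <- function(stack, shifts = NULL, factor = 4L,
                        normalize = TRUE, cutoff = 0.05) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be >= 1")
  if (is.null(shifts)) {
    shifts <- shiftTable(stack, "estimated")
    if (!nrow(shifts)) shifts <- shiftTable(stack, "nominal")
  }
  fr <- frames(stack)
  if (nrow(shifts) != length(fr))
    stop("need one shift per frame")
  if (normalize) {
    fr <- lapply(fr, function(m) {
      if (stack@bayer == "RGGB") m <- greenFill(m)
      normalizeFrame(m, cutoff = cutoff, pitch = stack@pitch)
    })
  }
  nr <- nrow(fr[[1]]); nc <- ncol(fr[[1]])
  hrPitch <- stack@pitch / factor
  NR <- nr * factor; NC <- nc * factor
  acc <- matrix(0, NR, NC)
  cov <- matrix(0L, NR, NC)
  # zero-shift placement: a pixel's sample lands on the fine cell nearest
  # the pixel centre (for even factors the centre falls on a cell boundary;
  # the floor choice biases all frames identically by half a fine cell)
  ctr <- factor %/% 2L
  baseR <- (seq_len(nr) - 1L) * factor + 1L + ctr
  baseC <- (seq_len(nc) - 1L) * factor + 1L + ctr
  for (i in seq_along(fr)) {
    offC <- as.integer(round(-shifts$dx[i] / hrPitch))
    offR <- as.integer(round(-shifts$dy[i] / hrPitch))
    rows <- baseR + offR; cols <- baseC + offC
    okR <- rows >= 1L & rows <= NR
    okC <- cols >= 1L & cols <= NC
    if (!any(okR) || !any(okC)) next
    idx <- cbind(rep(rows[okR], times = sum(okC)),
                 rep(cols[okC], each = sum(okR)))
    vals <- fr[[i]][okR, okC, drop = FALSE]
    acc[idx] <- acc[idx] + as.vector(vals)
    cov[idx] <- cov[idx] + 1L
  }
  filled <- cov > 0L
  out <- acc
  out[filled] <- acc[filled] / cov[filled]
  if (!all(filled)) out <- fillHoles(out, filled)
  new("HighResHologram", values = out, pitch = hrPitch, coverage = cov,
      wavelength = stack@wavelength)
}
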