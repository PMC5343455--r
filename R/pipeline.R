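#' Pipeline configuration
#'
#' Bundles every tunable parameter of the processing chain with the
#' platform defaults: 266 nm illumination, 1.12 um sensor pitch, 4x pixel
#' super-resolution, the 556-position acquisition pattern (14^2 rectangular
#' at 0.16 um plus 12 circles at 0.3 um with 30 positions each), the
#' 300-500 um autofocus search, and the three focus-criteria thresholds
#' (a < -9e-6, R^2 > 0.42, |z_peak - z2*| <= 15 um) with a 6-sigma
#' candidate threshold. Every field can be overridden by argument, and the
#' whole object round-trips through YAML.
#'
#' @param ... named overrides of the defaults listed above.
#' @return list of class \code{"PipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(sr_factor = 2)
#' cfg$wavelength
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    wavelength = 0.266, pixel_pitch = 1.12, sr_factor = 4,
    pattern = list(rect_n = 14, rect_step = 0.16, n_circles = 12,
                   radial_step = 0.3, per_circle = 30),
    z_min = 300, z_max = 500, z_step = 1,
    avg_half_range = 20, avg_step = 1,
    curve_half_range = 40, curve_step = 2,
    a_max = -9e-6, r2_min = 0.42, z_tol = 15, k_sigma = 6,
    window_radius = 5, lowpass_cutoff = 0.05, bg_cutoff = 0.12,
    supersample = 4, n_pixels = c(64, 64), seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return \code{readPipelineConfig}: a \code{"PipelineConfig"};
#'   \code{writePipelineConfig}: \code{path}, invisibly.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @param config a \code{"PipelineConfig"}.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write / read a raw frame stack as a 16-bit TIFF plus shift JSON
#' @param stack a [FrameStack-class].
#' @param path TIFF path; shifts and metadata go to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
writeFrameStack <- function(stack, path) {
  maxv <- 65535
  tiff::writeTIFF(lapply(frames(stack), function(m) m / maxv), path,
                  bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(
    list(pitch = stack@pitch, wavelength = stack@wavelength,
         bayer = stack@bayer, scale = maxv,
         nominal_shifts = shiftTable(stack, "nominal"),
         estimated_shifts = shiftTable(stack, "estimated")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  fr <- lapply(pages, function(p) round(p * meta$scale))
  st <- new("FrameStack", frames = fr,
            nominalShifts = as.data.frame(meta$nominal_shifts),
            estimatedShifts = if (length(meta$estimated_shifts$dx))
              as.data.frame(meta$estimated_shifts) else
              data.frame(dx = numeric(), dy = numeric()),
            pitch = meta$pitch, wavelength = meta$wavelength,
            bayer = meta$bayer)
  st
}

#' Write a super-resolved hologram as a float TIFF with a JSON sidecar
#' @param holo a [HighResHologram-class].
#' @param path TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeHologram <- function(holo, path) {
  v <- holo@values
  pages <- if (is.complex(v)) list(Re(v), Im(v)) else list(Re(v))
  sc <- .tiffScale(pages)
  tiff::writeTIFF(sc$pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pitch = holo@pitch, wavelength = holo@wavelength,
         complex = is.complex(v), offset = sc$offset, scale = sc$scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHologram
#' @export
readHologram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- .tiffUnscale(tiff::readTIFF(path, all = TRUE), meta)
  v <- if (isTRUE(meta$complex))
    matrix(complex(real = pages[[1]], imaginary = pages[[2]]),
           nrow(pages[[1]])) else pages[[1]]
  HighResHologram(v, pitch = meta$pitch, wavelength = meta$wavelength)
}

#' Run the full processing pipeline
#'
#' Simulation (when a scene is given) or ingestion of a recorded stack,
#' followed by pixel super-resolution, reconstruction and particle
#' detection. Every stage writes its artifact into \code{outDir} along
#' with a manifest (configuration, content hashes, package version) for
#' reproducibility.
#'
#' @param config a \code{"PipelineConfig"}.
#' @param scene a \code{"scatterScene"} to simulate, or NULL.
#' @param stack a [FrameStack-class] with recorded frames, or NULL.
#' @param noise a [NoiseScene-class] used when simulating.
#' @param outDir output directory (created if needed), or NULL to skip all
#'   artifact files.
#' @param z2 fixed reconstruction height, or NULL to autofocus.
#' @return The particle report data.frame (see [detectParticles()]),
#'   invisibly; attributes carry the SR hologram and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), scene = NULL,
                        stack = NULL, noise = quietScene(), outDir = NULL,
                        z2 = NULL) {
  if (is.null(scene) == is.null(stack))
    stop("give exactly one of 'scene' or 'stack'")
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  art <- character()
  if (!is.null(scene)) {
    pat <- makePattern(config$pattern$rect_n, config$pattern$rect_step,
                       config$pattern$n_circles, config$pattern$radial_step,
                       config$pattern$per_circle)
    sens <- sensorModel(pixelPitch = config$pixel_pitch)
    stack <- simulateStack(scene, pat, sensor = sens, noise = noise,
                           nPixels = config$n_pixels,
                           supersample = config$supersample,
                           wavelength = config$wavelength,
                           seed = deriveSeed(config$seed, "simulate"))
    if (!is.null(outDir)) {
      p <- file.path(outDir, "stack.tif")
      writeFrameStack(stack, p)
      art <- c(art, p, paste0(p, ".json"))
    }
  }
  stack <- tryCatch(estimateShifts(stack), error = function(e) stack)
  holo <- shiftAndAdd(stack, factor = config$sr_factor,
                      cutoff = config$lowpass_cutoff)
  if (!is.null(outDir)) {
    p <- file.path(outDir, "sr.tif")
    writeHologram(holo, p)
    art <- c(art, p, paste0(p, ".json"))
  }
  report <- detectParticles(
    holo, z2 = z2, zRange = c(config$z_min, config$z_max),
    avgHalfRange = config$avg_half_range, avgStep = config$avg_step,
    kSigma = config$k_sigma, windowRadius = config$window_radius,
    curveHalfRange = config$curve_half_range, curveStep = config$curve_step,
    aMax = config$a_max, r2Min = config$r2_min, zTol = config$z_tol,
    cutoff = config$bg_cutoff)
  if (!is.null(outDir)) {
    p <- file.path(outDir, "particles.csv")
    utils::write.csv(report, p, row.names = FALSE)
    art <- c(art, p)
    manifest <- list(
      package = "uvholo",
      version = as.character(utils::packageVersion("uvholo")),
      config = unclass(config),
      z2 = attr(report, "z2"),
      artifacts = as.list(tools::md5sum(art))
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(structure(report, hologram = holo))
}
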