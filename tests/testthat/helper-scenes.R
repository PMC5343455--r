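# Shared fixtures: everything is generated in code at test time.

# Noise-free monochrome sensor for precision oracles.
quietSensor <- function(pitch = 1.12)
  sensorModel(pixelPitch = pitch, bayer = "mono", shotNoise = FALSE,
              readNoiseSigma = 0)

# One strong "dust" fiducial plus one weak nanolens-boosted particle on a
# 96-pixel frame; the workhorse scene for registration and SR tests.
fiducialScene <- function() {
  scatterers(x = c(30, 66), y = c(66, 30), z2 = 400,
             diameter = c(4000, 300),
             strength = c(0.95 + 0i, 0.5 * exp(-1.2i)),
             nanolensGain = c(1, 10))
}

# A single phase-dominant particle, used for reconstruction and detection
# oracles (positions chosen off the grid centre).
singleParticleScene <- function()
  scatterers(x = 48, y = 34, z2 = 400, diameter = 300,
             strength = 0.5 * exp(-1.2i), nanolensGain = 10)

# Memoized expensive artifacts shared across test files (the 556-frame
# noiseless stack and its super-resolved hologram).
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

quietStack96 <- function() cached("quietStack96", {
  simulateStack(fiducialScene(), makePattern(), sensor = quietSensor(),
                noise = quietScene(), nPixels = c(96, 96))
})

quietHolo96 <- function() cached("quietHolo96", {
  shiftAndAdd(estimateShifts(quietStack96()))
})

singleParticleHolo <- function() cached("singleParticleHolo", {
  st <- simulateStack(singleParticleScene(), makePattern(),
                      sensor = quietSensor(), noise = quietScene(),
                      nPixels = c(96, 96))
  shiftAndAdd(st)
})

# Band-limited random test field on an n x n grid.
randomField <- function(n = 64, pitch = 0.28, wavelength = 0.266,
                        fmax = 0.45 / wavelength, seed = 1) {
  set.seed(seed)
  v <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  V <- stats::fft(v)
  fr <- uvholo:::fftFreq(n, pitch)
  V[outer(fr^2, fr^2, "+") > fmax^2] <- 0
  ComplexField(stats::fft(V, inverse = TRUE) / (n * n), pitch = pitch,
               wavelength = wavelength)
}
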