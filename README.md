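# uvholo

Computational core of a deep-UV (266 nm) lensless on-chip holographic
microscope, for researchers who detect and count nanoparticles or
biomolecular aggregates over sensor-sized fields of view. The sample sits
a few hundred micrometres above a bare 1.12-µm-pitch CMOS sensor; the
recorded interference between background illumination and object-scattered
light is an in-line hologram, and everything downstream is computation.
`uvholo` provides that computation end to end:

* **Angular-spectrum propagation** of complex optical fields
  (`propagate()`): the spectrum is multiplied by
  `exp(2πi·Δz·√((n/λ)² − fx² − fy²))`, with evanescent components decayed
  rather than zeroed.
* **Acquisition simulation** (`simulateFrame()`, `simulateStack()`): 556
  sub-pixel-shifted frames (196 on a ~0.16 µm rectangular grid, 360 on 12
  concentric circles), tilted-illumination hologram shifts `z·tanθ`,
  parasitic reflection fringes and frozen speckle from out-of-sample
  planes, Bayer masking, shot/read noise.
* **Pixel super-resolution with circular averaging**
  (`estimateShifts()`, `shiftAndAdd()`): shift-and-add onto a 4× finer
  grid (0.28 µm effective pitch); the circularly shifted frames smear out
  coherent noise that does not co-move with the sample plane.
* **Reconstruction** (`backpropagate()`, `autofocus()`, `peelObjects()`):
  hologram-to-object back-propagation, focus search by minimum amplitude /
  maximum phase, and digital peeling of large objects' twin images.
* **Nanoparticle detection** (`compensatePhase()`, `averageStack()`,
  `findCandidates()`, `focusCurve()`, `classifyCandidate()`,
  `detectParticles()`): phase background compensation
  `(φ + 2π)/(φ_bg + 2π)`, multi-height averaging over z₂ ± 20 µm,
  robust 6σ thresholding, and the three parabola focus criteria
  (`a < −9×10⁻⁶`, `R² > 0.42`, peak within ±15 µm of z₂*) that separate
  physical particles — which focus — from noise grains — which do not.
* **Mie detection-limit analysis** (`pecForwardRCS()`,
  `equivalentDiameter()`): forward-scattering radar cross section of a
  PEC nanosphere, `σ = (λ²/π)·|S(0)|²` with
  `S(0) = ½·Σ (2n+1)(aₙ + bₙ)`, and the cross-wavelength
  equivalent-diameter solver.

## Worked example

Why build a UV instrument at all? Translate a known detection limit across
wavelengths:

```r
library(uvholo)
pecForwardRCS(250, 532)        # forward RCS of a 250 nm sphere at 532 nm
#> [1] 137872.6                # nm^2
equivalentDiameter(250, 532, 266)
#> [1] 176.6019                # nm
```

A 250 nm particle at green illumination scatters like a ~177 nm particle
at 266 nm — the wavelength change alone buys roughly 70 nm of detection
limit.

Then run the full pipeline on a simulated acquisition:

```r
cfg <- pipelineConfig(z_min = 380, z_max = 420)
sc  <- demoScene(n = 3, fov = 64 * 1.12)   # 3 nanolens-boosted particles + fiducial
rep <- runPipeline(cfg, scene = sc, outDir = "out")
rep[, c("x_um", "y_um", "z2_star_um", "a", "r_squared", "passed")]
#>    x_um y_um z2_star_um         a r_squared passed
#> 1  9.01 16.5        395 -1.23e-05     0.847   TRUE
#> 2 11.87 63.3        400 -1.26e-05     0.845   TRUE
#> 3 63.21 15.8        398 -1.26e-05     0.853   TRUE
```

All three particles are recovered at their simulated positions (to well
under one sensor pixel), their focus curves are sharply concave
(`a < −9e−6`), fit well (`R² > 0.42`), and peak at the sample height —
so all three pass. `out/` receives the raw stack, the super-resolved
hologram, the particle CSV and a manifest with content hashes.

A thin command-line front end over the same functions is installed at
`inst/scripts/uvholo.R` (subcommands `simulate`, `superres`,
`reconstruct`, `detect`, `rcs`, `rcs-equiv`, `run`).

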