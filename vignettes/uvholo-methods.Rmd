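---
title: "Deep-UV lensless holography with uvholo: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-UV lensless holography with uvholo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(uvholo)
```

## The imaging geometry and what this package computes

In a lensless on-chip holographic microscope the sample sits a few hundred
micrometres (`z2`, nominally 300--500 um) above the bare active area of a
CMOS sensor, illuminated by a coherent 266 nm beam. The sensor records the
interference between the undiffracted background and the light scattered by
the sample -- an in-line hologram. Because there are no lenses, the field
of view equals the sensor area and the resolution is set by the 1.12 um
pixel pitch, which pixel super-resolution (SR) then pushes to an effective
0.28 um pitch. `uvholo` implements the complete computational chain of such
an instrument: a physics-based simulator of the acquisition, SR with
circular averaging, angular-spectrum reconstruction, digital object
peeling, multi-height nanoparticle detection with focus-criteria
validation, and a Mie-series detection-limit calculator.

## Field propagation

`propagate()` implements the angular spectrum method: the field's 2D
spectrum is multiplied by
$H(f) = \exp\!\big(2\pi i\, \Delta z \sqrt{(n/\lambda)^2 - f_x^2 - f_y^2}\big)$.
This is an exact solution of the scalar Helmholtz equation for the sampled,
periodic field, so propagation is unitary for propagating components:
round-trips reproduce a band-limited field to better than $10^{-8}$ and
energy is conserved to $10^{-10}$ (both are tested).

Numerical choices:

* **Evanescent components** ($f_x^2+f_y^2 > (n/\lambda)^2$) are attenuated
  with the real decay $\exp(-2\pi |\Delta z| q)$ rather than zeroed. Using
  $|\Delta z|$ means back-propagation also attenuates them -- amplifying
  them would blow up on measurement noise.
* **Boundary**: the FFT window is periodic by default; `pad` zero-pads by
  an integer factor when wrap-around must be suppressed (used in the
  diffraction-integral cross-checks).
* **Units**: all lateral lengths in micrometres; `z` grows from the sensor
  toward the sample, so reconstruction of a recorded hologram propagates by
  $-z_2$ and the twin image lives at $+z_2$.
* A single uniform medium (n = 1) stands between sample and sensor; the
  fused-silica substrate is folded into the effective `z2`, which is what
  the autofocus estimates anyway.

## The simulator: what it emulates and what it does not

`simulateFrame()`/`simulateStack()` build the sample-plane transmission
$t(x,y) = 1 - \sum_i s_i\, g_i\, D_i(x,y)$ on a grid `supersample` (default
4) times finer than the sensor pitch, where $s_i$ is a complex strength
(magnitude = absorption, argument = optical path delay; a *positive* delay
corresponds to a *negative* argument under this sign convention), $g_i \ge 1$
a phenomenological nanolens gain, and $D_i$ an area-faithful disk. The field
is propagated to the sensor, summed coherently with the coherent noise
constituents, squared into an intensity, integrated over the pixel aperture
(box filter), Bayer-masked (only green sites respond at 266 nm by default),
and digitized with gain, Poisson shot noise, Gaussian read noise and
quantization.

Two technical points matter for correctness:

* **Tilts as shifted transfer functions.** A tilted plane-wave carrier
  $\exp(2\pi i f_0 \cdot x)$ is not representable on a periodic grid. It is
  carried analytically by evaluating the transfer function at $H(f + f_0)$;
  since every plane shares the same carrier, it cancels exactly in the
  recorded intensity. For the sub-0.5 degree tilts of this instrument the
  resulting hologram displacement is $z \tan\theta$ per plane to well below
  the ADC quantization, which is also how `simulateStack()` gains its
  speed: the zero-tilt constituent fields are computed once and each frame
  needs only per-constituent Fourier shift ramps and one inverse FFT.
* **Band-limited object propagation.** A nanoparticle's hologram physically
  extends centimetres; in a periodic window it would wrap around and alias.
  Object-plane propagation therefore keeps only spatial frequencies whose
  rays stay inside the window over the distance `z2` (a smooth cos^2
  roll-off avoids ringing). Extended fields -- parasitic plane-wave fringes
  and the frozen speckle -- keep the full kernel, because for them the
  periodic idealization is the correct one.

The coherent `noiseScene()` defaults are two oblique parasitic reflections
(heights 1 and 5 mm, relative field amplitudes 0.03 and 0.02, fringe
periods 9 and 5.5 um) plus a frozen speckle field (contrast 0.04,
correlation length 5 um, height 2 mm). These values are a package choice,
set so that an SR hologram built from the rectangular frames alone retains
clearly visible background structure that circular averaging then removes;
they are not claimed to match any particular instrument. What the simulator
deliberately does *not* model: full Mie scattering at the sensor (a disk
perturbation suffices for sub-wavelength objects), laser pulse structure,
galvo dynamics, vectorial/polarization effects, or partial coherence. A
passing test suite therefore demonstrates the *pipeline's* correctness
under this model, not detector-grade realism.

## Pixel super-resolution with circular averaging

The acquisition pattern (`makePattern()`) is 196 rectangular sub-pixel
shifts (~0.16 um grid) that raise the sampling rate, plus 360 circular
shifts (12 circles, 0.3 um radial spacing, 30 per circle) that are
redundant for resolution but decisive for noise: structure originating at
heights $z_p \ne z_2$ moves by $z_p \tan\theta$ rather than
$z_2 \tan\theta$, so once the accumulation locks onto the sample plane,
everything else is smeared along circles several micrometres across.

`estimateShifts()` registers every frame to the first by upsampled cross
correlation. Two robustness devices are worth documenting. First, the
cross-power spectrum is whitened with a regularized phase-correlation
normalization ($CR/(|CR| + q\,\overline{|CR|})$, default $q = 3$): a few
strong periodic-fringe bins then cannot outvote the broadband hologram
signature of a sample-plane mark. Second, the integer peak search can be
restricted to a small residual window around the nominal galvo table
(`prior = "nominal"`, default 2 pixels), i.e. the table is trusted
coarsely and registration corrects residual positioning errors. Under the
default coherent-noise conditions this keeps the lock on the sample plane
to better than a quarter of a fine cell; in noise-free conditions recovery
is at the 0.005 um level.

`shiftAndAdd()` places each pixel's value onto the nearest cell of a
`factor`-times finer grid displaced by the negated shift, normalizing by
per-cell coverage (sub-cell residuals up to 0.14 um at factor 4 are
accepted; for even factors the pixel centre falls on a cell boundary and
the placement is biased half a fine cell, identically for every frame).
Cells never covered are filled by neighbour interpolation and flagged with
zero coverage. Frames are green-filled and envelope-normalized (division by
their own Gaussian low-pass, cutoff 0.05 um^-1) before accumulation.

## Reconstruction, autofocus and peeling

`backpropagate()` lifts the intensity hologram with a zero-phase square
root -- the standard single-shot in-line treatment; no iterative phase
retrieval is performed anywhere in the pipeline. After each propagation the
global piston phase (the $2\pi z/\lambda$ advance of the background, an
arbitrary constant modulo $2\pi$) is removed by rotating the mean phasor to
zero; without this, phase images at different heights are not comparable
and the wrapped background can sit anywhere in $(-\pi,\pi]$.

One consequence of the zero-phase lift deserves emphasis because it shapes
the autofocus behaviour: for an object with complex strength, defocus
rotates the reconstructed perturbation in the complex plane, so the
minimum-amplitude and maximum-phase foci are displaced to *opposite* sides
of the true height by an amount set by the strength's argument over the
defocus phase-rotation rate (about $\pm 6$ um under the default
conditions). A pure absorber focuses exactly under the amplitude criterion;
a phase-dominant particle focuses to within ~2 um under the phase
criterion; the midpoint of the two criteria stays on target. The detection
chain therefore refines each candidate's height on the compensated-phase
stack (a phase criterion), and the tests assert exactly this derived
behaviour rather than a criteria-agreement that the lift physically
precludes.

`peelObjects()` suppresses the twin-image ripples of large objects:
propagate to the twin plane ($+z_2$; optionally also the object plane),
mask cells whose phase deviates from the background median by more than a
threshold (deviation-from-median was chosen over absolute phase because the
piston is arbitrary), dilate (default 3 cells), and replace amplitude and
phase inside each masked component with the median over a surrounding
annulus (width 10 cells). The result returns to the sensor plane as a
complex hologram. Peeling refuses masks covering more than half the field,
where "background" is no longer defined.

## Detection

`compensatePhase()` divides $(\varphi + 2\pi)$ by
$(\varphi_{bg} + 2\pi)$, where $\varphi_{bg}$ is the phase of the
back-propagated *low-passed* hologram. The $2\pi$ offset guarantees a
denominator of at least $\pi$ for wrapped phase. The background cutoff
(default 0.12 um^-1) is deliberately wider than the envelope-normalization
cutoff: the background image must absorb everything that is *not* a
nanoparticle hologram -- large-dust interference and parasitic fringes with
periods of several micrometres included -- while the nanoparticle
signatures stay out of it. Averaging the compensated stack over
$z_2 \pm 20$ um at 1 um steps (41 planes; the half-range reading of the
neighbourhood was chosen so the focus is bracketed symmetrically) retains
laterally stationary particles and attenuates wandering noise grains by
roughly $1/\sqrt{N}$.

Candidates are cells strictly above `median + kSigma * 1.4826 * MAD`
(default 6 robust sigmas; 8-connected components of at least 2 cells,
intensity-weighted centroids). Each candidate's height is refined on the
averaged stack, its peak compensated phase is traced over
$z_2^* \pm 40$ um in 2 um steps (window radius 5 cells = 1.4 um), and an
ordinary least-squares parabola $y = az^2 + bz + c$ is tested against the
three focus criteria: $a < -9\times10^{-6}$ (per um^2, in the pipeline's
own compensated-phase units -- the bare threshold is dimensionally tied to
this normalization and is config-exposed), $R^2 > 0.42$ (computed against
the curve mean), and $|{-b/2a} - z_2^*| \le 15$ um. Physical particles
focus; noise grains do not.

The `contrastMetric()` reported for aggregates is
(mean background amplitude − minimum target amplitude) / mean background
amplitude, clipped at zero.

## Mie detection-limit analysis

`pecForwardRCS()` evaluates the forward-scattering radar cross section of a
perfect-electric-conductor sphere: with size parameter $x = \pi d/\lambda$,
$a_n = j_n(x)/h_n^{(1)}(x)$,
$b_n = [x j_n(x)]'/[x h_n^{(1)}(x)]'$,
$S(0) = \tfrac12 \sum_n (2n+1)(a_n+b_n)$ and
$\sigma = (\lambda^2/\pi)\,|S(0)|^2$, truncated at
$\lceil x + 4x^{1/3} + 2 \rceil$ terms. Spherical Bessel functions come
from base R's half-integer-order `besselJ`/`besselY`. Since RCS grows
monotonically with diameter in the working range, a detection limit
measured at one wavelength translates to another by bisection
(`equivalentDiameter()`, 0.1 nm tolerance): a 250 nm limit at 532 nm maps
to about 177 nm at 266 nm. Because the equivalence is a ratio within one
convention, it is insensitive to the overall RCS normalization. A
dielectric-sphere mode (`dielectricForwardRCS()`, complex-argument Bessel
functions by downward recurrence) is provided for material realism and
doubles as an independent cross-check: its RCS approaches the PEC value as
$|m| \to \infty$.

## Study conditions and problem sizes

The packaged reference conditions (`demoScene()`) are: a 4 um absorbing
dust particle as registration fiducial, plus phase-dominant 400 nm
particles (strength $0.6 e^{-1.3 i}$) with nanolens gain 32 -- the gain is
the phenomenological stand-in for the self-assembled nanolens that makes
sub-wavelength particles detectable in the first place. End-to-end
validation runs 556 frames of 128 x 128 pixels (a 143 um field) with the
default noise scene and shot/read noise; the circular-averaging property is
demonstrated on 512 x 512 frames at supersampling factor 2 (rendering
accuracy is set by the band-limited propagation and the pixel-aperture
integral, which the coarser grid still resolves; the default factor 4 is
used everywhere objects must be rendered with sub-pixel fidelity at small
frame sizes). These sizes are the package's chosen demonstration scale:
large enough that 20 particles, the fiducial, and the coherent noise
coexist in one field of view, small enough to run routinely.

## Known limitations

* No phase retrieval: twin-image energy is managed (circular averaging,
  background compensation, peeling), not eliminated.
* The nanolens is a gain parameter, not an optical model; per-cell
  transmissions may exceed physical bounds at high gains, which is
  accepted as the price of a linear signal model.
* Detection thresholds are calibrated in the pipeline's own
  compensated-phase units; transferring them to data with different
  normalization requires re-calibration.
* The simulator's coherent-noise amplitudes are plausible, not measured;
  conclusions about absolute detection limits on real sensors require real
  data.
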