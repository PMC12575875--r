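---
title: "Electron Fourier ptychography: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron Fourier ptychography: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efptycho)
```

## The imaging model

Tilted-illumination TEM treats the microscope as a linear filter acting on
the specimen exit wave. A beam tilt of magnitude $\tau$ at azimuth
$\theta$ multiplies the incident plane wave by
$\exp(2\pi i\,\mathbf{k}_\tau\cdot\mathbf{r})$ with
$|\mathbf{k}_\tau| = \tau/\lambda$; for a thin object with transmission
$O(\mathbf{r})$ the recorded image wave in Fourier space is the shifted
object spectrum filtered by the *axial* wave transfer function,

$$\Psi_\mathrm{im}(\mathbf{k}) = \hat O(\mathbf{k}-\mathbf{k}_\tau)\,
  w(\mathbf{k}), \qquad
  w = A\,e^{-i\chi}\,E_t\,E_s .$$

This formulation does not require the weak-phase approximation; the tilt
lives entirely in the exit wave. The components of $w$:

* $\chi(\mathbf{k}) = \pi\lambda C_1 |\mathbf{k}|^2 +
  \tfrac{\pi}{2}\lambda^3 C_3 |\mathbf{k}|^4$, Saxton notation with
  overfocus-positive $C_1$. Higher-order aberrations are deliberately not
  modelled and configuration keys for them are rejected.
* temporal coherence: $E_t = \exp\{-[(\pi\lambda\Delta/2)\,|\mathbf{k}|^2]^2\}$,
  with $\Delta$ the focal spread in nm. Under tilt, the envelope is
  referenced to $|\mathbf{k}_\tau|^2$, so it peaks on the *achromatic
  circle* $|\mathbf{q}+\mathbf{k}_\tau| = |\mathbf{k}_\tau|$ and dips at
  the passband centre by
  $1-\exp\{-[(\pi\lambda\Delta/2)|\mathbf{k}_\tau|^2]^2\}$. This
  convention reproduces the characteristic ≈10 %/≈45 % central losses at
  10/15 mrad for $\Delta = 4.3$ nm at 300 kV, which pins the scale of the
  envelope.
* spatial coherence: a Gaussian source of RMS angular spread $\beta$
  (the "illumination semi-angle", 0.02 mrad in all bundled
  configurations) gives
  $E_s = \exp\{-\tfrac12 (\beta/\lambda)^2 |\nabla\chi|^2\}$, the
  first-order expansion of $\chi$ over the source. At
  $\beta = 0.02$ mrad the RMS-versus-FWHM choice is numerically
  irrelevant.

The *effective* transfer function `effective_wtf()` — the same factors
evaluated at $\mathbf{q}+\mathbf{k}_\tau$ with the constant phase
$\chi(\mathbf{k}_\tau)$ removed — is used for analysing tilt choices
(optimal coupling, annular transfer); the linear phase ramp, a pure image
shift, is excluded from it and handled explicitly by
`compensate_tilt_shift()`. Reconstruction itself always uses the axial
$w(\mathbf{k})$ on the shifted spectrum, matching the forward model
exactly.

Units: nm, 1/nm and radians everywhere inside; constructors take kV, mm
($C_3$) and mrad and convert once.

## Closed-form tilt relations

For an uncorrected instrument ($C_3 > 0$) and underfocus, the tilt
$\tau = \sqrt{-C_1/C_3}$ couples defocus and spherical aberration
symmetrically (27 mrad for $C_1 = -2000$ nm, $C_3 = 2.7$ mm) — but the
temporal envelope makes such large tilts unusable, which is why the
low-fluence protocol uses small tilts (5 mrad costs < 3 % central loss at
$\Delta = 8.5$ nm). Beam tilt also changes the effective defocus by
$2C_3\tau^2$ (6.75 % of the 2 µm defocus at 5 mrad) and shifts the image
by $(C_1\tau + C_3\tau^3)$ along the azimuth, the gradient of the
aberration phase at $\mathbf{k}_\tau$ divided by $2\pi$.

## Synthetic data

`make_phantom()` builds pure-phase specimens (amplitude contrast is off by
default; phase dominates for thin biological objects): `lattice`
(crystalline foil), `blobs` (soft particles), `ice` (zero-mean band-passed
Gaussian noise, the standard amorphous-ice surrogate) and `composite`.
The simulator reproduces the two acquisition protocols: one axial + six
tilts at equal 60° azimuth spacing for radiation-robust samples, and four
tilts with no axial image for low-fluence work. The fluence budget is
split equally across images; the detector draws Poisson counts at
fluence × pixel² expected electrons and applies a unit-DC-gain Gaussian
MTF (σ = 0.35 cycles/pixel by default) — a parametric stand-in for a real
camera characterization, adequate because no analysis here depends on the
exact curve.

Two discretization choices matter:

* **Tilts are snapped to the frequency grid.** The plane-wave factor is
  then exactly periodic on the field of view and the shifted-spectrum
  identity above holds to machine precision as a *circular* DFT shift.
  The snap error is at most half a frequency step (sub-pixel on the
  upsampled canvas).
* **Band limits.** $\exp(i\varphi)$ spreads the spectrum beyond the band
  of $\varphi$; content that crosses the recording Nyquist after the tilt
  shift wraps around. Test fixtures therefore use strictly band-limited
  ice phantoms with $k_\mathrm{hi} + |\mathbf{k}_\tau|$ below Nyquist, so
  the wrap contribution sits at the $\varphi_\mathrm{rms}^2$ level.

## Preprocessing

Defocus is estimated by correlating the rotationally averaged,
background-subtracted amplitude spectrum against envelope-damped
$|\sin\chi(k; C_1)|$ templates over a defocus grid (zero-mean normalized
correlation over 0.1–0.9 Nyquist, parabolic peak refinement). The
background model — a running radial median with a window of 1/20 of
Nyquist — is deliberately simple; it removes the structure envelope
without tracking the CTF oscillation. With 4×4 patches, estimates beyond
3× the (unscaled) median absolute deviation are discarded and the mean ±
standard error of the survivors is reported. A 1-D (radial) correlation
suffices because only $C_1$ is fitted and astigmatism is out of scope;
when $C_3 \approx 0$ the spectrum cannot distinguish ±$C_1$ and the result
carries a `sign_ambiguous` flag — supply a one-signed grid (underfocus for
cryo data) to resolve it from prior knowledge.

Registration is plain phase correlation with parabolic sub-pixel
refinement (exact for integer circular shifts, ≲0.03 px in practice for
sub-pixel ones). Because stage drift and the tilt-induced aberration shift
cannot be separated by registration, the correction is staged: the
measured shift minus the predicted tilt shift is treated as drift and
removed first, then the predicted tilt shift itself — the net translation
equals the measured shift, and the report records all three vectors per
image.

## Reconstruction

The estimate lives as an object spectrum on a canvas of
`upsample` × the measurement shape — same field of view, extended Nyquist
— so each tilt's passband is an integer-offset crop. Per illumination:
crop, multiply by $w$, inverse transform, replace the real-space amplitude
by the measurement, transform back, and add the weighted difference into
the canvas:

$$\hat O \leftarrow \hat O + \alpha\,
  \frac{w^*}{\max|w|^2\,(1+\varepsilon)}\,\Delta\Psi .$$

Both the measured amplitude $\sqrt{I/\langle I\rangle}$ and the model
amplitude are compared in unit-RMS form and the model keeps its own flux:
the measured exposure scale is arbitrary, and the model loses a little
scattered power outside the passband, so matching raw means would bias
every update by that difference (observably ~10⁻³). With the true
spectrum inserted, the data error is ~10⁻⁸ — the model is exactly the
simulator.

**Step size and acceleration.** The decay schedule (×0.5 every 10
iterations, 50 iterations total, unity-amplitude/zero-phase start) is kept
as published practice. The step itself is defined as the *fraction of the
full amplitude-replacement projection* applied per tilt, default
`step0 = 1`: with the max-normalized weighting above, a small constant
step bounds the total movement of the estimate to `step0 × Σ decay` full
replacements regardless of the data — e.g. 0.1 × 19.4 ≈ 1.9 replacements,
which measurably cannot carry the flat initialization to convergence in
50 iterations (phase correlation plateaus near 0.86 on noiseless
seven-image data). A heavy-ball momentum term (0.9) on the canvas after
each sweep accelerates the slowest modes — the low-frequency separation of
phase from amplitude, which every view measures almost degenerately —
without changing the fixed point. Per-frequency Wiener weighting
$w^*/(|w|^2+\varepsilon\max|w|^2)$ was evaluated and is unstable under
sequential full-step updates (overlapping passbands thrash); the
max-normalized form is kept. $\varepsilon = 10^{-3}$ guards the division
where envelopes vanish. Tilt order is fixed as listed (a seeded shuffle is
available); `upsample = 2` suffices while $|\mathbf{k}_\tau|$ does not
exceed the measurement Nyquist. Envelopes are *included* in $w$ during
reconstruction (damped model matches damped data) rather than
deconvolved.

With `iterations = 0` the initial estimate is returned unchanged; NaNs in
an update abort with the iteration index; a passband leaving the canvas is
a configuration error.

## Evaluation

`redundancy_map()` counts, per object frequency, the illuminations whose
effective transfer exceeds a threshold (default 0.10, the conventional
10 % information-transfer limit), intersected with the recorded band
$|\mathbf{q}+\mathbf{k}_\tau| \le$ Nyquist — a tilt only measures what the
detector samples. A binary-disc mode (hard aperture radius, no envelopes)
supports purely geometric reasoning and is tested against brute-force
point-in-disc counting. Only redundancy ≥ 2 frequencies determine the
complex wavefunction; all quality metrics are evaluated inside that mask.

`psnr()` uses the ground-truth dynamic range (max − min) as the peak — the
normalization is configurable to max-only since the convention is not
universal — and removes the mean difference first (the global-phase gauge
of phase retrieval). `circular_average()` averages over annuli one
frequency step wide and conserves energy exactly;
`reflection_i_over_sigma()` scores a Bragg peak as background-subtracted
disc mean over the annulus standard deviation, refusing overlapping
disc/annulus geometry. Power-0.2 display weighting is provided for
visualization only and never enters a metric.

## Study conditions and what the tests show

The bundled fixtures scale the published protocols to desk-size grids;
the suite states its problem sizes explicitly as package choices:

* *Round trip* (noiseless): 256² ice phantom at 0.05 nm/px
  ($\varphi_\mathrm{rms}=0.05$ rad, band 0.3–4.5 nm⁻¹), $C_1=-20$ nm,
  $\Delta=2$ nm, one axial + six 10 mrad tilts, 50 iterations → phase
  correlation > 0.95 inside the redundancy ≥ 2 aperture, data error
  < 10⁻³. The defocus is scaled with the grid so the CTF stays well
  sampled (the 2 µm cryo defocus needs the full 2048²/0.05 nm field it was
  used with).
* *Fluence trend*: four 5 mrad tilts, no axial, $\Delta=8.5$ nm, total
  fluences 10³/3·10³/9·10³ e⁻/nm² on a 256² protein-in-ice composite
  (blob peaks 0.3 rad — a realistic projected protein phase), PSNR against
  the infinite-fluence reconstruction → strictly increasing with fluence.
  At these fluences the per-pixel counts are of order one, so absolute
  PSNRs are low; the *ordering* is the physical claim and is stable
  across seeds.
* *Preprocessing*: 512² ice micrograph at 0.26 nm/px, $C_1=-2000$ nm,
  $C_3=2.7$ mm, $\Delta=8.5$ nm → patch-median defocus within one 25 nm
  grid step; integer registration exact; sub-pixel within 0.1 px;
  aberration-shift compensation residual < 0.5 px.

What passing does *not* show: the phantoms contain no atomistic
potentials, no dynamical (multiple-scattering) contrast beyond the
multislice of smooth phase slices, no radiation damage accumulating over
the series, no detector DQE spectrum, and no beam-tilt miscalibration.
Real-data reconstructions face all of these; the suite validates the
algorithmic chain, not instrument realism.

## Known limitations

* Thin or moderately thick phantoms only; no 3-D (multi-slice)
  ptychography, no probe or aberration refinement in the loop.
* Motion correction within an exposure is out of scope; the package
  expects pre-summed, per-illumination images.
* Astigmatism and higher-order aberrations are not modelled anywhere
  (estimation, simulation, or reconstruction).
* The MRC support is deliberately minimal: mode 2 (float32) stacks with a
  JSON sidecar for tilt metadata.
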