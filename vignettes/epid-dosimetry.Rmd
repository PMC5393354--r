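---
title: "From cine EPID images to absolute water dose: the methods behind epiddose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cine EPID images to absolute water dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiddose)
```

## The measurement problem

An amorphous-silicon flat-panel imager (EPID) mounted on or near a linac
records cine-mode frame stacks during beam delivery. The panel is an
excellent imager — 1024 x 1024 pixels at 0.2 mm over a 20.48 cm square,
up to 50 frames per second — but a poor dosimeter as-is: its
scintillator is not water-equivalent, optical photons spread laterally
("glare"), every pixel has its own gain and dark current, and the raw
numbers are arbitrary ADU. `epiddose` implements the full chain that
turns such stacks into absolute 2D dose-in-water maps at the depth of
dose maximum (d_max), plus the gamma-index machinery used to compare
dose distributions for patient-specific QA.

The chain, in the canonical order the package fixes:

1. **Pixel correction.** With an averaged beam-off dark field
   $\overline{DF}$ and an averaged, offset-corrected open-beam flood
   field $\overline{FF}$ (300 frames each),
   $$I_{corr} = \frac{I_{raw} - n\,\overline{DF}}{\overline{FF}}.$$
   The stored flood is already dark-subtracted (it *is* the per-pixel
   gain map), so it appears alone in the denominator; a raw image
   integrated over $n$ cine frames has accumulated $n$ dark offsets,
   hence the factor $n$. Dead pixels (non-positive gain, or values more
   than `k_mad = 6` MADs from the map median) are filled with the
   median of their live 8-neighbours *after* the correction, so the
   fill lives in gain-free relative units.
2. **Beam-profile restoration.** Flood normalisation flattens the true
   open-beam shape — the "horns" of flattened (WFF) beams, the conical
   falloff of filter-free (FFF) beams. A centre-normalised reference
   profile map multiplies the corrected image to restore it. The
   package applies this *before* deconvolution; the ordering is a
   package decision (the physical chain leaves it ambiguous because the
   profile is smooth on the glare-kernel scale, making the two orders
   equal to well below 0.1%).
3. **Glare deconvolution.** The detector's point response $K_{de}$
   (dose deposition plus optical spread in the scintillator) is
   deconvolved to recover the incident primary fluence,
   $\Psi_p = I_{corr} \otimes^{-1} K_{de}$.
4. **Dose convolution.** A Monte Carlo pencil-beam kernel $K_{pb}$
   (dose in water at d_max per unit incident pencil fluence) converts
   fluence to relative water dose, $D_w = \Psi_p \otimes K_{pb}$.
5. **Absolute calibration.** A reference delivery — 10 x 10 cm², 100 MU
   = 100 cGy at d_max — is pushed through steps 1–4; the central-axis
   reading $D_{EPID}$ (mean of the central 5 x 5 pixels, a package
   choice that suppresses noise without washing out the CAX) gives
   $F_{ABS} = 100\,\mathrm{cGy} / D_{EPID}$, applied per energy mode.
   d_max is 1.5 cm for 6 MV and 6 MV FFF, 2.5 cm for 10 MV and
   10 MV FFF, 3.0 cm for 15 MV.

## Realising the inverse convolution

The inverse in step 3 is not specified by the physics; the package uses
a Wiener-style regularised inverse filter computed on a padded grid:

$$\hat\Psi = \hat I \,\frac{\overline{\hat K}}{|\hat K|^2 +
(\varepsilon \max|\hat K|)^2}.$$

* `regularization_eps` defaults to 1e-3 (dimensionless, relative to the
  kernel's peak spectral magnitude). Direct spectral division is
  unstable wherever $|\hat K|$ is small; the floor trades a bounded,
  quantifiable bias (a flat signal is reproduced to within
  $\varepsilon^2 = 10^{-6}$) for noise control. For noisy data the
  natural scale is the inverse per-pixel SNR.
* Padding is reflective by default, never narrower than the kernel half
  width, so the long glare tails cannot wrap around the panel edges.
* Noise can drive reconstructed fluence slightly negative; physical
  fluence is non-negative, so negatives are clipped to zero by default
  and the clipped count is recorded on the result.
* A pitch mismatch between kernel and image is always an error;
  `resample_kernel()` is the explicit remedy. Silent interpolation is
  how dosimetric scale errors sneak in.

## The two kernels

**Pencil-beam kernel ($K_{pb}$), by Monte Carlo.** A desk-scale photon
transport code generates $K_{pb}$: photons sampled from a packaged
bremsstrahlung-shaped spectrum enter a 30 cm water cube as a pencil
beam; free paths are drawn from the total attenuation coefficient;
interactions are Compton (exact Klein–Nishina sampling via Kahn's
method), photoelectric absorption, or pair production (local deposition
of $E - 1.022$ MeV plus two opposed 511 keV annihilation photons). The
kerma approximation — electrons deposit where they are set in motion —
is the one deliberate simplification: it makes the kernel core slightly
narrower than electron transport would, which is acceptable at d_max
where electronic equilibrium is nearly established, and it buys a
runtime of seconds for 2 x 10⁵ histories. Dose is tallied in a 2-mm
slab at d_max; histories run in independent batches whose spread gives
a per-bin relative standard error; launched = deposited + escaped
energy holds to machine precision by construction, and the test suite
verifies primary transmission against Beer–Lambert and the sampled
scattering angles against the analytic Klein–Nishina law.

The backing cross sections (0.01–20 MeV, ~40 log-spaced energies,
log-log interpolated) are built analytically: Klein–Nishina total cross
section times the electron density of water for Compton, an $E^{-3}$
power law anchored at 10 keV for photoelectric, standard water anchor
values above threshold for pair production. Coherent (Rayleigh) scatter
is excluded by design — under 5% above 100 keV — and the total is
defined as the sum of the partials, so the table is self-consistent
with the transport that samples from it. The value at 2 MeV,
0.0493 cm⁻¹, lands on the accepted water figure.

**Glare kernel ($K_{de}$), parametric.** A full optical-photon
simulation of the scintillator stack is out of scope here; the package
instead ships a parametric radial model per energy mode: a narrow
Gaussian core (sub-millimetre optical spread carrying ~94% of the
response) plus two exponential tails (few-mm and ~cm scales at the
few-percent level), each component normalised to unit 2D integral,
discretised and sum-normalised. Higher energies get a mildly broader
core; FFF modes a slightly larger tail fraction (softer spectrum). The
parameters are package defaults chosen once on these physical grounds
and are user-overridable; the kernel is monotone non-increasing
radially and visibly taller and narrower in the core than $K_{pb}$, as
a detector response should be.

**Spectra.** Per-mode spectra are $w(E) \propto E\,e^{-E/E_0}$
truncated at the nominal MV, with $E_0$ solved so the mean energy is
nominal/3 for WFF beams and 15% lower for FFF beams (no flattening
filter to harden the beam). These are stand-ins for commissioning-data
spectra and are replaceable via `photon_spectrum()`.

## Gamma-index comparison

`gamma_index()` implements the standard 2D gamma test with global
normalisation: a point passes criteria like 3%/3mm if some nearby
reference point is simultaneously close in space (scaled by the DTA)
and in dose (scaled by the dose criterion as a fraction of the
*reference global maximum*). Points below 10% of the reference maximum
are excluded, matching the validation protocol.

Numerics: the comparison runs on the evaluated grid; the reference is
bilinearly resampled once onto a lattice refined by `interp_factor`
(default 4) and searched over all offsets within 3 x DTA, visited in
order of increasing distance with early termination — provably
identical to the exhaustive search within the radius, and the suite
checks it against a brute-force implementation to 1e-6. The refined
lattice spacing bounds the DTA discretisation error. Grids may differ
(a 10 mm ion-chamber array against a sub-mm EPID grid); evaluated
points whose entire search region misses the reference extent are
excluded from the evaluated mask and counted, rather than silently
passed or failed. Local normalisation is available as an option but no
headline behaviour depends on it.

## The synthetic test bench

Everything above is testable without a linac because the package also
ships the forward model. `panel_model()` describes the detector: a
mean-1 Gaussian gain map (σ = 3%), a dark fixed pattern (50 ± 5 ADU),
2 ADU read noise, an ADU conversion such that a unit-amplitude delivery
integrates to 10⁴ counts per pixel — i.e. per-pixel SNR ≈ 100, the
noise level the round-trip claims are stated at — over 50 cine frames.
Real panel gain dispersion and dark magnitudes are not published for
this hardware; these are stated package choices, not hardware claims.
`simulate_epid_stack()` convolves a ground-truth fluence with
$K_{de}$, splits it over frames, and applies Poisson counting noise,
gain, dark and read noise per frame, reproducibly under a seed.
Calibration floods default to 25 x the reference amplitude over 300
frames, as real calibration exposures deliver far more signal than one
delivery — otherwise flood noise would imprint a fixed pattern on every
corrected image.

Fields are binary apertures (squares, rectangles, circles, even-odd
rasterised MLC polygons) blurred by a Gaussian penumbra (default
σ = 3 mm, a realistic d_max penumbra) and shaped by the mode's open-beam
profile: WFF horns of +4% at 8 cm off-axis, FFF falloff of −15% at
8 cm — plausible magnitudes chosen once, since the matching water-scan
curves are not published. Multi-segment "plans" sum random rectangular
segments into one composite fluence, emulating the time-integrated
image of a modulated delivery; gantry rotation is deliberately not
simulated, matching the integrated-image comparison workflow.

One subtlety: output factors. The CAX dose of a field depends on field
size through the $K_{pb}$ scatter tails, so a generator cannot just set
amplitude ratios and call them output factors.
`solve_field_amplitudes()` inverts this: it finds, per field size, the
amplitude whose *ground-truth* CAX output factor equals the requested
value, and the recovery tests then ask the full inverse chain to
reproduce those values.

Because the simulator's detector model is the same
linear-shift-invariant glare convolution the inverse chain assumes,
round-trip tests isolate the pipeline's correctness rather than its
robustness; the `mismatch_kernel` argument of `simulate_epid_stack()`
deliberately blends in a second kernel (10%) to probe the latter. What
passing tests therefore demonstrate is internal consistency of the
published chain at realistic noise, not agreement with any physical
panel: ghosting, dose-rate dependence, backscatter structure and
beam-spectrum drift are all outside the forward model.

## Problem sizes and numerical choices

The suite and the acceptance script run on desk-scale grids that keep
the physical extent of the hardware: 128 px at 1.6 mm or 256 px at
0.8 mm span the same 20.48 cm panel. Monte Carlo kernels use 10⁵–2x10⁵
histories (per-bin SE on the centre bin well under 1%); deconvolution
round trips run at 256²; gamma oracle equivalence at 32² where the
brute force is exact and affordable. Seeds are explicit everywhere
randomness exists — panel structure, acquisitions, Monte Carlo, plans —
and identical seeds give bit-identical results.

Known limitations, stated plainly: kerma approximation (narrower
$K_{pb}$ core than reality); parametric glare model in place of optical
transport; no ghosting/lag, dose-rate or temperature effects; 2D only,
at d_max, with the build-up slab absorbed into the kernels rather than
modelled; gamma DTA resolved to the refined lattice rather than exactly.
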