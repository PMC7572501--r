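---
title: "Methods: models, parameters and design choices in lumipipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lumipipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lumipipe` post-processes light-sheet microscopy stacks of cleared tissue.
This vignette explains the science each stage implements, the tunable
parameters and their defaults, what the synthetic phantom does and does not
emulate, the numerical choices that matter for reproducibility, and the
known limitations. Nothing here states an empirical result that the test
suite does not itself compute.

## The image model

A stack is an ordered set of 2D grayscale planes, `(z, y, x)` with `y`
increasing downward, unsigned 8- or 16-bit. All processing is strictly
per-plane: stripe shadows, contrast loss and blur are 2D phenomena of each
optical section, and per-plane processing keeps memory bounded and results
independent of stack partitioning (a property the tests assert). 16-bit
input is the intended case: adaptive equalization can only rescue small
brightness differences that the quantization has not already destroyed,
hence the full 65,535-level range is preserved end to end.

## CLAHE

Per tile, the intensity histogram (`n_bins` bins over the dtype range) is
clipped at `clip_limit * tile_pixels` and the clipped excess is
redistributed uniformly across all bins. Redistribution is single-pass and
*real-valued*: every bin receives `excess / n_bins`, which conserves
histogram mass exactly (asserted during mapping construction). Integer
single-pass dialects that dump the residual into the clip level do not
conserve mass; we prefer the exactly conservative variant since it is just
as deterministic and simpler to reason about.

The per-tile mapping is `m(b) = round(cdf(b) / N * (2^bit_depth - 1))`.
Pixels are blended bilinearly between the mappings of the four tiles whose
centres surround them; outside the centre lattice the tile coordinate is
clamped (replicate), so the half-tile frame at the plane border uses the
nearest tile's mapping — no dark frame artefacts.

Defaults: `tile_grid = 8x8`, `clip_limit = 0.01`, `n_bins = 2^bit_depth`.
The tile grid and clip limit follow the conventional CLAHE practice; the
bin count matches the dtype so no grey levels are merged before
equalization. With one tile and `clip_limit = 1` the operation reduces to
plain global histogram equalization, which the tests verify against a
brute-force cumulative-histogram oracle.

## Pie-slice destriping

### Geometry and angle conventions

Stripe shadows make an angle α with the horizontal image edge, measured
counter-clockwise as displayed (y down on screen), stored mod 180 since
stripes are undirected. Their spectral energy lies along a ray at 90 − α
in the centred power spectrum, where spectral angles θ are taken as
`atan2(uy, ux)` on the centred frequency grid. The opposite handedness of
the two measurements is deliberate: it is what makes the familiar
"90 − α" relation hold, and the cross-module tests (generator -> estimator
-> filter) pin it down numerically.

The wedge is a symmetric trapezoid in (radius, transverse-offset)
coordinates: radii `d1..d2`, full transverse width linear from `w1` at
`d1` to `w2` at `d2`, plus its point mirror. This is the simplest shape
consistent with four distances and one angle. `d2` may be the token
`"nyquist"`, resolved per plane shape as `min(rows, cols) / 2`; a numeric
`d2` beyond the largest representable radius is clamped to Nyquist with a
logged warning.

### Mask construction

The binary wedge is smoothed by convolution with an isotropic Gaussian
(`edge_sigma`, truncated at 4σ) — a smooth transition profile applied to
the arbitrary wedge shape rather than an analytic radial formula — then
the mask `1 - attenuation * smoothed_wedge` is made *exactly*
point-symmetric by averaging with its mirror (for even dimensions the
unmatched Nyquist row/column maps to itself), and the DC gain is forced to
1 so the mean intensity is preserved. Exact symmetry guarantees a real
inverse transform; the filter asserts that the imaginary residual stays
below `1e-6` of the dtype maximum and treats anything larger as a
programming error, not data.

### Rescaling

The inverse transform is real-valued but unbounded. Two modes are offered
because "rescaling" is genuinely underdetermined: `clip` (default)
truncates to the dtype range, preserving absolute intensity comparability
across planes — important when a threshold segmentation follows; `minmax`
affinely maps onto the input's own range, maximizing per-plane contrast at
the cost of comparability. Defaults: `attenuation = 1`, `edge_sigma = 2`,
`d1 = 5`, `d2 = "nyquist"`, `w1 = 3`, `w2 = 9`.

### Angle estimation

`estimate_stripe_angle()` builds a direction histogram of spectral power:
each plane is mean-subtracted, windowed by a *radial* Hann window, and its
centred log-power spectrum computed; the median across planes (log-domain,
robust to single-plane outliers) is converted back to power and summed
over `180 / n_theta`-degree direction bins within a radial band, excluding
a 3-pixel guard block around DC. The peak bin θ\* gives α = (90 − θ\*) mod
180. Numerical choices that matter, found the hard way and locked in by
tests:

* the window must be radially symmetric — a separable window's
  cross-shaped sidelobes bias the 0°/90° bins;
* the per-bin statistic must be power, not log-power — summing log-power
  lets bin pixel-count imbalance dominate the histogram;
* the default radial band is `(Nyquist/4, Nyquist)`: stripe shadows are
  only a few pixels wide, so their energy extends to the highest spatial
  frequencies, whereas thick anatomical structures (vessels, nuclei)
  concentrate at low frequency. Estimating in the upper band separates the
  two without any segmentation.

When the peak is less than `confidence_ratio` (default 2) times the median
bin power, the estimate carries a `low_confidence` attribute and a warning
— isotropic planes have no meaningful stripe direction.

## Unsharp masking

`detail = plane − G_sigma(plane)`; where `|detail| > threshold`, `out =
plane + amount * detail`; rounded and clipped to the dtype. The Gaussian
uses reflected (edge-duplicating) borders to avoid halo at plane edges.
Defaults `sigma = 1.5`, `amount = 0.5`, `threshold = 0` implement a
deliberately slight sharpening; all three are config-exposed. The operator
is linear in the input before clipping when `threshold = 0`, and the tests
compare it against a direct 2D convolution oracle.

## The pipeline

The stage order `clahe -> destripe -> unsharp -> segment -> colormap` is
frozen: configurations choose a subset, never a permutation, because the
chain's benefit depends on the sequence (equalize first, then remove the
amplified stripes, then sharpen). `alpha = "auto"` is resolved once per
stack from up to 16 evenly spaced planes. The run report echoes the
effective (default-filled) configuration, records per-plane stripe-band
energy before and after destriping, and checksums input and output, making
runs auditable and reproducible; reports are deterministic modulo wall
times.

## The phantom: a stated world

`generate_phantom()` emulates the intensity structure of autofluorescence
recordings of cleared tumour tissue:

* textured background (low-pass Gaussian field, `texture_sigma = 8` px,
  amplitude fixed at 10% of the background level of 8000);
* bright tubular vessels (random-walk centrelines, radius 3–6 px,
  intensity 50,000) — the brightest tissue classes in such recordings are
  vascular/collagen structures;
* dark ellipsoidal nuclei (radius 2–4 px, intensity 2,000);
* multiplicative occluder shadows: each occluder casts a *half-line* band
  downstream along the stripe direction (width 3 px, gain
  `1 - attenuation`, floor-bounded), matching the physics of a particle
  obstructing the illumination sheet — shadows reduce excitation
  proportionally, hence multiplicative, not additive;
* Gaussian read noise (σ = 200), optional Poisson shot noise (off by
  default).

Structure edges use distance-based partial coverage
(`clamp(R + 0.5 − d, 0, 1)`) as the anti-aliasing rule — equivalent in
effect to one level of supersampling for these primitives — and the truth
masks apply the 50% coverage rule. Consequently the intensity threshold
matched to a truth mask is the *half-intensity* between background and
structure.

Determinism: three sub-seeds (`seed`, `seed+1`, `seed+2`) drive
structures/texture, occluder placement, and noise separately, so the
stripe-free twin (`occluders_per_plane = 0`, same seed) shares structures
*and* noise draws with its striped sibling and differs only through the
shadow field. The tests rely on this to measure destriping error directly.

What the phantom does **not** emulate: optical point-spread blur,
scattering, depth-dependent attenuation, realistic histological texture,
or diffraction spreading of shadows (width is constant along the ray, for
testability). A green destriping test therefore establishes correctness of
the frequency-domain machinery on a known stated world, not clinical
performance on tissue.

## Protocol calculators

* `dmp_mass_for_water()`: 1:1 hydrolysis stoichiometry,
  `water_mass x 104.15 / 18.02` = 5.78 g per gram of water. The volume
  companion divides by density (0.847 g/mL) and yields 6.82 mL — notably
  *not* the 8 mL sometimes quoted alongside the mass figure; the mass is
  treated as primary and the volume derived transparently.
* `undersampling_factor()`: `block / (section x n_sections)`; 3000/5 = 600
  and 4000/5 = 800 bracket the conventional estimate for standard
  histology.
* `volume_shrinkage_percent()`: per record `(1 − V_post/V_pre) x 100`,
  unweighted arithmetic group means, swelling reported as negative.
  Dimension triples are converted by the rectangular product; volumes are
  accepted directly so no measurement geometry is presumed. The shipped
  `shrinkage_synthetic.csv` is a **synthetic** stand-in table (n = 16 per
  group, constructed to group means of 10% and 31%) used to exercise the
  CSV path; it is not measurement data.

## Storage and configuration

Stacks are uncompressed grayscale TIFF — the de facto interchange format
for microscopy slice stacks — via a minimal built-in baseline codec
(uint8/uint16, both byte orders on read, little-endian on write);
floating-point, RGB, compressed or tiled pages are rejected with a message
naming the offending page rather than converted silently, because the
pipeline's rescaling contracts are defined on unsigned integers. Directory
sequences are ordered by the numeric value of the last integer group in
each filename (robust to inconsistent zero padding). Configurations are
single YAML documents with a schema version; unknown keys anywhere are
errors, and omitted stage parameters are filled with the package defaults
so the run report can echo the complete effective configuration.

## Known limitations

* **Residual stripe energy is irreducible by a pie filter alone.** Two
  properties of the (physically motivated) shadow model spread stripe
  energy outside any wedge: half-line shadows have broadband spectra
  (their terminations act like point sources), and multiplicative shadows
  are modulated by the anatomy, creating structure-times-gain cross terms
  far from the stripe ray. In-wedge energy suppression is essentially
  complete (the acceptance test measures ≥ 90%), but the RMS distance to
  the stripe-free twin improves far less, and widening the wedge starts
  removing anatomy faster than stripe residue. The acceptance suite keeps
  the strict RMS expectation and documents its failure rather than
  loosening it.
* Angle estimation assumes a single dominant stripe direction per stack;
  multi-directional artefacts need multiple runs.
* CLAHE tile boundaries assume roughly stationary contrast statistics per
  tile; extreme tile grids on tiny planes are rejected rather than padded.
* The TIFF codec intentionally covers only the baseline grayscale profile;
  proprietary microscope formats are out of scope.
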