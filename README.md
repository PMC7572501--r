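# lumipipe

Computational post-processing for light-sheet (ultramicroscopy) recordings
of cleared tissue, aimed at 3D histopathology: large tumour resectates are
rendered transparent, imaged as stacks of hundreds to thousands of optical
sections, and the monochrome autofluorescence images are then enhanced so
that diagnosis-relevant structures (vessels, collagen, erythrocytes,
nuclei, fat) become visible. `lumipipe` implements the enhancement chain as
a tested R library plus a command-line tool, together with a synthetic
phantom generator (so everything is testable without patient data) and
small calculators for the clearing protocol's arithmetic.

## The processing chain

Each plane of a stack is processed independently, in a fixed order:

1. **CLAHE** — contrast-limited adaptive histogram equalization. On a grid
   of tiles, each tile's histogram is clipped at `clip_limit x tile_pixels`,
   the excess redistributed uniformly, and the cumulative mappings blended
   bilinearly between tiles. For 16-bit input the default bin count is
   65,536 so that barely perceptible brightness differences survive
   equalization instead of being quantized away.
2. **Destriping** — shadow stripes cast by light-absorbing particles run at
   an angle α to the horizontal image edge; in the centred 2D power
   spectrum their energy concentrates along a ray at 90 − α. The filter
   multiplies the spectrum by a mask that attenuates a pie-slice (wedge)
   region there: radii `d1..d2`, transverse width interpolating `w1 -> w2`,
   edges softened by a Gaussian transition profile (`edge_sigma`) to avoid
   ringing, point-symmetric by construction so the filtered image stays
   real. α can be given or estimated from the data
   (`estimate_stripe_angle()`, a direction histogram of spectral power).
3. **Unsharp masking** — `out = plane + amount x (plane − G_sigma(plane))`
   wherever the detail exceeds `threshold`; a slight final sharpening.
4. Optional **threshold segmentation** (intensity intervals -> label
   volume) and **colour mapping** (brightness -> RGB through piecewise
   linear maps) for 3D visualization of the monochrome recordings.

## Worked example

```r
library(lumipipe)

ph <- generate_phantom(phantom_spec(shape = c(8, 256, 256),
                                    stripe_angle_deg = 25, seed = 7))
cfg <- pipeline_config(list(
  list(clahe    = list(n_bins = 65536L)),
  list(destripe = list(alpha = "auto", edge_sigma = 1)),
  "unsharp"))
res <- process_stack(ph$stack, cfg)
```

prints (via the summary lines below):

```
<image_stack 'phantom-seed7': 8 plane(s) of 256 x 256, 16-bit>
resolved stripe angle: 25 degrees
mean stripe-band energy: 3.48e+17 -> 1.7e+16 (95.1% removed)
```

The phantom was generated with stripes at 25 degrees; `alpha = "auto"`
recovered exactly 25, and the matched wedge removed 95% of the spectral
energy in the stripe band (`res$report$per_plane` holds the per-plane
before/after energies). The protocol calculators:

```r
dmp_mass_for_water(1)            # 5.78  (grams of DMP per gram of water)
dmp_volume_for_water(1)          # 6.82  (mL, via density 0.847 g/mL)
undersampling_factor(3000, 5, 1) # 600   (one 5 um section of a 3 mm block)
```

5.78 g rounds to the protocol's quoted 5.8 g of
2,2-dimethoxypropane per gram of tissue water; a 3–4 mm block sampled by a
single 5 µm section is undersampled by a factor of 600–800.

## Command line

```sh
./exec/lumipipe phantom --output ph/ --seed 7 --alpha 25
./exec/lumipipe estimate-angle --input ph/phantom.tif
./exec/lumipipe run --config cfg.yaml --input ph/phantom.tif --output out.tif
./exec/lumipipe calc dmp --water 1
```

`run` writes the processed stack, a JSON run report (parameter echo,
per-plane stripe-band energies, checksums), and any segmentation/colormap
side outputs next to it. Configs are YAML; see `load_config()`.

## Scope

No wet-lab protocol logic, microscope control, surface rendering, or
oblique reslicing; stacks are processed strictly per-plane (2D), matching
how the enhancement chain is defined.
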