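---
title: "Voxel-cube quantification of 3-D co-culture stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-cube quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voxcube)
```

## The analysis model

`voxcube` targets dense 3-D co-cultures in which individual cells cannot
be segmented. Instead of per-cell measurements it produces per-*region*
measurements on a fixed grid of 32 × 32 × 16-voxel cubes (x, y, z), gated
by a nuclei-derived foreground mask, and discriminates cell populations
*statistically* through a marker threshold learned from mono-cultures.
Every stage is deterministic given its inputs; all randomness in the
package lives in the synthetic generator and the colocalization
randomization test, both seeded.

### Segmentation

The DAPI channel is smoothed with a separable Gaussian, σ = (4, 4, 0)
pixels in (x, y, z), and thresholded at the Otsu value of the whole
smoothed volume.

* σ~z~ = 0 is taken literally: no smoothing across z at all, implemented
  as exact plane-wise 2-D convolution. With ~1-µm z steps the axial
  sampling is much coarser than lateral sampling, and the optical PSF
  already couples neighbouring planes.
* The large in-plane σ is not for noise suppression — it deliberately
  bleeds nuclear signal into the perinuclear space so that the mask
  covers cell bodies ("adjacent regions"), which is where cytoplasmic
  markers live.
* One *global* Otsu threshold is computed (256 bins spanning the volume's
  min–max), not per-plane thresholds: a single threshold is what makes
  cube foreground fractions comparable across the stack. Comparison is
  `>=` (ties are foreground) so boundary behaviour is exactly testable.
  When several splits tie in between-class variance (an empty histogram
  valley), the middle tying edge is returned, which keeps the threshold
  scale-equivariant and centred.
* Thresholding happens on the *raw* smoothed volume; background
  subtraction (per-channel median of mask-negative voxels, clipped at 0)
  follows it. The background median and the Otsu threshold are both
  recorded for audit. The median was chosen over the mean because the
  background sample inevitably contains residual cell signal.

### Cube quantification

Cubes tile from the origin in half-open blocks; trailing margins that do
not fill a whole cube are dropped, so every retained cube has the same
denominator (16 384 voxels). The acquisition geometry this analysis was
designed for (1024 × 1024-px planes) is divisible by 32, so in practice
only z margins are ever dropped. Inclusion demands *strictly more than*
50 % foreground; the boundary case (8 192 of 16 384) is excluded and
pinned by a test. Channel means are taken over foreground voxels only —
including the DAPI channel, for uniformity — on the background-subtracted
stack.

### Discrimination

The reference cutoff is the smallest observed fibroblast-mono-culture
cube CEA mean such that at least 95 % of those cubes lie at or below it
(the `ceiling(0.95 n)`-th order statistic). A rank statistic, not an
interpolated quantile, because the quantity being honoured is a
*coverage* statement ("contains 95 % of cubes"); with an interpolated
quantile the realised coverage could dip below 95 %. Cubes exactly at the
cutoff count as contained (fibroblast side). Because the split is known
to skew towards the CEA-bright population, classified tables always
carry their compartment sizes, and summaries never report a compartment
mean without its n.

### Volumetric intensity

The per-µm³ path sums a channel over all mask-positive voxels and divides
by their physical volume — no cubes, no inclusion rule. The denominator
is the *foreground* volume, not the imaged volume: cavity fields contain
large cell-free regions and using the full volume would dilute the
measure by empty space. Absolute values are in arbitrary intensity units
per µm³; only ratios and orderings between conditions are meaningful.

### Colocalization

Thresholded Pearson correlation in the Costes style: thresholds descend
along the orthogonal-regression line of channel B on channel A until the
correlation of sub-threshold voxels is ≤ 0; r is then computed over
voxels above threshold in either channel. The descending scan uses 256
candidate levels across channel A's range — the same discretisation as
the Otsu histogram — because scanning every distinct voxel value is
quadratic in volume size and adds no precision beyond the acquisition bit
depth. Significance comes from shuffling 3 × 3-px blocks (the PSF scale)
of channel A within each z-plane; z is never mixed because the PSF
parameter is a single in-plane scalar. Partial edge blocks are permuted
within their own shape group, which conserves each plane's histogram
exactly. The p-value uses the add-one rule, so with the reference setting
of 10 randomizations the smallest attainable p is 1/11 ≈ 0.091;
`n_randomizations` is configurable and should be raised when finer
p-resolution matters. Thresholds are computed once from the observed pair
and reused for the randomized recomputations (the marginal histograms are
conserved by the shuffle).

### 2-D ROIs

The monolayer path formalises only the stated thresholds: cell mask from
smoothed DAPI (Otsu), cancer mask from smoothed CEA within the cell mask
(Otsu), fibroblast mask as the remainder after dilating the cancer mask
by a 2-px guard band against edge bleed. Real cell-type calls on
monolayers also used morphology by eye; that is not modelled, and the
guard-band radius and smoothing σ are declared, configurable parameters
reported in output. SEM is computed across replicate images, never across
pixels. A CEA channel without contrast inside the cell mask yields an
empty cancer mask (and the compartment is reported missing, never zero).

## The synthetic generator

`generate_stack()` emulates what the analysis assumes about the data, at
the scale the tests need:

* **Nuclei** are rigid random-orientation ellipsoids placed without
  overlap by rejection sampling. Defaults: cancer-like nuclei with
  semi-axes ≈ 4.2 µm and axis ratio ≈ 1.15 at DAPI 240 ± 30; fibroblast-
  like nuclei with short semi-axis ≈ 3.5 µm, axis ratio ≈ 2.8 (spindle
  nuclei ≈ 20 µm long) at DAPI 80 ± 12 — a 3× nuclear brightness contrast.
* **Cytoplasm** is a perinuclear halo (2.5–3 µm) carrying the marker
  channels: CEA 120 ± 60 (cancer) vs 30 ± 15 (fibroblast), collagen IV
  mirrored — a 4× contrast with strong per-cell heterogeneity, echoing
  the broad and partly bimodal marker distributions seen in real
  stainings. The halo also emits 30 % of the nuclear DAPI level,
  standing in for RNA-bound dye and out-of-focus nuclear light that
  brighten the cell mass between nuclei.
* **Geometry.** Cells occupy 75 % of the y extent (`cell_bed_fraction`);
  imaged cavity fields always contain cell-free medium, and that margin
  is what keeps the DAPI histogram bimodal and gives the >50 %-foreground
  inclusion rule both kinds of cube to act on. Mono-cultures place cells
  uniformly ("interspersed"); co-cultures default to "islets" — clusters
  of ~60 cells — because real co-cultures grow in zones and clusters, and
  cube-level population labels are only meaningful when patches reach
  cube scale.
* **Optics and noise.** Anisotropic Gaussian blur, default σ = (1, 1, 2)
  px in (x, y, z) (axial resolution is several times worse than lateral
  at these numerical apertures), then a uniform background (5), Poisson
  photon noise (gain 0.5) and Gaussian read noise (sd 2).
* **Ground truth** is returned per voxel (background / cancer /
  fibroblast, plus a nucleus-only mask and nucleus centres), so
  segmentation recall, cube majority labels and classification accuracy
  are all measurable exactly.

All intensity levels are stand-ins — no quantitative intensity
distributions exist for the real stains — and are configuration, not
constants. What passing tests show is that the *pipeline* recovers
contrasts and orderings it is fed at realistic geometry, noise and
density; they are silent about real biology. Features deliberately not
modelled: spectral bleed-through, photobleaching along z, depth-dependent
attenuation, non-ellipsoidal nuclei, touching-nucleus texture.

## Problem sizes and numerical choices

The shipped validation experiments use cavities of 192 × 192 × 32 voxels
(72 cubes each, five cavities per condition) for the reference-threshold
study and 128 × 128 × 32 for the contrast/ordering panels — large enough
for hundreds of pooled cubes while keeping a full run in minutes on one
CPU. Nucleus density defaults to ~3.9 × 10⁻⁴ nuclei per voxel (roughly a
quarter of the cell bed volume is nuclear), near the practical limit of
non-overlap rejection sampling and consistent with the very dense
cultures the analysis was designed for.

Numerical conventions worth knowing:

* Axis order is Z, Y, X(, C) everywhere internally; user-facing triples
  that mirror imaging conventions (`sigma_px`, `cube_shape`,
  `blur_sigma_px`) are (x, y, z) and documented as such. Coordinates and
  grid indices are 0-based with half-open intervals.
* Gaussian smoothing uses replicate (edge-clamp) boundaries realised as a
  banded-matrix product per axis; kernel radius is ⌈4σ⌉.
* Otsu requires at least two distinct values — constant input is a
  degenerate-histogram error, never a silent all-background mask.
* Integer TIFF round trips are lossless (8/16-bit); non-integer stacks
  are rescaled to 16 bits with the scale factor recorded in a YAML
  sidecar. OME-XML `PhysicalSize` metadata, when present in a file's
  description tag, takes precedence over caller-supplied voxel sizes;
  absent any metadata the package warns and assumes 1 µm isotropic.
* Cavity seeds derive from the master seed as `seed + 7919 i (mod 2³¹−1)`,
  so per-cavity reruns are reproducible in isolation.

## Known limitations

* The cube-level population split inherits the skew of its real
  counterpart: everything brighter than the fibroblast reference lands in
  the cancer compartment, including mixed cubes. The compartment-size
  reporting makes this visible but does not remove it.
* With 10 randomizations the colocalization p-value floor (1/11) is the
  reference setting, not a recommendation.
* `cell_bed_fraction` models cell-free space as a y-margin; real cavity
  geometry (circular cross-sections, curved walls) is not modelled, and
  none of the analysis depends on it.
* The 2-D ROI module formalises threshold-based cell-type calls only;
  its accuracy on real monolayers therefore depends on marker quality
  more than the 3-D path does.
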