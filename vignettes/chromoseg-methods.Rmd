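---
title: "Segmenting nuclei and chromocenters: methods and design notes"
author: "chromoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting nuclei and chromocenters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoseg)
```

# The problem

In interphase nuclei of *Arabidopsis thaliana* (and many other species),
pericentromeric repeats, transposable elements and other repeat-rich
domains coalesce into a handful of densely DAPI-stained foci called
**chromocenters**. Their number, size and brightness report on the state of
heterochromatin, and they change drastically across development (e.g.
dark-grown seedlings), genotype (e.g. *ddm1* mutants with relaxed
heterochromatin) and stress. Quantifying them from confocal z-stacks is a
segmentation problem with two nested objects: the nucleus and the bright
foci inside it. Manual annotation is slow and notoriously user-dependent,
so `chromoseg` provides two automated routes plus the morphometrics and the
agreement statistics needed to evaluate them:

* a **classical pipeline**: threshold-based nucleus detection on a filtered
  z-projection, followed by chromocenter segmentation with a hierarchical
  watershed on a 3D structure-tensor feature;
* a **deep pipeline**: a cascade of three compact U-Nets (region proposal,
  nucleus segmentation, chromocenter segmentation);
* a **synthetic scene generator** producing DAPI-like z-stacks with exact
  ground truth, which is how every stage of this package is tested without
  relying on any external image collection.

# Morphometric parameters

For a nucleus mask $N$ with chromocenter regions $C_1, \dots, C_k$ and an
intensity image $I$ (by convention the maximum z-projection of the raw
stack), the package computes:

* per-chromocenter **relative area fraction** $\mathrm{RAF}_i = |C_i| / |N|$;
* **heterochromatin fraction**
  $\mathrm{HF} = \sum_i |C_i| / |N| = \sum_i \mathrm{RAF}_i$;
* **relative heterochromatin intensity**
  $\mathrm{RHI} = \overline{I}_{C} / \overline{I}_{N}$, the mean
  chromocenter intensity over the mean nucleus intensity;
* **relative heterochromatin fraction**
  $\mathrm{RHF} = \mathrm{HF} \times \mathrm{RHI}$, which algebraically
  equals $\sum_{C} I / \sum_{N} I$ — the proportion of stained DNA residing
  in chromocenters.

Two conventions are fixed here because the definitions leave them open.
The nucleus mean *includes* chromocenter pixels (the plain reading of "mean
intensity of nucleus"); excluding them would inflate RHI by a factor that
grows with HF and would break the $\mathrm{RHF} = \sum_C I / \sum_N I$
identity. A nucleus with no detected chromocenters reports
$\mathrm{HF} = \mathrm{RHI} = \mathrm{RHF} = 0$ with `cc_count = 0`,
never `NA`, so that downstream statistics cannot silently drop nuclei.
Areas are reported in µm² when a pixel size is known and in px² otherwise,
with an explicit `units` column.

# The classical pipeline

## Nucleus detection

`detectNuclei()` works on a 2D projection of the stack (`zProject()`, max
or population-sd). The projection is median-filtered over a disk (radius 2
px by default; the radius is exposed because no single value suits every
pixel size), thresholded by **minimum cross-entropy** (Li & Lee's
criterion: the threshold minimizing
$-m_{1,\mathrm{low}}\log\mu_\mathrm{low} -
m_{1,\mathrm{high}}\log\mu_\mathrm{high}$, found by exhaustive scan over
the observed intensity levels with ties broken toward the lower threshold
for determinism), hole-filled, and cleaned of regions below `minArea`
(default 500 px, which removes debris, plastids and other small bright
contaminants). Touching nuclei are split by placing markers at local maxima
of the Euclidean distance transform (minimum separation
$0.5\sqrt{\texttt{minArea}}$) and growing them within the binary mask.
Components are 4-connected throughout, which avoids diagonal bridges
between adjacent nuclei.

Curation — the removal of false detections and the addition of missed
nuclei — is file-based (`applyCuration()` with a JSON edit list of label
removals and polygon additions) so that the curation step is scriptable
and auditable rather than interactive.

## Chromocenter segmentation

For each nucleus, `segmentChromocenters()` crops the surrounding sub-stack
(10 % margin), computes the **largest eigenvalue of the 3D structure
tensor** (Gaussian-derivative gradients at `sigmaGrad`, outer product
smoothed componentwise at `sigmaInt`; the z-derivative is multiplied by
dx/dz because confocal stacks are strongly anisotropic — 0.05–0.1 µm
pixels against 0.35–0.43 µm slice spacing), projects it along z, and
segments the projection with `hWatershed()` restricted to the nucleus
mask.

`hWatershed()` reproduces the three controls of the interactive
H-watershed plugin in batch form:

* **h** — a maximum survives as a seed iff its *dynamics* (peak height
  minus the highest saddle toward a higher peak) is at least `h`;
* an **intensity floor** — pixels below it are removed from every region;
* **peak flooding** — each region is truncated to pixels above
  $(1 - \mathrm{pf}/100)$ of its own peak value.

The dynamics-thresholded flooding itself is delegated to EBImage's
watershed (`tolerance = h`), with the seed-dynamics behavior verified in
the test suite against a brute-force threshold-connectivity oracle.

Two batch guards replace the curation an interactive session would
provide. The feature is flattened in a 3-px band along the nucleus
boundary before the watershed, because the nucleus edge is the strongest
gradient structure in any crop and otherwise seeds spurious rim regions
(with isotropic treatment it can even dominate the whole feature range).
And regions smaller than `minCcArea` (4 px) are discarded as texture
speckle — faint-phenotype nuclei otherwise accumulate many 1–3-px
false foci.

**Defaults.** The plugin this step emulates is tuned interactively per
image, so batch defaults had to be chosen here: `h` = 5 % of the
per-nucleus feature range, floor = 25 % of that range, peak flooding
30 %, `sigmaGrad` = 1 px, `sigmaInt` = 1.5 px, rim band 3 px, minimum
region 4 px. They were calibrated once on generator scenes (light and
dark presets) for focus-count recovery close to 1 and for measured HF
close to ground truth: a larger `sigmaInt` merges foci closer than about
$2\sigma$ and inflates every mask, while flooding 100 % (the "uncurated"
neutral setting) floods each basin down to the nucleus boundary and
degenerates to HF = 1. With these defaults, generator benchmarks recover
focus counts within a few percent for both phenotypes, overestimate HF by
about 1.6× on the light preset and underestimate it by about 2× on the
dark preset — the faint, low-contrast regime is genuinely hard for any
non-interactive setting, and per-dataset tuning is expected there. All
values are arguments, and both `h` and the floor can be given in absolute
feature units instead (`hRelative`/`intensityRelative = FALSE`).

# The deep pipeline

The cascade mirrors the classical route with three U-Nets: a **region
proposal** network trained on the binary union of dilated nucleus masks
(mask-then-box: thresholded heatmap components become bounding boxes with
a 15 % margin), a **nucleus** network and a **chromocenter** network
operating on per-nucleus fragments resized to the network input. Fragment
probability maps are mapped back through the inverse resize and merged by
pixelwise maximum, a deterministic and order-independent rule; the merged
maps are binarized (default threshold 0.5 for both stages, so a pixel is
kept as soon as object is more likely than background; the presets
0.5/0.25 and 0.8/0.2 are useful when chromocenter probabilities are
systematically conservative) and composed into a tri-level mask
(0 background / 128 nucleus / 255 chromocenter), with chromocenters
masked to nuclei by construction.

The networks are implemented directly in R (shift-decomposed 3×3
convolutions evaluated as BLAS matrix products, ReLU, 2×2 max pooling,
nearest-neighbor upsampling with skip concatenation, sigmoid head; He
initialization; Adam). The default loss is BCE plus soft Dice — the Dice
term keeps gradients informative for small foregrounds such as
chromocenters. Images are min–max normalized per image before entering
the network, which makes the cascade indifferent to 8- vs 16-bit sources.
Everything is seeded: the same `UNetConfig` reproduces identical initial
weights, shuffling order, loss history and parameters on one machine.
Chromocenter training fragments are cut from ground-truth nucleus boxes
by default (`extractFragments()`); cutting them from predicted proposals
is possible by feeding `proposeRegions()` output instead.

Desk-scale configurations (depth 2, 8 base filters, 64×64 tiles, 64
training fragments, 10 epochs, batch 4, learning rate 2e-3) train in
about a minute per stage on one CPU and reach held-out nucleus Dice
above 0.95 on generator scenes; these are also the problem sizes used
throughout the test suite. `augmentPair()` provides the usual seeded
augmentation (flips, 90° and small free rotations, intensity scale/gamma,
additive noise) with nearest-neighbor mask interpolation so masks stay
binary.

# The synthetic scene generator

`generateScene()` renders a field of elliptical nuclei (random semi-axes
and orientation, soft rim falloff, a low-frequency multiplicative
nucleoplasm texture, a Gaussian axial intensity profile) containing
non-overlapping chromocenter disks rendered as 3D Gaussian bumps whose
disk-mean contrast over the nucleoplasm equals the configured ratio.
Scenes optionally contain touching nucleus pairs and small extranuclear
debris blobs (which exercise the min-area filter and curation). Voxel
metadata mirrors a typical confocal acquisition: 0.1 µm pixels, 0.35 µm
slice spacing — this anisotropy matters, because the structure tensor's
z-derivative scaling is what keeps the axial intensity profile from
dominating the feature.

Ground truth (tri-level mask, label images, per-nucleus morphometrics) is
computed on the noiseless, quantized rendering *before* Poisson shot noise
(intensity-proportional) and additive Gaussian read noise (sd 3 counts on
a ~70-count nucleoplasm) are applied, so truth records are exact oracles.
The presets encode the qualitative phenotypes of interest — `light`: 8–10
foci at contrast 2.2; `dark`: 4–8 fainter foci (contrast 1.4) in larger
nuclei; `ddm1`: 4–8 small faint foci in smaller nuclei — with 3 nuclei per
192×192×7 field. These numbers are the generator's fixed study
conditions: chosen once as realistic for DAPI-stained Arabidopsis
material, not tuned per experiment.

What the generator deliberately does **not** emulate: optics (no PSF,
no depth-dependent attenuation), chromatic or stage drift, irregular
nucleus shapes, nucleoli, cytoplasmic background structures, or the
full diversity of real sample preparation. Tests passing on generator
scenes therefore demonstrate the *mechanics* of the pipelines — correct
formulas, stable segmentation behavior, learnability — not performance on
real microscope data, which always requires tuning `h`, thresholds and
training data to the acquisition at hand.

# Numerical choices and degenerate inputs

* Thresholding requires at least two distinct intensity levels; constant
  images raise a "degenerate histogram" error rather than guessing.
* Cross-entropy ties go to the lower threshold; watershed label order is
  made deterministic by relabeling in first-occurrence order.
* A constant image inside the watershed mask yields zero labels; an empty
  nucleus mask is an error.
* The largest eigenvalue of the 3×3 tensor is computed with the analytic
  trigonometric formula, clamped to $[-1, 1]$ before `acos` and to
  non-negative output (the tensor is positive semi-definite); it matches
  LAPACK eigen-decomposition to better than 1e-6 relative.
* Median filtering uses reflected edges and radius 0 as identity; the
  standard-deviation projection is the population (divide-by-N) form so
  expected values are exact in tests.
* Heatmap binarization uses `>= threshold`, making the mask monotone
  non-increasing in the threshold.
* `dice(∅, ∅) = 1`: perfect agreement on absence.
* Object matching is greedy by descending pixel overlap (ties broken by
  label order), each object used at most once. Greedy is deterministic
  and auditable; on small random instances it attains the exhaustive
  max-overlap assignment, which the test suite checks by enumeration.

# Known limitations

* Touching nuclei that the region-proposal network sees as one blob yield
  a single merged box, and the nucleus count is then under-estimated; the
  classical pipeline's distance-transform split handles these cases
  better.
* The hierarchical watershed defaults are calibrated for focus-like
  chromocenters a few pixels across; strongly fragmented heterochromatin
  (severe *ddm1*-like phenotypes) will need a lower `h` and floor.
* 2D morphometrics on projections systematically differ from volumetric
  quantities; this package intentionally stays in 2D (projection space),
  matching the workflow it implements.
* The pure-R U-Net is adequate for desk-scale models; it is not intended
  for training at realistic dataset sizes, where a GPU framework is the
  right tool.
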