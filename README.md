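# chromoseg

Batch segmentation and morphometry of DAPI-stained plant nuclei and their
heterochromatic **chromocenters** from confocal z-stacks.

In interphase nuclei of *Arabidopsis thaliana*, pericentromeric repeats and
other heterochromatic domains coalesce into 8–10 bright DAPI foci. Their
number, area and intensity quantify the state of heterochromatin, which
reorganizes during development (dark-grown seedlings), in mutants (*ddm1*)
and under stress. Segmenting nucleus and foci by hand is slow and
user-dependent; `chromoseg` automates both steps with two complementary
pipelines plus the statistics needed to compare segmentations.

**Classical pipeline** — nuclei are detected on a median-filtered
z-projection by minimum cross-entropy thresholding (Li & Lee), touching
nuclei are split by distance-transform markers, and chromocenters are
segmented per nucleus by a batch **hierarchical H-watershed** (seed
dynamics threshold *h*, intensity floor, peak flooding) on the z-projected
largest eigenvalue of the 3D structure tensor. File-based curation edits
(JSON removal/addition lists) replace interactive clicks.

**Deep pipeline** — a cascade of three compact U-Nets implemented directly
in R: region proposal → per-fragment nucleus segmentation → per-fragment
chromocenter segmentation, merged back to full-image probability maps and
thresholded (0.5/0.5 by default) into a tri-level mask.

**Morphometry** — per nucleus, with mask $N$, chromocenters $C_i$ and
intensity $I$ (max z-projection):

- RAF\_i = |C_i| / |N| (relative chromocenter area fraction)
- HF = Σ|C_i| / |N| (heterochromatin fraction)
- RHI = mean I over chromocenters / mean I over the nucleus
- RHF = HF × RHI = Σ_C I / Σ_N I (fraction of stained DNA in chromocenters)

**Comparison** — Dice coefficients, whole-mask and per-object with greedy
overlap matching, for inter-user / inter-method agreement.

**Synthetic scenes** — a seeded generator of DAPI-like z-stacks
(elliptical nuclei, Gaussian chromocenter foci, touching pairs, debris,
Poisson + Gaussian noise) with exact pre-noise ground truth. Presets
`light`, `dark` and `ddm1` emulate the contrasted phenotypes above; every
claim in the test suite is validated against this generator.

## Worked example

```r
library(chromoseg)

# a synthetic field of 3 light-phenotype nuclei, with ground truth
scene <- generateScene(sceneConfig("light", seed = 7))
proj  <- zProject(scene$stack, "max")

rois <- detectNuclei(proj)           # classical nucleus detection
rois
#> RoiSet: 3 nuclei on a 192 x 192 projection (min area 500 px)
#>   provenance: 3 auto, 0 added

seg  <- segmentChromocenters(scene$stack, rois)
meas <- measureBatch(rois, seg$ccLabels, proj)
meas$records[, c("nucleus_id", "cc_count", "hf", "rhi", "rhf")]
#>   nucleus_id cc_count        hf      rhi       rhf
#> 1          1        8 0.1082251 1.505658 0.1629500
#> 2          2        9 0.1560559 1.491874 0.2328158
#> 3          3        8 0.1718919 1.419339 0.2439728

# agreement with the generator's ground truth
diceCoefficient(labelImage(rois) > 0, scene$truth@nucleusLabels > 0)
#> [1] 0.9279515
```

Each row is one nucleus: 8–9 detected chromocenters (ground truth: 9, 9,
10) covering 11–17 % of the nucleus area (HF) at ~1.5× the mean nuclear
intensity (RHI), so 16–24 % of the DAPI signal sits in chromocenters
(RHF) — the regime expected for light-grown material, whereas the `dark`
preset yields RHF around 2–5 %. The nucleus masks agree with the
generator's ground truth at Dice ≈ 0.93.

A shell front end over the same functions is installed with the package
(`inst/scripts/chromoseg`): `simulate`, `detect`, `curate`,
`chromocenters`, `measure`, `compare`, `train`, `predict`.

## Documentation

The methods vignette (`vignettes/chromoseg-methods.Rmd`) describes the
models, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and known limitations.
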