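---
title: "Quantifying cell metabolism from fluorescence images and flux assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell metabolism from fluorescence images and flux assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxcell)
```

# What the package computes

`redoxcell` implements a single-cell metabolic imaging analysis chain for
label-free autofluorescence and TMRE microscopy, together with the
plate-based and extracellular-flux assays that usually accompany such
experiments, and the group statistics used to summarize them. Everything
can be exercised end to end on synthetic scenes with known ground truth,
so every stage is testable without microscope data.

The two imaging readouts at the core are:

* **Optical redox ratio (ORR).** NAD(P)H and FAD are the dominant
  autofluorescent metabolic cofactors (electron donor and acceptor).
  The ORR is the per-pixel or per-cell ratio
  $\mathrm{ORR} = I_{NAD(P)H} / I_{FAD}$ and reports the cellular
  oxidation–reduction state.
* **Mitochondrial membrane potential.** TMRE is a cationic dye whose
  non-quenching-mode fluorescence scales with accumulation. Because
  accumulation across the inner mitochondrial membrane follows the
  Nernst relation, the mitochondrial-to-nuclear intensity ratio maps to
  a potential:
  $$\Delta\Psi = -RT\,\log_{10}\!\left(\frac{FI_m}{FI_n}\right),\qquad
  RT = 61.5\ \mathrm{mV\ per\ decade\ at\ 37^\circ C}.$$
  The logarithm is base 10: 61.5 mV is the physiological Nernst slope
  *per tenfold* concentration ratio ($2.303\,RT/F$ at 310 K), and only
  the decadic reading yields physiological potentials. The nuclear mean
  is the cytosolic reference because TMRE equilibrates similarly in
  nucleus and cytosol while the nucleus is free of mitochondrial
  contamination.

# Image model and segmentation

Images are nonnegative photon-count grids (`IntensityImage`); object
masks are integer label images (`LabelImage`, 0 = background). For
photon-counting acquisitions, decay stacks are integrated to intensity:
at each pixel the counts are summed over all time bins and over a
sliding $(2r+1)\times(2r+1)$ spatial bin ($r=1$, i.e. 3×3, by default);
windows are truncated at image edges rather than padded. No lifetime
fitting is performed — only integration to intensity.

Segmentation is nucleus-seeded: nuclei are *supplied* as a label mask
(in the reference workflow they are traced manually; here the generator
provides ground-truth nuclei), and cells are grown outward by
multi-source geodesic propagation on the 4-connected pixel graph. A
step between neighbors $p,q$ costs
$\sqrt{\lambda^2 + (I(p)-I(q))^2}$ on the guide image, so fronts move
freely through flat intensity and stall across edges; each foreground
pixel takes the label of the cheapest seed, with cost ties broken
toward the lower label id (a deterministic convention that makes the
operation exactly reproducible and oracle-checkable). The
regularization $\lambda$ defaults to 0.05, a value at which the
intensity term dominates across cell boundaries while distances still
break ties inside flat regions; it is exposed as a parameter. The
cytoplasm is the cell minus its nucleus; border-touching cells are
retained.

Two global thresholding methods gate the propagation and the
mitochondrial mask:

* **Otsu** — maximizes between-class variance; used to keep the
  redox-channel propagation out of background.
* **Minimum cross-entropy (Li)** — minimizes
  $-(A_0\log\mu_0 + A_1\log\mu_1)$ over splits, where $A_k$ and
  $\mu_k$ are the intensity mass and mean of each class; used with a
  **threshold correction factor** that multiplies the computed
  threshold (the reference TMRE workflow uses factor 2, which
  restricts the foreground to bright, cell-dense signal).

Both are implemented as exhaustive scans over the sorted unique pixel
values, and both return the *midpoint between the two values flanking
the best split*. This convention guarantees the threshold lies strictly
between the image minimum and maximum and makes an independent
brute-force oracle trivial; binarization uses `pixels >= t`. Ties in
the criterion go to the lowest candidate split.

**Mitochondrial masking.** The mitochondrial compartment of each cell
is the set of cytoplasm pixels at or above a single global TMRE
threshold. That threshold is computed over *cytoplasmic pixels only*
(default: Otsu). This is a deliberate choice: TMRE fields are
effectively trimodal (background, cytosol/nucleus, mitochondria), and a
threshold computed over the whole image can lock onto the
background-versus-cell boundary, which would dissolve the mitochondrial
compartment into the cytosol. Restricting the candidate pixels to the
cytoplasm makes the single global threshold separate exactly the two
populations it is meant to separate. Cells whose mask comes out empty
are excluded from the potential table and reported, not silently
dropped.

# Per-cell redox conventions

The per-cell ORR is reported in two ways: the **ratio of cytoplasmic
means** (`orr`, the primary definition — robust to isolated zero-FAD
pixels) and the **mean of per-pixel ratios** over defined pixels
(`orr_pixel_mean`, auxiliary). Pixels with zero FAD are undefined and
excluded rather than epsilon-padded, which would otherwise inflate
ratios. Under the ratio-of-means convention, fold-changes factor
exactly: $\mathrm{fold(ORR)} =
\mathrm{fold}(I_{NAD(P)H})/\mathrm{fold}(I_{FAD})$ for uniform
multiplicative shifts, a property the tests assert. Normalization to
control divides by the pooled control-cell mean (cells are pooled per
condition, not per field of view).

# Flux and plate assays

A `FluxTrace` holds 12 measurement cycles (3 per phase) with the
mito-stress injection schedule (oligomycin, FCCP,
rotenone + antimycin A after cycles 3, 6, 9). Phase membership is
determined by injection indices, never by agent concentration. Rates
are normalized per well by crystal-violet A590 (a DNA-content proxy).
**Basal respiration** is the baseline mean OCR minus the
post-rotenone/antimycin mean (the non-mitochondrial floor); the
OCR:ECAR ratio uses baseline means. Conditions are classified into
energetic/aerobic/glycolytic/quiescent quadrants relative to the
control baseline means, with boundary points (ties) assigned to the
less active side, i.e. quiescent at the origin. ATP-linked, maximal
and spare respiration are provided as derived metrics but are not part
of the headline surface.

Plate reductions follow the standard recipes: WST-1 subtracts the
650 nm phenol-red read per well and then the mean blank (no-cell)
signal; CytoID divides by Hoechst per well; cell growth subtracts the
mean pre-treatment baseline count and expresses condition means as
percent of control (values above 100 and below 0 are both meaningful);
senescence is a straight percent positive.

# Statistics

Group comparisons mirror the analysis a plate/imaging study would run:
one-way ANOVA (classical decomposition via `lm`), then **Dunnett's
many-to-one test with a single pooled variance** across all groups
(control included) at a two-sided family-wise $\alpha = 0.01$. The
adjusted p-value is the null probability that the *maximal* absolute
comparison statistic exceeds the observed one, which accounts for the
correlation induced by the shared control. It is evaluated on a seeded
Monte-Carlo sample of the max-$|t|$ null ($10^5$ draws by default;
group means as independent normals, pooled variance as
$\chi^2_{df}/df$). Two numerical details: the adjusted p is clamped
from below by the unadjusted pooled t-test p (an exact bound that Monte
Carlo noise must not violate), and the null sample can be precomputed
once per design (`dunnettNullSample()`) and reused, which makes
repeated testing and the calibration simulations fast and mutually
consistent. With a single treatment group the procedure reduces to the
pooled two-sided t-test. Summary heatmaps use
$z = (\mu_{treatment} - \mu_{control})/\sigma_{control}$ per variable.

# The synthetic-data generator

`generateCellScene()` renders what the analysis consumes: elliptical
cells (random semi-axes and orientation) placed without overlap by
rejection sampling, concentric circular nuclei, and plus-shaped
mitochondrial puncta scattered through the cytoplasm. Expected
intensities are piecewise constant per compartment; per-pixel Poisson
noise models photon counting. Defaults are chosen to be realistic for
photon-count autofluorescence imaging and are fixed once: background 2
counts, cytoplasmic NAD(P)H 60 and FAD 50 counts (nucleus at 0.6 of
cytoplasm), nuclear/cytosolic TMRE 30 counts, puncta covering half the
cytoplasm (a dense mitochondrial network), 10% lognormal cell-to-cell
brightness variation, 25 cells per 256×256 field. Condition effects
are multiplicative folds on the channel baselines; the TMRE
mitochondrial mean is $n_0 \cdot 10^{-\Delta\Psi/RT}$, the inverse of
the Nernst relation, so the configured potential is the scene's ground
truth. The per-cell brightness factor scales nuclear and mitochondrial
TMRE together and cancels in the Nernst ratio.

What the generator does *not* emulate: optics (no point-spread
function, no channel bleed-through), realistic cell and mitochondrial
morphology, spatial intensity texture within compartments, field
illumination gradients, or segmentation-relevant pathologies such as
touching cells. Passing recovery tests therefore demonstrates that the
measurement chain is unbiased and correctly plumbed under the stated
image-formation model — not that segmentation would be accurate on
real micrographs.

Flux traces are generated with configured phase means plus Gaussian
cycle noise (default 2% of baseline); with zero noise basal
respiration is recovered exactly. Plate generators produce replicate
wells around configured condition values, including blank and baseline
wells, and recover configured percents exactly at zero noise.

```{r example}
sc <- generateCellScene(simConfig(seed = 1, imageSize = 128, nCells = 6))
res <- potentialPipeline(channels(sc)$tmre, nuclei(segmentation(sc)))
res$cells[, c("cell_id", "fi_n", "fi_m", "delta_psi_mV")]
```

# Problem sizes and verification

The test suite verifies, among others: threshold and propagation
results against independent brute-force oracles (20 random histograms;
10 random 16×16 Dijkstra scenes); recovery of configured NAD(P)H/FAD
folds of 1.70/1.99 within ±5% from two conditions of 200 cells each
(8 scenes of 25 cells per condition); recovery of membrane-potential
targets of −30, −61.5 and −120 mV within 3 mV (median over 125 cells
per target); exact noiseless and unbiased noisy basal-respiration
recovery; and the family-wise error of the Dunnett procedure at
$\alpha = 0.01$ within $[0.005, 0.02]$ over 2500 null experiments of 4
groups × 30 observations. These sizes are the package's chosen
verification conditions; they run in a few seconds on one CPU.

# Known limitations

* Nuclei must be supplied; there is no automatic nucleus detector.
* The per-cell ORR definition (ratio of means vs. mean of ratios) is a
  convention; both are reported, and they differ on heterogeneous
  cells.
* TIFF output is 8/16-bit integer (exact for photon counts and label
  ids); floating-point maps such as the ORR image are kept in memory
  and exported through CSV tables.
* Cells are pooled across fields and replicates as independent
  observations in the statistics; no hierarchical nesting is modeled.
* Quench-mode TMRE, FCCP calibration and plasma-membrane potential
  corrections are out of scope.
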