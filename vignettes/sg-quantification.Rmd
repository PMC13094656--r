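---
title: "Methods: compartment-resolved stress-granule quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-resolved stress-granule quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SGprofiler)
```

## The problem and the model

Colonic mucosa in cross-section shows two compartments with different
biology: intestinal epithelial cells arranged around crypt lumina, and
immune-relevant cells scattered through the lamina propria. A stress-granule
marker such as G3BP1 must be quantified separately in each, and within
epithelial cells separately for nucleus and cytoplasm, because spot counts,
spot sizes and radial localization carry different information.

SGprofiler treats this as a staged object-segmentation problem over three
channels (nuclear stain, epithelial membrane marker, target protein), all
normalized to $[0,1]$:

1. **Primary objects (nuclei).** Gaussian smoothing (`smoothingSigma`),
   Otsu or manual threshold, hole filling, then declumping: local maxima of
   the Euclidean distance transform (maxima closer than
   `nucleusDiameterMin` merge into one seed) initialize seeded region
   growing over the foreground. Objects outside the equivalent-diameter
   band $[d_{\min}, d_{\max}]$ are discarded.
2. **Epithelial region.** The membrane channel is smoothed, Otsu-thresholded,
   morphologically closed, hole-filled, and cleaned of fragments smaller
   than $d_{\min}^2$ pixels. A crypt annulus therefore becomes a filled
   disc: the region includes the lumen it encloses.
3. **Compartment assignment of nuclei.** Majority rule on the overlap
   fraction with the region: the epithelial pipeline keeps nuclei with
   fraction $\ge 0.5$, the lamina pipeline keeps the complement. Objects
   are kept or dropped whole — never clipped — so downstream pixel-set
   identities stay exact.
4. **Cells.** ECP grows cells from nuclear seeds over the
   membrane-intensity landscape (the propagation algorithm popularized by
   CellProfiler's secondary-object module; membrane ridges act as barriers,
   regularization $\lambda = 0.05$). PCP instead expands every nucleus by an
   exact Euclidean distance (`expansionDistance`, default 5 px), resolving
   contested pixels to the nearest seed with ties to the lower label, and
   never claiming epithelial pixels.
5. **Cytoplasm.** For each label $L$: cytoplasm$(L)$ = cell$(L)$ minus
   nucleus$(L)$, as a literal pixel-set difference. Empty cytoplasm is
   allowed and flagged.
6. **Spots.** Threshold, 8-connected components, area band
   $[\texttt{spotAreaMin}, \texttt{spotAreaMax}]$, no declumping. Each spot
   is attributed twice by maximum pixel overlap: to a subcellular
   compartment (nucleus vs cytoplasm, ties to the nucleus — so a spot
   straddling the nuclear edge counts as nuclear) and to a whole cell
   (ties to the lower label). A cell is positive iff it carries at least
   `minSpotsPositive` (default 2) spots, and the headline readout is
   $100 \times \text{positives} / \text{total}$.
7. **Filters (PCP).** Oversize (area $> 3\times$ the single-pass mean cell
   area of the image, candidate included), epithelial overlap
   ($> 0.5$ fraction inside the region), border contact. Evaluated in that
   fixed order; the first matching reason is recorded, so the audit sums
   reconcile exactly with the total.

### Measurements

For an object with area $A$ (pixels) and chain-code perimeter $P$:
form factor $= 4\pi A/P^2$; radius $=$ mean of the Euclidean distance
transform over the object (mean distance to the nearest outside pixel);
compactness $= 2\pi \cdot \overline{r^2}/A$ with $\overline{r^2}$ the mean
squared pixel distance from the centroid. The compactness normalization is
chosen so a perfect disc scores exactly 1 in the continuous limit
($\overline{r^2} = R^2/2$, $A = \pi R^2$); elongation or boundary
irregularity raises it. Integrated intensity is the plain sum over object
pixels, and mean $\times$ area $=$ integrated holds to float accumulation.

Radial distribution: every cytoplasm pixel gets a normalized depth
$d = d_{nuc}/(d_{nuc}+d_{edge})$, with $d_{nuc}$ the distance to the cell's
nucleus pixel set and $d_{edge}$ the distance to the nearest non-cell pixel;
$d$ is binned into `nRadialBins` (default 3) equal intervals. `FracAtD_b` is
bin $b$'s share of total cytoplasmic marker intensity; `BinAreaFrac_b` is
its share of cytoplasm pixels, reported alongside because outer rings are
geometrically larger and raw fractions conflate localization with area.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `nucleusDiameterMin/Max` | 8 / 40 | px | equivalent-diameter band for plausible nuclei at typical 63x tissue scans; the minimum also sets the declumping seed separation |
| `smoothingSigma` | 1 | px | suppresses shot noise without moving half-max edges |
| `spotAreaMin/Max` | 2 / 200 | px | discards single-pixel specks and stain blotches |
| `expansionDistance` | 5 | px | lamina cytoplasm rim; the underlying workflow specifies "a number of pixels" without fixing it, so it is config-exposed |
| `nRadialBins` | 3 | — | perinuclear / intermediate / peripheral |
| `minSpotsPositive` | 2 | spots | the positivity rule ("at least 2 granules") |
| `areaFilterFactor` | 3 | — | oversize removal at 3x the mean area |
| `epcamOverlapMax` | 0.5 | fraction | majority rule for "overlaps the epithelium" |
| `thresholdMethod` | otsu | — | per-image Otsu; `manual` + `manualThreshold` for fixed-threshold studies |

## Numerical choices

- **Otsu.** 256 fixed-width bins over $[0,1]$; the threshold is the upper
  edge of the cut bin maximizing between-class variance; ties resolve to the
  lowest cut; foreground is strictly above the threshold. Constant images
  raise a named degenerate-input error (pipelines translate a constant
  *marker* channel into "zero spots", since no signal is a legitimate
  observation for the target protein, while constant nuclear or membrane
  channels remain errors).
- **Connectivity.** 8-connectivity for object labeling and spot components;
  4-connectivity underlies the border test. Labels are renumbered in
  raster-scan order of each object's first pixel, so identical inputs give
  identical label maps.
- **Perimeter.** The verbal definition accompanying the original
  perimeter readout ("total number of pixels in distinct areas") is not
  implementable as stated; we use the standard weighted chain code on the
  outer 8-connected boundary (orthogonal steps 1, diagonal $\sqrt2$),
  anchored by the form-factor convergence of rasterized discs (the suite
  asserts $4\pi A/P^2 \in [0.88, 1.05]$ for radii 10–200). Sub-resolution
  objects (a few pixels) have intrinsically coarse shape metrics; a single
  pixel is assigned its unit-square crack perimeter of 4.
- **Radial depth metric.** The two-sided normalization
  $d_{nuc}/(d_{nuc}+d_{edge})$ is one of several possible ring definitions;
  it is exact at both boundaries (0 at the nucleus, $\to 1$ at the cell
  edge) and reduces to concentric rings for concentric disc geometry, which
  is what the annulus oracle in the tests checks.
- **Agreement.** Differences are automated $-$ manual, so a negative bias
  reads as underestimation by the pipeline. The limits-of-agreement
  multiplier defaults to 1.96 (95 %); reported 96 % intervals are reachable
  via `multiplier = qnorm(0.98)`. Stratified agreement bins pairs by the
  pair mean with half-open intervals $[lo, hi)$.
- **Focus score.** Defined as normalized variance
  $\mathrm{var}/\mathrm{mean}^2$ of the whole channel (population
  variance). The name is inherited from image-QC practice; no formula is
  fixed by the source workflow, so the convention is documented here and
  verified only for the property that matters: it never increases under
  Gaussian blur.
- **Normalization.** Acquisition bit depth is not standardized in exported
  TIFFs; integer data are divided by the dtype full scale (255 / 65535) and
  float data are clipped to $[0,1]$. This is a convention, not a claim about
  any particular microscope.

## Design decisions on genuinely open points

- **Secondary-object method (ECP).** The source workflow names only the
  module, not its variant (distance / propagation / watershed). We use
  propagation (EBImage `propagate`), which is the published algorithm behind
  that module and coincides with nearest-seed growth on flat membranes —
  the property the tests pin down (corridor boundary within 1 px of
  equidistance).
- **Nucleus containment vs region containment.** A kept nucleus can poke
  slightly outside the epithelial region while its overlap fraction is
  $\ge 0.5$. We guarantee nucleus $\subseteq$ cell (cells may thus own a few
  out-of-region pixels) because the cytoplasm identity and every
  parent–child measurement depend on it.
- **One-sided area filter.** "Deviates from the mean by a factor of 3" is
  read one-sidedly (only oversized cells are removed), following the
  accompanying description of removed cells as "too large"; small cells are
  biologically legitimate. The mean is computed in a single pass with the
  candidate included — simplest and deterministic.
- **Positivity timing.** The percentage of positive cells is computed over
  all cells *before* the exclusion filters, keeping the headline readout
  aligned with the spot-attribution stage; the per-cell `kept` flag and the
  audit allow post-filter recomputation.

## The synthetic scene generator

`generateScene()` renders what the pipelines assume: crypts as annular
epithelial bands (membrane marker positive) carrying a ring of epithelial
nuclei; lamina nuclei scattered outside with a minimum separation
(2.8 $\times$ mean radius) and starting 2 px from the band — lamina propria
cells genuinely abut the basement membrane, and this adjacency is what makes
segmentation accuracy depend on membrane staining quality; nuclei as discs
with a low-order radial Fourier perturbation (controllable form-factor and
compactness shifts); per-cell Poisson spot counts by compartment, rendered
as discs with a minimum center separation so zero-noise counts are
unambiguous; additive Gaussian noise and blur. Ground truth (label maps,
per-cell spot counts, nucleus morphometry, compartment class) is recorded
before degradation. All randomness flows from one locally seeded generator;
the global RNG state is untouched and equal seeds give bit-identical scenes.

Remission-like scenes multiply spot rate (1.6), spot radius (1.25), marker
intensity scale (1.5), nucleus radius (1.15) and outline irregularity (2.0)
— fixed, documented effect directions used to check that group differences
propagate through the pipelines, not estimates of any clinical effect size.

`degradeQuality()` models poor membrane staining as contrast compression
about the channel mean plus Gaussian blur, membrane channel only. Because a
blurred *step* keeps its half-max edge, mild blur barely moves an Otsu mask;
the low-quality condition used in the suite is blur $\sigma = 18$ px with
contrast 0.3 — strong enough that the smeared band swallows the nearest
lamina nuclei, which is the mechanism by which staining quality degrades
automated counts.

**What the generator does not emulate** — and hence what passing tests do
not show about real tissue: anisotropic point-spread functions, uneven
illumination and vignetting, autofluorescence textures, touching or
overlapping nuclei in dense infiltrates, partial-volume effects of 4 µm
sections, marker bleed-through between channels, and cell-type heterogeneity
inside the lamina propria. Accuracy numbers from clean synthetic scenes are
upper bounds, not expected clinical performance.

## Problem sizes and runtime

The test suite and examples use 256 x 256 px scenes with one crypt,
14 epithelial and roughly 30 lamina nuclei and a few hundred spots —
large enough to exercise every stage (declumping, masking, expansion,
attribution, filtering) while keeping a full suite run under a minute.
Batch-level properties (Poisson rate recovery, degraded-vs-clean deviation,
count agreement) use 3–7 seeded scenes each.

## Known limitations

- Spot attribution by maximum overlap misassigns spots whose majority
  pixels fall just across a compartment or cell boundary; the per-cell
  counts remain conserved but individual assignments near edges are
  arbitrary at the 1-px scale.
- The PCP cell model (fixed-distance expansion) is a geometric surrogate,
  not a membrane segmentation; derived "cytoplasmic" intensities in the
  lamina are ring averages.
- No declumping of spots: merged granules count once; dense-granule regimes
  are better compared via integrated intensity.
- 2-D only, by design (thin sections); no mosaic stitching; no proprietary
  container formats (export to TIFF first, without burned-in scale bars,
  which corrupt thresholding).
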