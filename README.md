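# SGprofiler

Automated quantification of stress-granule marker spots in multichannel
immunofluorescence images of colonic mucosa.

Stress granules (SGs) are membrane-free cytoplasmic condensates of RNA and
protein that assemble under cellular stress; the nucleating protein G3BP1 is
a practical marker of residual molecular inflammation in gut tissue. Counting
and localizing G3BP1 spots in tissue sections is tedious and subjective by
hand, and the colonic mucosa makes it harder still: intestinal epithelial
cells (IECs) line ring-shaped crypts, while immune cells sit in the
surrounding lamina propria, and the two compartments must be quantified
separately. SGprofiler provides two complementary, fully automated workflows
for this problem, aimed at quantitative-imaging and mucosal-immunology labs.

## The two pipelines

Input is a three-channel field of view: a nuclear stain (DAPI), an epithelial
membrane marker (EpCAM), and the target protein (G3BP1).

**ECP (epithelial pipeline)** — `runECP()`:
nuclei are segmented from the nuclear channel (Gaussian smoothing, Otsu
threshold, hole filling, distance-transform declumping); the epithelial
region is masked from the membrane channel; nuclei outside the crypt are
discarded (majority rule); cell objects are grown from each nucleus over the
membrane-intensity landscape; cytoplasm is the per-label set difference
cell \ nucleus; marker spots are detected (threshold + 8-connected
components + area band) and attributed to parents by maximum overlap.

**PCP (lamina propria pipeline)** — `runPCP()`:
the same nuclei and epithelial mask, but nuclei *inside* the region are
discarded; cells are grown by exact Euclidean expansion (default 5 px,
nearest-seed ties to the lower label, never into the epithelium); a cell is
G3BP1-positive iff it carries at least 2 spots, and

```
% positive = 100 × (G3BP1-positive cells) / (total cells)
```

Cells are then filtered with a full audit trail, in fixed order: oversize
(area > 3 × mean area), epithelial overlap (> 50 % inside the mask), and
border-touching.

Per-object measurements follow the CellProfiler conventions:

- area A (pixels), perimeter P (chain code, diagonal steps √2),
  form factor 4πA/P² (1 for a circle),
- radius = mean distance-transform value over the object,
- compactness = 2π · msd / A (msd = mean squared distance from the
  centroid) — exactly 1 for a perfect disc, larger for irregular nuclei,
- FracAtD: the cytoplasm is split into 3 radial bins by normalized depth
  d_nuc/(d_nuc + d_edge) (bin 1 perinuclear, bin 3 peripheral) and each bin's
  fraction of total cytoplasmic marker intensity is reported next to its
  area fraction.

QC and validation: `qualityMetrics()` (focus score = var/mean², intensity
statistics, histogram), `segmentationDeviation()` (|auto − manual| counts),
`pairedRegression()` and `blandAltman()` (bias and limits of agreement,
differences defined automated − manual), and `bruteForceSpotCount()` as an
independent second counter. A seeded synthetic scene generator
(`generateScene()`) renders crypt + lamina scenes with full ground truth so
the whole chain is testable without any image downloads.

## Worked example

```r
library(SGprofiler)

sc  <- generateScene(sceneSpec(seed = 42))
pcp <- runPCP(sc$image)
pcp$manifest
```

```
RunManifest: pipeline 'pcp' on image 'synthetic_control_seed42' (v0.1.0, seed 1)
  nuclei_initial               45
  epithelial_mask_area         13669
  nuclei_masked                31
  cells                        31
  spots_detected               166
  spots_assigned               166
  cells_kept                   28
```

The scene rendered 45 nuclei (14 epithelial, 31 lamina propria). The
epithelial mask removes the 14 crypt nuclei; 31 lamina cells are expanded,
166 marker spots are detected inside them and all are attributed; the filter
chain removes 3 cells (border/overlap/oversize) with reasons recorded in
`pcp$filterAudit`.

```r
head(pcp$objects[, c("cell_id", "n_spots_total", "positive",
                     "nucleus_area", "nucleus_form_factor",
                     "nucleus_compactness")], 3)
#  cell_id n_spots_total positive nucleus_area nucleus_form_factor nucleus_compactness
#        1             6     TRUE           83                1.05                1.01
#        2             5     TRUE          104                1.03                1.00
#        3             3     TRUE           92                1.06                1.00
```

Method agreement against ground truth over five zero-noise scenes (cell and
spot counts):

```r
pairedRegression(manual, auto)
# Paired regression (n = 10): slope 1.004, intercept -0.1196, r 1, R^2 0.9999
blandAltman(auto, manual)
# Bland-Altman agreement over 10 pairs
#   bias 0.3, SD 0.6749, LoA [-1.023, 1.623] (x1.96)
```

A thin CLI wrapper lives in `inst/scripts/sgprofiler.R` with subcommands
`simulate`, `ecp`, `pcp`, `qc` and `validate`.

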