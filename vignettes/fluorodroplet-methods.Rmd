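---
title: "Methods: droplet and fluorescent-contour quantification in fluorodroplet"
author: "fluorodroplet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet and fluorescent-contour quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Static droplet-trapping microfluidic arrays hold aqueous-in-oil droplets at
fixed hexagonal sites (here 35 um trap radius, 360 um pitch) so that single
encapsulated cells can be imaged repeatedly under brightfield and
fluorescence. A typical experiment produces folders of 30-40 overlaid
frames, each containing tens of droplets and a mixture of live (green),
dead (red), "dying" (both channels), and nanoparticle-tracked cells, plus
free-floating cells and sub-cellular debris. `fluorodroplet` automates the
four quantities such experiments need: droplet detection, per-class cell /
nanoparticle (NP) contour detection, droplet-occupancy and co-encapsulation
tables, and per-cell intracellular intensity statistics.

All processing happens on 16-bit intensities. 8-bit input is lifted by a
factor of 257 so both extremes map exactly (0 -> 0, 255 -> 65535); the same
lift converts 8-bit colour boundaries into the processing domain. Channel
order is (B, G, R) throughout, matching the boundary notation used in the
droplet-microfluidics literature; RGB-native file formats are reordered at
load time.

# Droplet detection

Droplets are near-perfect circles of known radius range (25-50 um;
calibration defaults to 1 um/px, consistent with a trap pitch of 360 um
published interchangeably as 350-370 px). The detector is a Circular Hough
Transform (CHT):

1. **Median smoothing** (default 3 px window, edge-replicated) suppresses
   read noise without blurring the thin droplet rims.
2. **Edge extraction**: Sobel gradients, non-maximum suppression, and
   hysteresis. The automatic high threshold is a pure noise floor: 8x the
   median gradient magnitude of the frame, which sits near 10 sigma of the
   read-noise gradient, with an absolute floor of 256 grey units
   (sub-0.4% contrast) for noise-free frames whose median is 0; the low
   threshold is half the high one. A data-adaptive split such as Otsu's is
   deliberately avoided here: edge strength in these overlays spans an
   order of magnitude (droplet rims are ~5-10x weaker than fluorescent
   cell edges), so any threshold adapted to the structure present tracks
   the bright population and erases the faint rims. Suppressing only noise
   is sufficient because spurious strong structure is harmless to the
   accumulator — cell-sized edges do not lie on circles in the droplet
   radius range.
3. **Voting**: every edge pixel casts votes at distance R along both
   gradient directions, for each candidate radius (default 1 px step over
   the configured range). Per radius, the (a, b) accumulator is pooled over
   a 5x5 neighbourhood before thresholding: Sobel direction quantization
   displaces votes by a few pixels at radii of 25-50 px, and pooling
   reabsorbs them. A centre candidate must collect at least
   `voteThresholdFrac * 2 * pi * R` pooled votes (default fraction 0.4,
   validated by the exact-recovery property on synthetic lattices).
4. **Peak extraction**: greedy non-maximum suppression ordered by votes
   (ties towards the smaller (row, col)), with a minimum centre distance of
   `2 * rMin` by default. Detections still closer than `2 * rMax` are
   treated as duplicate detections of one trap and only the strongest is
   kept; optional lattice validation reports (but never removes) detections
   whose nearest-neighbour distance is off the 360 +/- 10 um pitch.

Centres are integer pixels; no sub-pixel refinement is attempted. The
droplet count is by construction the length of the droplet table.

# Contour detection

Each fluorescence class is defined by an 8-bit (B, G, R) interval. The
defaults are the published boundaries for live ([0,51,0]-[153,255,153]),
dead ([0,0,51]-[153,153,255]), overlap ([0,51,51]-[153,255,255]),
Eu3+-doped NPs ([51,0,51]-[255,102,255]) and Tb3+-doped NPs
([51,0,0]-[255,51,51]). Per class the pass is:

colour mask -> masked luminance grayscale (Rec. 601 weights
`0.114 B + 0.587 G + 0.299 R`, then 3 px median) -> Canny edges (automatic
thresholds as above) -> dilation then erosion with a 3x3 box (a closing
that bridges broken edge fragments and removes speckle) -> interior fill
of closed contours -> random-walker segmentation -> contour extraction.

Design choices a reader should know about:

* **Grayscale formula.** The luminance weights are the Rec. 601 standard;
  any fixed positive weighting would serve, since each class mask isolates
  one colour family before conversion.
* **Interior fill.** The morphological stages operate on edge maps; a fill
  step is required before segmentation so that objects are solid regions.
* **Random-walker markers.** Markers are local maxima of the Euclidean
  distance transform with a minimum separation of `sqrt(minAreaCell / pi)`
  px (the radius of the smallest countable cell). Plateaus contribute one
  representative (nearest the plateau centroid; ties to the smaller
  (row, col)). Components with a single marker keep one label, so isolated
  cells are never fragmented; components with several markers are split by
  solving the combinatorial Dirichlet problem on the 4-connected pixel
  graph with edge weights `exp(-beta * dg^2)` (`beta` = 130 on grey values
  scaled to [0, 1]) plus a small uniform term, each pixel taking the label
  of the marker a random walker is most likely to reach first. The sparse
  linear systems are solved per connected component on a padded crop, so
  cost scales with object area, not frame area.
* **Pixel sets are mask-defined.** After segmentation, each label is
  intersected with the class's colour mask, and mask pixels left uncovered
  adopt the nearest label within 3 px (an iterative 8-neighbour
  completion). Class membership is what the boundary test says — the
  edge-based stages only close and separate objects, and their
  localization sits a pixel or two inside the mask because each median
  pass erodes a thin boundary layer. Without the completion step a cell at
  the minimal countable area can lose its outermost pixels and fall below
  the area threshold. The measured area is therefore the count of
  classified pixels, which is also what the thresholds are calibrated
  against.
* **Convexity adjustment.** Each boundary is traced and compared with its
  convex hull; when the deepest convexity defect exceeds 3 px the boundary
  polygon is replaced by the hull (pixel set and area unchanged).
* **Area thresholds.** Contours below 130 px^2 (cell classes) or 150 px^2
  (NP classes) are logged as debris and removed; the thresholds are
  inclusive (>=) and sit just below the mean object areas of ~140 and ~170
  px^2 reported for these assays.
* **Class-conflict resolution.** The per-class passes run independently, so
  one physical object can satisfy two boundaries (a bright "dying" cell is
  inside both the live and the overlap interval). Contours from different
  classes whose centroids fall within 5 px are treated as one object,
  resolved by the precedence overlap > dead > live > eu_np > tb_np, so
  dual-signal cells are counted once, as overlap. This precedence is this
  package's choice; whether per-class passes could double-count in the
  original assays is not documented anywhere we know of.

# Encapsulation and tracking

Droplet and contour centre maps are joined by a distance test: a contour
belongs to a droplet when its centroid lies within the droplet's detected
radius (every detected radius is inside the configured 25-50 um scan
range; using the detected radius is tighter than scanning a fixed maximal
radius and consistent with the detected geometry). A contour inside two
detections goes to the nearest centre, ties to the lower droplet id (ids
are assigned in centre-lexicographic order, so the tie-break is
deterministic and order-independent). Contours inside no droplet are
flagged free-floating and excluded from all population counts.

Occupancy counts only cell classes (live, dead, overlap): 0 = empty, 1 =
single-cell (SCE), >= 2 = multi-cell (MCE). NP contours never count toward
occupancy; a droplet holding at least one cell and at least one NP cluster
is `tracked`. The population summary satisfies
`nEmpty + nSce + nMce = nDroplets` and `assigned + free = total contours`
exactly, and these identities are asserted in the test suite on every
benchmarked image.

# Intensity quantification

Per-contour statistics (mean, min, max, variance over the pixel set) are
computed on a single 16-bit fluorescence channel chosen by class (live and
overlap -> G, dead -> R, NP classes -> B; configurable), because uptake
readouts are single-channel. The variance is the population variance
(divide by n); the sample convention is available as an option since
published single-cell figures rarely state which was used. The background
is the median grey value inside detected droplets but outside all contour
pixel sets — the carrier fluid around the cells — with a whole-image
non-contour fallback when no droplet was found. Normalization is a ratio
(mean / background) by default, which makes it invariant to global
illumination scaling; subtraction is available as an option. Histograms
use 256 uniform bins over [0, 65535] (the 8-bit binning of the 16-bit
range) and carry the 16-bit statistics as annotation.

# The synthetic-scene generator

Real microscopy from these devices is not redistributable, so validation
runs on generated scenes with exact ground truth. A scene is a hexagonal
trap lattice (360 um pitch, margins of 100 px) with one droplet per trap
(radius uniform in 25-50 px, centre jitter +/- 3 px), rendered as a
brightfield-like annulus: background 4000, droplet interior 2500, rim
9500 grey units. These greys are deliberately below 51 * 257 so no
achromatic structure can leak into any colour mask even with noise.

Cells are hard-edged ellipses (aspect 0.75-1.3, random orientation) with
pixel counts drawn from N(140, 6) truncated at 131 px^2 — the assays this
emulates chose the 130 px^2 threshold *because* essentially all real cells
exceeded it, so the generator renders countable cells only, and smaller
objects enter as explicit debris (20-110 px^2) instead. NP clusters use
N(170, 8) truncated at 151 px^2. Cell colours place the class's readout
channel at an intensity mu (uniform in 16000-60000; NP classes 42000-60000,
keeping magenta clusters outside the dead-cell boundary) and the remaining
channels at fixed small fractions of mu chosen to sit inside the class's
own boundary and outside all others — except that bright overlap cells
intentionally also satisfy the live and dead intervals, exercising the
conflict-resolution path. Occupancy is multinomial over 0-3 cells per
droplet (default probabilities 0.62/0.27/0.09/0.02, i.e. ~0.5 cells per
droplet as in the emulated assays); placements are non-overlapping with
>= 4 px clearance and stay inside the droplet interior. Free-floating
cells (Poisson, mean 1 per image) are placed clear of every droplet, and
debris may sit inside droplets or in the open channel but never across a
rim. I.i.d. Gaussian noise (default sigma 400; the intensity benchmark
uses 1140 ~ 3% of the mid-range signal) is added to every channel and
clipped to [0, 65535]. A scene is a pure function of (spec, seed, image
index).

What the generator does *not* emulate: optical point-spread blur,
photobleaching, uneven illumination, chromatic cross-talk beyond the
overlap class, droplet shrinkage, and out-of-focus debris. Passing the
synthetic benchmarks therefore demonstrates the correctness of the
geometry, classification, bookkeeping and statistics of the pipeline — not
robustness to every optical artefact of a real microscope; the automatic
thresholds would need checking against real frames before quantitative
use on a new instrument. JPEG input is decoded but its compression
artefacts can smear pixels across colour boundaries near object edges;
lossless TIFF/PNG are the formats these assays actually use.

# Benchmarks and problem sizes

The validation suite runs three assay-scale benchmarks chosen to match the
populations of the emulated experiments: a triplicate of viability sets
(28 images of 2048 x 1500 px, 28 traps each — ~780 droplets and >= 275
encapsulated cells per set) scored by percent count agreement
`100 * (1 - |auto - truth| / truth)` per category; duplicate
nanoparticle-tracking runs of the same lattice size scored on the droplet
subpopulation table; and a 12-image uptake set yielding >= 142 matched
single cells scored by per-cell relative agreement of mean intensity.
Smaller configurations of the same generator (2-droplet frames, 64 x 64
oracle frames) drive the unit and property tests, including exact
equivalence of the CHT against an exhaustive accumulator and of the median
filter and morphology against brute-force definitions.

# Numerical conventions and degenerate inputs

* Coordinates are 1-based (x = column, y = row) in all R-facing tables.
* Vote positions round half away from zero (C `lround`).
* A blank frame yields zero droplets and zero contours; empty results
  propagate as empty tables, never errors.
* An even median/morphology kernel, mismatched mask shape, empty contour
  pixel set, or zero background under ratio normalization are errors.
* Ties (equal votes, equidistant droplets, equal random-walker
  probabilities) break towards the smaller index or (row, col), making
  every stage deterministic; re-running a batch yields byte-identical
  tables.

# Known limitations

* The CHT assumes circular droplets; squeezed or elliptical droplets need
  an ellipse parameterization that is out of scope here.
* Centres are integer pixels; radius resolution equals the radius step.
* Colour-boundary classification cannot separate co-cultured cell types
  with overlapping emission; that requires additional stains or channels.
* The automatic Canny threshold assumes edges are sparse relative to the
  frame; a frame dominated by texture at edge-like gradients would need
  explicit thresholds.
* Cross-frame identity tracking (time lapse) is not implemented; image
  analyses are independent per frame by design.
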