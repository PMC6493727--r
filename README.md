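# fluorodroplet

Automated quantification of fluorescence microscopy from droplet
microfluidic trapping arrays.

Static trapping arrays hold aqueous-in-oil droplets at fixed hexagonal
sites so single encapsulated cells can be imaged under overlaid
brightfield + fluorescence. Analysing such experiments by hand means
counting hundreds of cells per condition and tracing each cell's boundary
for intensity readouts — hours of manual work per experiment, with
person-to-person variability. `fluorodroplet` automates the whole chain
for folders of 16-bit (or 8-bit, lifted by 257) overlay images:

* **Droplet detection** by Circular Hough Transform: edge pixels vote at
  distance *R* along their gradient direction into an (a, b) accumulator
  per candidate radius (25–50 µm by default); pooled accumulator peaks with
  at least `0.4 · 2πR` votes become droplet centres, followed by
  non-maximum suppression and trap-level deduplication on the 360 µm
  hexagonal lattice.
* **Contour detection** per fluorescence class, each class defined by 8-bit
  (B, G, R) boundaries (live `[0,51,0]–[153,255,153]`, dead
  `[0,0,51]–[153,153,255]`, overlap/"dying" `[0,51,51]–[153,255,255]`,
  Eu³⁺-doped NPs `[51,0,51]–[255,102,255]`, Tb³⁺-doped NPs
  `[51,0,0]–[255,51,51]`): colour mask → masked luminance grayscale →
  Canny edges → morphological closing → interior fill → seeded
  random-walker segmentation of touching cells → convex-hull adjustment →
  area thresholding (≥ 130 px² for cells, ≥ 150 px² for NP clusters).
* **Encapsulation / tracking**: droplet and contour centre maps are joined
  (contour centroid within the detected droplet radius); droplets are
  classified empty / single-cell / multi-cell, free-floating cells are
  excluded, and cell + nanoparticle co-encapsulation yields droplet
  tracking tables.
* **Intracellular intensity**: per-cell mean / min / max / population
  variance on the class's 16-bit fluorescence channel, background
  normalization against the droplet carrier fluid, and 8-bit-binned
  histograms of the 16-bit range.

A seeded synthetic-scene generator renders ground-truthed trap-array
images (hexagonal lattice, droplets, coloured cells / NP clusters /
debris, read noise), so every stage is validated end to end without
microscope data. See the methods vignette
(`vignettes/fluorodroplet-methods.Rmd`) for the models, defaults and
their rationale.

## Worked example

Generate a small two-droplet scene and analyse it:

```r
library(fluorodroplet)

spec <- sceneSpec(imageSize = c(420L, 560L), seed = 3L)
scene <- generateScene(spec, imageIndex = 1L)

cfg <- runConfig(boundaries = defaultColorBoundaries()[c("live", "dead",
                                                         "overlap")],
                 logLevel = "quiet")
res <- analyzeImage(scene$image, cfg)

dropletTable(res$droplets)
#>   dropletId   x   y radius votes
#> 1         1 457  98     41   127
#> 2         2 102 101     37   143

occupancySummary(res$encapsulation)
#>   nDroplets nEmpty nSce nMce nLive nDead nOverlap nEuNp nTbNp nFreeContours
#> 1         2      1    0    1     0     0        2     0     0             0
#>   nTracked viability
#> 1        0         0

res$intensity[, c("contourId", "classLabel", "nPixels", "mean", "normalizedMean")]
#>   contourId classLabel nPixels     mean normalizedMean
#> 1         1    overlap     145 40235.05       15.87181
#> 2         2    overlap     137 59759.77       23.57387
```

Two droplets are found at the trap sites (radii 41 and 37 px, centre
error ≤ 1 px against the generator's truth). Both rendered cells are
"dying" (overlap class) and sit in the same droplet, so the occupancy
table reports one multi-cell droplet and one empty droplet and a
viability of 0. Their mean intensities (40235 and 59760 grey units)
recover the generator's true means (40194 and 59759) to within 0.1%;
`normalizedMean` is the ratio to the background level estimated from the
droplet carrier fluid.

For folders of images, `runPipeline(loadConfig("cfg.yaml"))` writes
`droplets.csv`, `contours.csv`, `encapsulation.csv`, `intensity.csv` and
`summary.csv` (per-image rows plus a grand total). A thin command-line
wrapper is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fluorodroplet.R", package = "fluorodroplet"))')
Rscript "$CLI" simulate --out scenes/ --n-images 30 --seed 7 --kind viability
Rscript "$CLI" run --input scenes/ --out results/
```

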