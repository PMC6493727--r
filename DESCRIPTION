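Package: fluorodroplet
Title: Automated Quantification of Droplet Microfluidic Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch analysis of overlaid brightfield and fluorescence microscopy
    images from droplet microfluidic trapping arrays. Droplets held in a
    hexagonal trap lattice are detected with a Circular Hough Transform over a
    known radius range; fluorescent cells and nanoparticle clusters are
    detected per colour class by BGR boundary masking, Canny edge detection,
    morphological closing, random-walker segmentation and area thresholding.
    Droplet and contour centre maps are joined into encapsulation and
    co-encapsulation (droplet tracking) tables, and per-cell intracellular
    fluorescence statistics (mean, min, max, variance, background-normalised
    mean, 8-bit-binned histograms) are quantified on the 16-bit grayscale.
    A seeded synthetic-scene generator renders ground-truthed trap-array
    images so every pipeline stage can be validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    Matrix,
    EBImage,
    tiff,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jpeg,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'fluorodroplet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'droplets.R'
    'contours.R'
    'encapsulation.R'
    'intensity.R'
    'synthetic.R'
    'pipeline.R'
    'benchmarks.R'
    'imageIO.R'
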