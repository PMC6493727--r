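#' @include fluorodroplet-package.R
NULL

## ---------------------------------------------------------------------------
## Core image container
## ---------------------------------------------------------------------------

#' OverlayImage: a 16-bit, 3-channel microscopy overlay
#'
#' Holds an overlaid brightfield + fluorescence frame as an `H x W x 3`
#' integer array of 16-bit intensities in channel order (B, G, R), together
#' with its source path and the bit depth of the file it was read from.
#' All processing in the package happens in this 16-bit domain; 8-bit input
#' is lifted by a factor of 257 so that 255 maps to 65535 exactly.
#'
#' @slot pixels integer array `H x W x 3`, values in `[0, 65535]`, (B, G, R)
#' @slot sourcePath character scalar, origin file ("" for in-memory scenes)
#' @slot bitDepthOriginal integer, 8 or 16
#' @export
setClass("OverlayImage",
  representation(pixels = "array", sourcePath = "character",
                 bitDepthOriginal = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 1L || d[2] < 1L) return("H and W must be >= 1")
    rng <- range(object@pixels)
    if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 65535)
      return("intensities must lie in [0, 65535]")
    if (!object@bitDepthOriginal %in% c(8L, 16L))
      return("bitDepthOriginal must be 8 or 16")
    TRUE
  })

#' ImageBatch: an ordered folder of overlay images
#'
#' @slot paths character vector of image files, lexicographic order
#' @slot images list of [OverlayImage-class] (may be empty when loading
#'   lazily; `paths` always carries the batch order)
#' @slot folder character scalar
#' @export
setClass("ImageBatch",
  representation(paths = "character", images = "list", folder = "character"),
  validity = function(object) {
    if (length(object@paths) == 0L) return("batch is empty")
    if (is.unsorted(object@paths)) return("paths must be in lexicographic order")
    TRUE
  })

## ---------------------------------------------------------------------------
## Parameter objects
## ---------------------------------------------------------------------------

#' Droplet detection parameters
#'
#' Calibration and Circular Hough Transform settings. Radii and trap spacing
#' are given in microns and converted to pixels through `micronsPerPixel`
#' (default 1: the trap lattice has 360 um spacing and its published pixel
#' equivalent is 350-370 px, implying about 1 um/px).
#'
#' @slot micronsPerPixel um per pixel
#' @slot rMinUm,rMaxUm droplet radius range searched, um (defaults 25, 50)
#' @slot medianKernel odd median-filter width, px
#' @slot voteThresholdFrac accumulator peak threshold as a fraction of the
#'   ideal perimeter vote count `2*pi*R`
#' @slot radiusStep accumulator radius step, px
#' @slot minCenterDistance minimum distance between detected centres, px
#'   (`NA` = `2 * rMin` in pixels)
#' @slot trapSpacingUm,trapTolUm trap lattice spacing and tolerance, um
#' @slot latticeValidation check retained neighbour distances against the
#'   trap spacing and warn on violations
#' @export
setClass("DropletParams",
  representation(micronsPerPixel = "numeric", rMinUm = "numeric",
                 rMaxUm = "numeric", medianKernel = "integer",
                 voteThresholdFrac = "numeric", radiusStep = "numeric",
                 minCenterDistance = "numeric", trapSpacingUm = "numeric",
                 trapTolUm = "numeric", latticeValidation = "logical"),
  validity = function(object) {
    if (!(object@rMinUm > 0 && object@rMinUm < object@rMaxUm))
      return("need 0 < rMin < rMax")
    if (object@medianKernel < 3L || object@medianKernel %% 2L == 0L)
      return("medianKernel must be odd and >= 3")
    if (!(object@voteThresholdFrac > 0 && object@voteThresholdFrac <= 1))
      return("voteThresholdFrac must be in (0, 1]")
    if (!(object@trapTolUm < object@trapSpacingUm))
      return("trapTolUm must be smaller than trapSpacingUm")
    TRUE
  })

#' @param micronsPerPixel,rMinUm,rMaxUm,medianKernel,voteThresholdFrac,radiusStep,minCenterDistance,trapSpacingUm,trapTolUm,latticeValidation see slots
#' @return a `DropletParams` object
#' @rdname DropletParams-class
#' @export
dropletParams <- function(micronsPerPixel = 1, rMinUm = 25, rMaxUm = 50,
                          medianKernel = 3L, voteThresholdFrac = 0.4,
                          radiusStep = 1, minCenterDistance = NA_real_,
                          trapSpacingUm = 360, trapTolUm = 10,
                          latticeValidation = FALSE) {
  new("DropletParams", micronsPerPixel = micronsPerPixel, rMinUm = rMinUm,
      rMaxUm = rMaxUm, medianKernel = as.integer(medianKernel),
      voteThresholdFrac = voteThresholdFrac, radiusStep = radiusStep,
      minCenterDistance = minCenterDistance, trapSpacingUm = trapSpacingUm,
      trapTolUm = trapTolUm, latticeValidation = latticeValidation)
}

#' Contour detection parameters
#'
#' @slot cannyTMin,cannyTMax Canny hysteresis thresholds on the Sobel
#'   gradient magnitude (`NA` = automatic: high from Otsu on the non-zero
#'   gradient magnitudes, low = high / 2)
#' @slot morphKernel odd side of the square structuring element, px
#' @slot dilateIters,erodeIters morphology iteration counts
#' @slot minAreaCell area threshold for cell classes, px^2 (default 130)
#' @slot minAreaNp area threshold for nanoparticle classes, px^2 (default 150)
#' @slot hullDefectDepth convexity-defect depth above which a boundary is
#'   replaced by its convex hull, px
#' @slot mergeRadius centroid distance below which contours from different
#'   class passes are treated as one object, px
#' @slot beta random-walker edge-weight sharpness
#' @slot markerMinSep minimum separation of segmentation markers, px
#'   (`NA` = `sqrt(minAreaCell / pi)`)
#' @export
setClass("ContourParams",
  representation(cannyTMin = "numeric", cannyTMax = "numeric",
                 morphKernel = "integer", dilateIters = "integer",
                 erodeIters = "integer", minAreaCell = "numeric",
                 minAreaNp = "numeric", hullDefectDepth = "numeric",
                 mergeRadius = "numeric", beta = "numeric",
                 markerMinSep = "numeric"),
  validity = function(object) {
    if (!is.na(object@cannyTMin) && !is.na(object@cannyTMax) &&
        !(object@cannyTMin < object@cannyTMax))
      return("cannyTMin must be < cannyTMax")
    if (object@morphKernel < 1L || object@morphKernel %% 2L == 0L)
      return("morphKernel must be odd and >= 1")
    if (object@minAreaCell <= 0 || object@minAreaNp <= 0)
      return("area thresholds must be > 0")
    TRUE
  })

#' @param cannyTMin,cannyTMax,morphKernel,dilateIters,erodeIters,minAreaCell,minAreaNp,hullDefectDepth,mergeRadius,beta,markerMinSep see slots
#' @return a `ContourParams` object
#' @rdname ContourParams-class
#' @export
contourParams <- function(cannyTMin = NA_real_, cannyTMax = NA_real_,
                          morphKernel = 3L, dilateIters = 1L, erodeIters = 1L,
                          minAreaCell = 130, minAreaNp = 150,
                          hullDefectDepth = 3, mergeRadius = 5, beta = 130,
                          markerMinSep = NA_real_) {
  new("ContourParams", cannyTMin = cannyTMin, cannyTMax = cannyTMax,
      morphKernel = as.integer(morphKernel),
      dilateIters = as.integer(dilateIters),
      erodeIters = as.integer(erodeIters), minAreaCell = minAreaCell,
      minAreaNp = minAreaNp, hullDefectDepth = hullDefectDepth,
      mergeRadius = mergeRadius, beta = beta, markerMinSep = markerMinSep)
}

#' Colour boundary of a fluorescence class
#'
#' Lower/upper 8-bit (B, G, R) triples; a pixel belongs to the class when
#' every 16-bit channel lies within `[lower * 257, upper * 257]`.
#'
#' @slot classLabel one of live, dead, overlap, eu_np, tb_np, or a custom name
#' @slot lower,upper integer (B, G, R) triples, 0-255
#' @export
setClass("ColorBoundary",
  representation(classLabel = "character", lower = "integer",
                 upper = "integer"),
  validity = function(object) {
    if (length(object@lower) != 3L || length(object@upper) != 3L)
      return("lower and upper must be (B, G, R) triples")
    if (any(object@lower < 0L) || any(object@upper > 255L))
      return("boundaries must be 8-bit values")
    if (any(object@lower > object@upper))
      return("lower must be <= upper componentwise")
    TRUE
  })

#' @param classLabel,lower,upper see slots
#' @return a `ColorBoundary` object
#' @rdname ColorBoundary-class
#' @export
colorBoundary <- function(classLabel, lower, upper) {
  new("ColorBoundary", classLabel = classLabel,
      lower = as.integer(lower), upper = as.integer(upper))
}

#' Default colour boundaries for the five built-in classes
#'
#' Live (Calcein-AM green), dead (red), overlap ("dying", green + red),
#' Eu3+-doped nanoparticles (magenta) and Tb3+-doped nanoparticles (blue).
#'
#' @return named list of [ColorBoundary-class] objects
#' @export
defaultColorBoundaries <- function() {
  list(
    live    = colorBoundary("live",    c(0, 51, 0),   c(153, 255, 153)),
    dead    = colorBoundary("dead",    c(0, 0, 51),   c(153, 153, 255)),
    overlap = colorBoundary("overlap", c(0, 51, 51),  c(153, 255, 255)),
    eu_np   = colorBoundary("eu_np",   c(51, 0, 51),  c(255, 102, 255)),
    tb_np   = colorBoundary("tb_np",   c(51, 0, 0),   c(255, 51, 51))
  )
}

## cell-type classes counted for occupancy; NP classes only mark tracking
.CELL_CLASSES <- c("live", "dead", "overlap")
.NP_CLASSES <- c("eu_np", "tb_np")
## precedence when two class passes detect the same object (highest first)
.CLASS_PRECEDENCE <- c("overlap", "dead", "live", "eu_np", "tb_np")

## ---------------------------------------------------------------------------
## Result containers
## ---------------------------------------------------------------------------

#' DropletMap: detected droplets of one image
#'
#' @slot droplets data.frame with columns `dropletId, x, y, radius, votes`
#'   (x = column, y = row, 1-based pixel indices)
#' @slot imageIndex integer position of the image in its batch
#' @export
setClass("DropletMap",
  representation(droplets = "data.frame", imageIndex = "integer"),
  validity = function(object) {
    need <- c("dropletId", "x", "y", "radius", "votes")
    if (!all(need %in% names(object@droplets)))
      return(paste("droplets needs columns:", paste(need, collapse = ", ")))
    TRUE
  })

#' ContourSet: labelled fluorescent regions of one image
#'
#' @slot info data.frame with one row per contour: `contourId, classLabel,
#'   area, x, y, hullAdjusted` (x, y = centroid, 1-based)
#' @slot pixels list of 2-column integer matrices (row, col) per contour
#' @slot boundary list of 2-column matrices (x, y) tracing each boundary
#' @slot imageIndex integer
#' @export
setClass("ContourSet",
  representation(info = "data.frame", pixels = "list", boundary = "list",
                 imageIndex = "integer"),
  validity = function(object) {
    n <- nrow(object@info)
    if (length(object@pixels) != n || length(object@boundary) != n)
      return("pixels/boundary lists must match info rows")
    if (n > 0 && any(object@info$area != vapply(object@pixels, nrow, 1L)))
      return("area must equal the pixel-set size")
    TRUE
  })

#' EncapsulationResult: droplet occupancy and tracking for one image
#'
#' @slot records data.frame, one row per droplet: `dropletId, occupancy,
#'   nLive, nDead, nOverlap, nEuNp, nTbNp, tracked`
#' @slot assignments data.frame, one row per contour: `contourId, classLabel,
#'   dropletId` (`NA` = free-floating)
#' @slot summary one-row data.frame of population counts
#' @slot imageIndex integer
#' @export
setClass("EncapsulationResult",
  representation(records = "data.frame", assignments = "data.frame",
                 summary = "data.frame", imageIndex = "integer"))

## ---------------------------------------------------------------------------
## Synthetic scenes
## ---------------------------------------------------------------------------

#' SceneSpec: parameters of the synthetic trap-array scene generator
#'
#' Defaults emulate the imaged device: hexagonal trap lattice at 360 um
#' spacing (1 um/px), droplet radii 25-50 px, cell areas around 140 px^2,
#' nanoparticle cluster areas around 170 px^2, debris below 130 px^2.
#'
#' @slot imageSize (H, W) px
#' @slot micronsPerPixel um/px
#' @slot trapSpacing,trapRadius lattice spacing and trap radius, um
#' @slot margin lattice margin from the image border, px
#' @slot dropletRadiusRange droplet radius range, um
#' @slot occupancyProbs probabilities of 0..3 cells per droplet
#' @slot classMix named probabilities over cell classes (live/dead/overlap)
#' @slot npClasses nanoparticle classes present (character, may be empty)
#' @slot npMix probabilities over `npClasses`
#' @slot coEncapsulationRate probability a droplet carries NP cluster(s)
#' @slot cellAreaMean,cellAreaSd,cellAreaMin cell area distribution, px^2
#' @slot npAreaMean,npAreaSd,npAreaMin NP cluster area distribution, px^2
#' @slot debrisPerImage expected debris blobs per image (area < 130 px^2)
#' @slot debrisAreaRange debris area range, px^2
#' @slot freeCellsPerImage expected free-floating cells outside droplets
#' @slot cellIntensityRange,npIntensityRange 16-bit class-channel intensity
#' @slot noiseSigma i.i.d. Gaussian noise sd, 16-bit grey units
#' @slot backgroundLevel,dropletInterior,rimIntensity 16-bit grey levels
#' @slot rimWidth droplet rim half-width, px
#' @slot seed integer driving all randomness
#' @export
setClass("SceneSpec",
  representation(imageSize = "integer", micronsPerPixel = "numeric",
                 trapSpacing = "numeric", trapRadius = "numeric",
                 margin = "numeric", dropletRadiusRange = "numeric",
                 occupancyProbs = "numeric", classMix = "numeric",
                 npClasses = "character", npMix = "numeric",
                 coEncapsulationRate = "numeric", cellAreaMean = "numeric",
                 cellAreaSd = "numeric", cellAreaMin = "numeric",
                 npAreaMean = "numeric", npAreaSd = "numeric",
                 npAreaMin = "numeric", debrisPerImage = "numeric",
                 debrisAreaRange = "numeric", freeCellsPerImage = "numeric",
                 cellIntensityRange = "numeric", npIntensityRange = "numeric",
                 noiseSigma = "numeric", backgroundLevel = "numeric",
                 dropletInterior = "numeric", rimIntensity = "numeric",
                 rimWidth = "numeric", seed = "integer"),
  validity = function(object) {
    if (abs(sum(object@occupancyProbs) - 1) > 1e-8)
      return("occupancyProbs must sum to 1")
    if (length(object@classMix) > 0 && abs(sum(object@classMix) - 1) > 1e-8)
      return("classMix must sum to 1")
    if (length(object@npClasses) != length(object@npMix))
      return("npMix must match npClasses")
    if (object@dropletRadiusRange[1] >= object@dropletRadiusRange[2])
      return("dropletRadiusRange must be increasing")
    TRUE
  })

#' SceneTruth: ground truth of a generated scene
#'
#' @slot droplets data.frame `dropletId, x, y, radius`
#' @slot objects data.frame `objectId, type, classLabel, x, y, area,
#'   dropletId, trueMeanIntensity` (dropletId `NA` = free-floating)
#' @slot imageIndex integer
#' @export
setClass("SceneTruth",
  representation(droplets = "data.frame", objects = "data.frame",
                 imageIndex = "integer"))

## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

#' RunConfig: validated configuration of a pipeline run
#'
#' @slot inputDir,outputDir folders
#' @slot extensions file extensions loaded
#' @slot dropletParams [DropletParams-class]
#' @slot contourParams [ContourParams-class]
#' @slot boundaries named list of [ColorBoundary-class]; the class passes run
#' @slot classChannels named character mapping class -> intensity channel
#'   ("B", "G", "R" or "luminance")
#' @slot normalization "ratio" or "subtract"
#' @slot varianceMode "population" or "sample"
#' @slot debugOverlays write annotated overlay PNGs
#' @slot logLevel "quiet", "info" or "debug"
#' @export
setClass("RunConfig",
  representation(inputDir = "character", outputDir = "character",
                 extensions = "character", dropletParams = "DropletParams",
                 contourParams = "ContourParams", boundaries = "list",
                 classChannels = "character", normalization = "character",
                 varianceMode = "character", debugOverlays = "logical",
                 logLevel = "character"),
  validity = function(object) {
    if (!object@normalization %in% c("ratio", "subtract"))
      return("normalization must be 'ratio' or 'subtract'")
    if (!object@varianceMode %in% c("population", "sample"))
      return("varianceMode must be 'population' or 'sample'")
    ok <- vapply(object@boundaries, function(b) is(b, "ColorBoundary"), TRUE)
    if (length(ok) && !all(ok)) return("boundaries must be ColorBoundary objects")
    TRUE
  })
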