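#' @include AllClasses.R
NULL

#' Number of detected droplets
#' @param x a [DropletMap-class]
#' @return integer count (always the length of the droplet table)
#' @export
setGeneric("nDroplets", function(x) standardGeneric("nDroplets"))

#' @rdname nDroplets
#' @export
setMethod("nDroplets", "DropletMap", function(x) nrow(x@droplets))

#' Droplet table accessor
#' @param x a [DropletMap-class]
#' @return data.frame `dropletId, x, y, radius, votes`
#' @export
setGeneric("dropletTable", function(x) standardGeneric("dropletTable"))

#' @rdname dropletTable
#' @export
setMethod("dropletTable", "DropletMap", function(x) x@droplets)

#' Number of contours
#' @param x a [ContourSet-class]
#' @return integer count
#' @export
setGeneric("nContours", function(x) standardGeneric("nContours"))

#' @rdname nContours
#' @export
setMethod("nContours", "ContourSet", function(x) nrow(x@info))

#' Contour table accessor
#' @param x a [ContourSet-class]
#' @return data.frame `contourId, classLabel, area, x, y, hullAdjusted`
#' @export
setGeneric("contourTable", function(x) standardGeneric("contourTable"))

#' @rdname contourTable
#' @export
setMethod("contourTable", "ContourSet", function(x) x@info)

#' Contour pixel set accessor
#' @param x a [ContourSet-class]
#' @param i contour index (row of [contourTable()])
#' @return 2-column integer matrix (row, col)
#' @export
setGeneric("contourPixels", function(x, i) standardGeneric("contourPixels"))

#' @rdname contourPixels
#' @export
setMethod("contourPixels", "ContourSet", function(x, i) x@pixels[[i]])

#' Image pixel accessor
#' @param x an [OverlayImage-class]
#' @return integer `H x W x 3` array in (B, G, R) order
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' @rdname imagePixels
#' @export
setMethod("imagePixels", "OverlayImage", function(x) x@pixels)

#' Occupancy summary accessor
#' @param x an [EncapsulationResult-class]
#' @return one-row data.frame of population counts
#' @export
setGeneric("occupancySummary", function(x) standardGeneric("occupancySummary"))

#' @rdname occupancySummary
#' @export
setMethod("occupancySummary", "EncapsulationResult", function(x) x@summary)

setMethod("show", "OverlayImage", function(object) {
  d <- dim(object@pixels)
  cat("OverlayImage ", d[1], "x", d[2], " (B,G,R), 16-bit (source depth ",
      object@bitDepthOriginal, ")\n", sep = "")
  if (nzchar(object@sourcePath)) cat("  source:", object@sourcePath, "\n")
})

setMethod("show", "ImageBatch", function(object) {
  cat("ImageBatch of", length(object@paths), "images from",
      object@folder, "\n")
})

setMethod("show", "DropletMap", function(object) {
  cat("DropletMap:", nrow(object@droplets), "droplets (image",
      object@imageIndex, ")\n")
  if (nrow(object@droplets)) print(head(object@droplets, 5))
})

setMethod("show", "ContourSet", function(object) {
  cat("ContourSet:", nrow(object@info), "contours (image",
      object@imageIndex, ")\n")
  if (nrow(object@info)) print(table(object@info$classLabel))
})

setMethod("show", "EncapsulationResult", function(object) {
  cat("EncapsulationResult (image", object@imageIndex, ")\n")
  print(object@summary)
})

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth:", nrow(object@droplets), "droplets,",
      nrow(object@objects), "objects (image", object@imageIndex, ")\n")
})

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec ", object@imageSize[1], "x", object@imageSize[2],
      " px, trap spacing ", object@trapSpacing, " um, droplet radii [",
      object@dropletRadiusRange[1], ", ", object@dropletRadiusRange[2],
      "] um, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: input", object@inputDir, "-> output", object@outputDir,
      "\n  classes:", paste(names(object@boundaries), collapse = ", "), "\n")
})
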