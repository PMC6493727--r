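#' @include AllClasses.R synthetic.R
NULL

#' Build a validated run configuration
#'
#' @param inputDir,outputDir input image folder and output folder
#' @param extensions image extensions to load
#' @param dropletParams a [DropletParams-class]
#' @param contourParams a [ContourParams-class]
#' @param boundaries named list of [ColorBoundary-class]; the class passes
#'   to run (defaults to all five built-in classes)
#' @param classChannels named map class -> intensity channel
#' @param normalization "ratio" or "subtract"
#' @param varianceMode "population" or "sample"
#' @param debugOverlays write annotated overlay PNGs next to the tables
#' @param logLevel "quiet", "info" or "debug"
#' @return a [RunConfig-class]
#' @export
runConfig <- function(inputDir = ".", outputDir = "fluorodroplet_out",
                      extensions = c("tiff", "tif", "png"),
                      dropletParams = fluorodroplet::dropletParams(),
                      contourParams = fluorodroplet::contourParams(),
                      boundaries = defaultColorBoundaries(),
                      classChannels = .DEFAULT_CLASS_CHANNELS,
                      normalization = "ratio",
                      varianceMode = "population",
                      debugOverlays = FALSE, logLevel = "info") {
  cfg <- new("RunConfig", inputDir = inputDir, outputDir = outputDir,
             extensions = extensions, dropletParams = dropletParams,
             contourParams = contourParams, boundaries = boundaries,
             classChannels = classChannels, normalization = normalization,
             varianceMode = varianceMode, debugOverlays = debugOverlays,
             logLevel = logLevel)
  validObject(cfg)
  validObject(dropletParams)
  validObject(contourParams)
  for (b in boundaries) validObject(b)
  cfg
}

#' Load a run configuration from YAML
#'
#' Unspecified keys keep their documented defaults (25-50 um radii,
#' 130/150 px^2 area thresholds, the five built-in colour boundaries,
#' 360 um trap spacing); unknown keys raise a warning; invalid values are
#' fatal with the offending key named.
#'
#' @param path YAML file
#' @return a [RunConfig-class]
#' @export
loadConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("input", "output", "extensions", "droplet", "contour",
             "classes", "boundaries", "intensity", "debug_overlays",
             "log_level")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))

  dp <- do.call(dropletParams, .mapKeys(y$droplet, c(
    microns_per_pixel = "micronsPerPixel", r_min_um = "rMinUm",
    r_max_um = "rMaxUm", median_kernel = "medianKernel",
    vote_threshold_frac = "voteThresholdFrac", radius_step = "radiusStep",
    min_center_distance = "minCenterDistance",
    trap_spacing_um = "trapSpacingUm", trap_tol_um = "trapTolUm",
    lattice_validation = "latticeValidation"), "droplet"))
  cp <- do.call(contourParams, .mapKeys(y$contour, c(
    canny_t_min = "cannyTMin", canny_t_max = "cannyTMax",
    morph_kernel = "morphKernel", dilate_iters = "dilateIters",
    erode_iters = "erodeIters", min_area_cell = "minAreaCell",
    min_area_np = "minAreaNp", hull_defect_depth = "hullDefectDepth",
    merge_radius = "mergeRadius", beta = "beta",
    marker_min_sep = "markerMinSep"), "contour"))

  bounds <- defaultColorBoundaries()
  if (!is.null(y$classes)) bounds <- bounds[unlist(y$classes)]
  if (!is.null(y$boundaries)) {
    for (nm in names(y$boundaries)) {
      b <- y$boundaries[[nm]]
      bounds[[nm]] <- colorBoundary(nm, unlist(b$lower), unlist(b$upper))
    }
  }
  if (any(vapply(bounds, is.null, TRUE)))
    stop("config error at key 'classes': unknown class name")

  intens <- y$intensity
  cc <- .DEFAULT_CLASS_CHANNELS
  if (!is.null(intens$class_channels))
    cc[names(intens$class_channels)] <- unlist(intens$class_channels)

  tryCatch(
    runConfig(inputDir = y$input %||% ".",
              outputDir = y$output %||% "fluorodroplet_out",
              extensions = unlist(y$extensions %||%
                                    list("tiff", "tif", "png")),
              dropletParams = dp, contourParams = cp, boundaries = bounds,
              classChannels = cc,
              normalization = intens$normalization %||% "ratio",
              varianceMode = intens$variance %||% "population",
              debugOverlays = isTRUE(y$debug_overlays),
              logLevel = y$log_level %||% "info"),
    error = function(e) stop("config error: ", conditionMessage(e),
                             call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## translate snake_case YAML keys into constructor arguments, complaining
## about unknown ones
.mapKeys <- function(lst, map, section) {
  if (is.null(lst)) return(list())
  bad <- setdiff(names(lst), names(map))
  if (length(bad))
    warning("unknown config keys ignored in '", section, "': ",
            paste(bad, collapse = ", "))
  args <- lst[names(lst) %in% names(map)]
  names(args) <- map[names(args)]
  ## "auto" thresholds mean NA (derive from the data)
  args <- lapply(args, function(v) if (identical(v, "auto")) NA_real_ else v)
  args
}

#' Analyze one overlay image
#'
#' The per-image pipeline: luminance grayscale + median smoothing, Circular
#' Hough Transform, trap deduplication, per-class contour passes with area
#' filtering and conflict resolution, contour-to-droplet assignment,
#' occupancy classification and intensity quantification.
#'
#' @param img an [OverlayImage-class]
#' @param config a [RunConfig-class]
#' @param imageIndex index recorded in all outputs
#' @return list `droplets` ([DropletMap-class]), `contours`
#'   ([ContourSet-class]), `encapsulation` ([EncapsulationResult-class]),
#'   `intensity` (data.frame)
#' @export
analyzeImage <- function(img, config = runConfig(), imageIndex = 1L) {
  dp <- config@dropletParams
  gray <- medianSmooth(.luminance(img@pixels), dp@medianKernel)
  dm <- circularHough(gray, dp, imageIndex)
  dm <- deduplicateTraps(dm, dp)
  cs <- detectContours(img, config@boundaries, config@contourParams,
                       imageIndex)
  enc <- classifyOccupancy(assignContoursToDroplets(dm, cs))
  it <- intensityTable(img, cs, enc, dm, config@classChannels,
                       config@normalization, config@varianceMode)
  list(droplets = dm, contours = cs, encapsulation = enc, intensity = it)
}

#' Run the batch pipeline over a folder (or in-memory images)
#'
#' Processes every image independently and writes `droplets.csv`,
#' `contours.csv`, `encapsulation.csv`, `intensity.csv` and `summary.csv`
#' (per-image rows plus a grand-total row) into the output folder.
#' Re-running on the same inputs yields byte-identical tables: every stage
#' is deterministic.
#'
#' @param config a [RunConfig-class]
#' @param images optional list of [OverlayImage-class] to analyze instead
#'   of reading `config@inputDir`
#' @param writeTables write the CSV outputs (disable for in-memory use)
#' @return (invisibly) list `summary` (data.frame), `perImage` (list of
#'   [analyzeImage()] results)
#' @export
runPipeline <- function(config, images = NULL, writeTables = TRUE) {
  t0 <- Sys.time()
  if (is.null(images)) {
    if (!dir.exists(config@inputDir))
      stop("input folder not found: ", config@inputDir)
    batch <- loadImageBatch(config@inputDir, config@extensions)
    n <- length(batch@paths)
    getImage <- function(i) batch@images[[i]]
  } else {
    n <- length(images)
    getImage <- function(i) images[[i]]
  }
  if (writeTables && !dir.exists(config@outputDir))
    dir.create(config@outputDir, recursive = TRUE)

  perImage <- vector("list", n)
  summaries <- vector("list", n)
  info <- config@logLevel %in% c("info", "debug")
  for (i in seq_len(n)) {
    ti <- Sys.time()
    res <- tryCatch(analyzeImage(getImage(i), config, i), error = function(e)
      stop("image ", i, ": ", conditionMessage(e), call. = FALSE))
    perImage[[i]] <- res
    s <- res$encapsulation@summary
    summaries[[i]] <- cbind(image = i, s)
    if (info)
      message(sprintf(
        "image %d: %d droplets | live %d dead %d overlap %d | SCE %d MCE %d | %.1fs",
        i, s$nDroplets, s$nLive, s$nDead, s$nOverlap, s$nSce, s$nMce,
        as.numeric(difftime(Sys.time(), ti, units = "secs"))))
    if (config@debugOverlays && writeTables)
      .writeOverlayPNG(getImage(i), res$droplets, res$contours,
                       file.path(config@outputDir,
                                 sprintf("overlay_%03d.png", i)))
  }
  summary <- do.call(rbind, summaries)
  total <- summary[1, , drop = FALSE]
  total$image <- NA_integer_
  for (cn in setdiff(names(summary), c("image", "viability")))
    total[[cn]] <- sum(summary[[cn]])
  total$viability <- if ((total$nLive + total$nDead + total$nOverlap) > 0)
    total$nLive / (total$nLive + total$nDead + total$nOverlap) else NA_real_
  summary <- rbind(summary, total)
  rownames(summary) <- NULL

  if (writeTables) {
    .writeRunTables(config@outputDir, perImage, summary)
    if (info)
      message(sprintf("batch of %d image(s) done in %.1fs", n,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(list(summary = summary, perImage = perImage))
}

.writeRunTables <- function(outDir, perImage, summary) {
  dropletRows <- lapply(perImage, function(r)
    if (nrow(r$droplets@droplets))
      cbind(image = r$droplets@imageIndex, r$droplets@droplets) else NULL)
  contourRows <- lapply(perImage, function(r)
    if (nrow(r$contours@info))
      cbind(image = r$contours@imageIndex, r$contours@info) else NULL)
  encRows <- lapply(perImage, function(r) coEncapsulationTable(r$encapsulation))
  intRows <- lapply(perImage, function(r) r$intensity)
  exportTable(do.call(rbind, dropletRows) %||%
                data.frame(image = integer(), dropletId = integer()),
              file.path(outDir, "droplets.csv"), "csv")
  exportTable(do.call(rbind, contourRows) %||%
                data.frame(image = integer(), contourId = integer()),
              file.path(outDir, "contours.csv"), "csv")
  exportTable(do.call(rbind, encRows), file.path(outDir, "encapsulation.csv"),
              "csv")
  exportTable(do.call(rbind, intRows), file.path(outDir, "intensity.csv"),
              "csv")
  exportTable(summary, file.path(outDir, "summary.csv"), "csv")
}

## annotated overlay: droplet boundaries green, centres orange, contour
## boundaries in the display colours used for each class
.OVERLAY_COLORS <- list(live = c(255, 0, 0), dead = c(0, 0, 255),
                        overlap = c(160, 32, 240), eu_np = c(255, 255, 0),
                        tb_np = c(255, 165, 0))

.writeOverlayPNG <- function(img, dm, cs, path) {
  px <- img@pixels
  rgb <- array(0, c(dim(px)[1], dim(px)[2], 3L))
  for (k in 1:3) rgb[, , k] <- px[, , 4L - k] / 65535
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  setPix <- function(rows, cols, colr) {
    ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
    idx <- rows[ok] + (cols[ok] - 1L) * H
    for (k in 1:3) {
      pl <- rgb[, , k]
      pl[idx] <- colr[k] / 255
      rgb[, , k] <<- pl
    }
  }
  dd <- dm@droplets
  for (i in seq_len(nrow(dd))) {
    th <- seq(0, 2 * pi, length.out = max(32L, round(4 * dd$radius[i])))
    setPix(round(dd$y[i] + dd$radius[i] * sin(th)),
           round(dd$x[i] + dd$radius[i] * cos(th)), c(0, 255, 0))
    setPix(rep(round(dd$y[i]) + (-1:1), 3),
           rep(round(dd$x[i]) + (-1:1), each = 3), c(255, 165, 0))
  }
  for (i in seq_len(nContours(cs))) {
    b <- cs@boundary[[i]]
    colr <- .OVERLAY_COLORS[[cs@info$classLabel[i]]] %||% c(255, 255, 255)
    setPix(round(b[, 2]), round(b[, 1]), colr)
  }
  png::writePNG(rgb, path)
  invisible(path)
}
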