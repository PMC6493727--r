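#' @include AllClasses.R
NULL

#' Median smoothing of a 16-bit grayscale
#'
#' Every output pixel is the median of its `kernel x kernel` neighbourhood
#' with edge-replicated borders, removing speckle noise while preserving the
#' droplet rims that the Hough transform consumes.
#'
#' @param gray integer matrix (H x W) of 16-bit intensities
#' @param kernel odd window width, px
#' @return integer matrix of the same size
#' @export
medianSmooth <- function(gray, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("median kernel must be odd")
  if (kernel > min(dim(gray))) stop("kernel larger than the image")
  storage.mode(gray) <- "integer"
  cpp_median_filter(gray, kernel)
}

## Gradient-magnitude edge map for the Hough stage, with the automatic
## hysteresis thresholds of .autoHighThreshold (low = high / 2).
.gradientEdges <- function(gray) {
  g <- cpp_sobel(matrix(as.numeric(gray), nrow(gray), ncol(gray)))
  mag <- sqrt(g$gx^2 + g$gy^2)
  pos <- mag[mag > 0]
  if (length(pos) == 0L)
    return(list(edges = matrix(FALSE, nrow(gray), ncol(gray)),
                gx = g$gx, gy = g$gy))
  high <- .autoHighThreshold(mag, pos)
  edges <- cpp_canny_nms(g$gx, g$gy, high / 2, high)
  list(edges = edges, gx = g$gx, gy = g$gy)
}

#' Circular Hough Transform droplet detection
#'
#' Finds circles of known radius range in a smoothed grayscale. Edge pixels
#' (gradient-magnitude hysteresis with automatic thresholds) vote along
#' their +/- gradient direction into a per-radius `(a, b)` accumulator;
#' accumulator cells whose 3x3-pooled votes reach
#' `voteThresholdFrac * 2 * pi * R` become centre candidates, and greedy
#' non-maximum suppression (highest votes first, ties broken towards the
#' smaller (row, col)) enforces a minimum centre separation. The droplet
#' count is by definition the length of the returned droplet table.
#'
#' @param gray smoothed integer grayscale matrix (see [medianSmooth()])
#' @param params a [DropletParams-class]
#' @param imageIndex index recorded in the result
#' @return a [DropletMap-class]
#' @export
circularHough <- function(gray, params = dropletParams(), imageIndex = 1L) {
  mpp <- params@micronsPerPixel
  rMin <- max(2L, as.integer(round(params@rMinUm / mpp)))
  rMax <- as.integer(round(params@rMaxUm / mpp))
  radii <- as.integer(unique(round(seq(rMin, rMax, by = params@radiusStep))))
  mcd <- params@minCenterDistance
  if (is.na(mcd)) mcd <- 2 * rMin

  e <- .gradientEdges(gray)
  cand <- cpp_cht_candidates(e$edges, e$gx, e$gy, radii,
                             params@voteThresholdFrac)
  kept <- .greedyNms(cand, mcd)
  .newDropletMap(kept, imageIndex)
}

## greedy non-maximum suppression over candidate peaks (0-based row/col in,
## same out); highest votes first, tie -> smaller (row, col)
.greedyNms <- function(cand, minDist) {
  if (nrow(cand) == 0L)
    return(data.frame(row = integer(), col = integer(),
                      radius = integer(), votes = integer()))
  o <- order(-cand$votes, cand$row, cand$col)
  cand <- cand[o, , drop = FALSE]
  keep <- integer(0)
  kr <- numeric(0); kc <- numeric(0)
  d2 <- minDist^2
  for (i in seq_len(nrow(cand))) {
    if (length(keep) == 0L ||
        all((kr - cand$row[i])^2 + (kc - cand$col[i])^2 >= d2)) {
      keep <- c(keep, i)
      kr <- c(kr, cand$row[i]); kc <- c(kc, cand$col[i])
    }
  }
  cand[keep, , drop = FALSE]
}

## candidate rows (0-based) -> DropletMap with ids in centre-lexicographic
## (y, x) order and 1-based pixel coordinates
.newDropletMap <- function(kept, imageIndex) {
  if (nrow(kept) > 0L) {
    df <- data.frame(x = kept$col + 1L, y = kept$row + 1L,
                     radius = kept$radius, votes = kept$votes)
    df <- df[order(df$y, df$x), , drop = FALSE]
    df <- cbind(dropletId = seq_len(nrow(df)), df)
    rownames(df) <- NULL
  } else {
    df <- data.frame(dropletId = integer(), x = integer(), y = integer(),
                     radius = integer(), votes = integer())
  }
  new("DropletMap", droplets = df, imageIndex = as.integer(imageIndex))
}

#' Eliminate multiple detections per trap
#'
#' Detections whose centres lie within `2 * rMax` (px) of one another are
#' grouped as a single trap and only the highest-vote member is kept. When
#' `latticeValidation` is enabled the retained nearest-neighbour distances
#' are checked against the hexagonal trap spacing (`trapSpacingUm` +/-
#' `trapTolUm`) and violations are reported via [message()] but never
#' removed.
#'
#' @param map a [DropletMap-class] from [circularHough()]
#' @param params a [DropletParams-class]
#' @return a deduplicated [DropletMap-class]
#' @export
deduplicateTraps <- function(map, params = dropletParams()) {
  df <- map@droplets
  if (nrow(df) <= 1L) return(map)
  groupDist <- 2 * params@rMaxUm / params@micronsPerPixel
  o <- order(-df$votes, df$y, df$x)
  df <- df[o, , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ki <- which(keep)
    if (length(ki) == 0L ||
        all(sqrt((df$x[ki] - df$x[i])^2 + (df$y[ki] - df$y[i])^2) >= groupDist))
      keep[i] <- TRUE
  }
  df <- df[keep, , drop = FALSE]
  if (params@latticeValidation && nrow(df) > 1L) {
    spacing <- params@trapSpacingUm / params@micronsPerPixel
    tol <- params@trapTolUm / params@micronsPerPixel
    d <- as.matrix(stats::dist(df[, c("x", "y")]))
    diag(d) <- Inf
    nn <- apply(d, 1L, min)
    off <- abs(nn - spacing) > tol
    if (any(off))
      message(sum(off), " droplet(s) off the trap lattice (nearest ",
              "neighbour outside ", spacing, " +/- ", tol, " px)")
  }
  kept <- data.frame(row = df$y - 1L, col = df$x - 1L,
                     radius = df$radius, votes = df$votes)
  .newDropletMap(kept, map@imageIndex)
}

## Automatic Canny high threshold on a gradient-magnitude image: a pure
## noise floor. Edge strength in these overlays spans an order of
## magnitude (droplet rims and dim cells sit 5-10x below bright cells), so
## any threshold adapted to the structure present — Otsu or a quantile —
## erases the faint population whenever the bright one dominates. The only
## edges that must be suppressed are noise edges: 8x the median gradient
## magnitude of the frame sits near 10 sigma of the noise gradient, and a
## small absolute floor of 256 grey units (sub-0.4% contrast on the 16-bit
## scale) covers noise-free frames where the median is 0. Spurious weak
## structure this admits is harmless downstream: in the Hough stage it does
## not lie on circles of the droplet radii, and in the contour stage it
## falls inside masked blobs whose interiors are filled anyway.
.autoHighThreshold <- function(mag, pos = mag[mag > 0]) {
  max(8 * .fastMedian(mag), 256)
}

## median via partial sort (stats::median fully sorts megapixel vectors)
.fastMedian <- function(x) {
  n <- length(x)
  half <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) sort(x, partial = half)[half]
  else { s <- sort(x, partial = c(half, half + 1L)); (s[half] + s[half + 1L]) / 2 }
}
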