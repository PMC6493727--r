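#' @include AllClasses.R droplets.R
NULL

#' Binary colour mask of one fluorescence class
#'
#' A pixel is in the mask iff every channel lies within the class's
#' `[lower * 257, upper * 257]` interval: 8-bit (B, G, R) boundaries are
#' lifted into the 16-bit processing domain before the componentwise test.
#'
#' @param img an [OverlayImage-class]
#' @param boundary a [ColorBoundary-class]
#' @return logical H x W matrix
#' @export
buildColorMask <- function(img, boundary) {
  px <- img@pixels
  cpp_color_mask(px, dim(px)[1], dim(px)[2],
                 boundary@lower * 257L, boundary@upper * 257L)
}

## Rec. 601 luminance on the (B, G, R) array, rounded to integer grey;
## optionally zeroed outside a mask
.luminance <- function(px, mask = NULL) {
  cpp_luminance(px, dim(px)[1], dim(px)[2], mask)
}

#' Masked, smoothed grayscale of an overlay image
#'
#' Pixels outside the mask are set to zero, the remaining (B, G, R) values
#' are converted to luminance grayscale (Rec. 601 weights
#' `0.114 B + 0.587 G + 0.299 R`, rounded) and the result is median-smoothed.
#'
#' @param img an [OverlayImage-class]
#' @param mask logical H x W matrix (or `NULL` for the whole frame)
#' @param kernel odd median window, px
#' @return integer H x W matrix
#' @export
maskedGrayscale <- function(img, mask = NULL, kernel = 3L) {
  if (!is.null(mask) && !all(dim(mask) == dim(img@pixels)[1:2]))
    stop("mask shape does not match the image")
  medianSmooth(.luminance(img@pixels, mask), kernel)
}

#' Canny edge detection
#'
#' Median smoothing, Sobel gradient, non-maximum suppression perpendicular
#' to the gradient and hysteresis linking between `tMin` and `tMax`. With
#' `NA` thresholds the high threshold is a noise floor — 8x the median
#' gradient magnitude of the frame (about 10 sigma of the read-noise
#' gradient), floored at 256 grey units for noise-free frames — and the
#' low threshold is half of it. A data-adaptive split (e.g. Otsu) is
#' deliberately not used: edge strength spans an order of magnitude across
#' dim and bright objects, and a threshold adapted to the bright
#' population erases the dim one.
#'
#' @param gray integer H x W grayscale matrix
#' @param tMin,tMax hysteresis thresholds on the Sobel gradient magnitude
#' @param medianKernel smoothing window applied before the gradient
#' @return logical H x W edge mask (thin edges)
#' @export
cannyEdges <- function(gray, tMin = NA, tMax = NA, medianKernel = 3L) {
  if (!is.na(tMin) && !is.na(tMax) && tMin >= tMax)
    stop("tMin must be < tMax")
  sm <- medianSmooth(gray, medianKernel)
  g <- cpp_sobel(matrix(as.numeric(sm), nrow(sm), ncol(sm)))
  if (is.na(tMin) || is.na(tMax)) {
    mag <- sqrt(g$gx^2 + g$gy^2)
    pos <- mag[mag > 0]
    if (length(pos) == 0L) return(matrix(FALSE, nrow(gray), ncol(gray)))
    tMax <- .autoHighThreshold(mag, pos)
    tMin <- tMax / 2
  }
  cpp_canny_nms(g$gx, g$gy, tMin, tMax)
}

#' Binary morphology with a square structuring element
#'
#' Minkowski dilation / erosion with a `kernel x kernel` box applied `iters`
#' times; pixels outside the image count as background. Dilation joins
#' broken edge fragments, the subsequent erosion removes speckle and
#' detaches touching objects (the pipeline applies them in that order,
#' i.e. a morphological closing).
#'
#' @param mask logical H x W matrix
#' @param kernel odd box side, px
#' @param iters iteration count
#' @return logical H x W matrix
#' @export
morphDilate <- function(mask, kernel = 3L, iters = 1L) {
  cpp_box_dilate(mask, as.integer(kernel), as.integer(iters))
}

#' @rdname morphDilate
#' @export
morphErode <- function(mask, kernel = 3L, iters = 1L) {
  cpp_box_erode(mask, as.integer(kernel), as.integer(iters))
}

## ---------------------------------------------------------------------------
## Random-walker segmentation
## ---------------------------------------------------------------------------

## seeds for segmentation: local maxima of the distance transform with a
## minimum separation; returns a matrix (row, col) ordered by decreasing
## distance value
.distanceMarkers <- function(mask, minSep) {
  dm <- EBImage::distmap(mask * 1L)
  dm <- dm@.Data
  if (!any(dm > 0)) return(matrix(integer(), 0L, 2L))
  s <- max(1L, as.integer(ceiling(minSep)))
  dmax <- cpp_box_maxfilter(dm, 2L * s + 1L)
  cand <- dm >= dmax - 1e-9 & dm >= 1.2
  if (!any(cand)) cand <- dm >= dmax - 1e-9 & dm > 0
  plat <- cpp_label8(cand)
  n <- max(plat)
  idx <- which(plat > 0)
  rc <- arrayInd(idx, dim(plat))
  lab <- plat[idx]
  ## one representative pixel per plateau: the member closest to the
  ## plateau centroid (ties -> smaller (row, col))
  reps <- matrix(0L, n, 2L)
  vals <- numeric(n)
  for (k2 in seq_len(n)) {
    m <- rc[lab == k2, , drop = FALSE]
    ctr <- colMeans(m)
    d2 <- (m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2
    o <- order(d2, m[, 1], m[, 2])[1]
    reps[k2, ] <- m[o, ]
    vals[k2] <- dm[m[o, 1], m[o, 2]]
  }
  o <- order(-vals, reps[, 1], reps[, 2])
  reps <- reps[o, , drop = FALSE]
  ## greedy min-separation
  keep <- logical(nrow(reps))
  for (i in seq_len(nrow(reps))) {
    ki <- which(keep)
    if (length(ki) == 0L ||
        all((reps[ki, 1] - reps[i, 1])^2 + (reps[ki, 2] - reps[i, 2])^2 >=
            minSep^2))
      keep[i] <- TRUE
  }
  reps[keep, , drop = FALSE]
}

## random-walker label assignment within one connected component.
## pixIdx: linear indices of the component; seeds: linear indices of its
## markers; returns per-pixel marker assignment (integer along pixIdx).
.randomWalkerComponent <- function(pixIdx, seeds, dims, gray = NULL,
                                   beta = 130) {
  n <- length(pixIdx)
  id <- integer(prod(dims))
  id[pixIdx] <- seq_len(n)
  H <- dims[1]
  ## 4-neighbour edges (right and down)
  rc <- arrayInd(pixIdx, dims)
  nbr <- list(pixIdx + 1L, pixIdx + H)
  ok <- list(rc[, 1] < dims[1], rc[, 2] < dims[2])
  ei <- integer(0); ej <- integer(0)
  for (d in 1:2) {
    sel <- ok[[d]] & id[nbr[[d]]] > 0L
    ei <- c(ei, id[pixIdx[sel]])
    ej <- c(ej, id[nbr[[d]][sel]])
  }
  if (is.null(gray)) {
    w <- rep(1, length(ei))
  } else {
    gv <- as.numeric(gray[pixIdx]) / 65535
    w <- exp(-beta * (gv[ei] - gv[ej])^2) + 1e-6
  }
  L <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = c(-w, -w),
                            dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  sIdx <- id[seeds]
  uIdx <- setdiff(seq_len(n), sIdx)
  m <- length(seeds)
  lab <- integer(n)
  lab[sIdx] <- seq_len(m)
  if (length(uIdx)) {
    B <- L[uIdx, sIdx, drop = FALSE]
    rhs <- -B %*% diag(m)
    X <- as.matrix(Matrix::solve(L[uIdx, uIdx], rhs))
    lab[uIdx] <- max.col(X, ties.method = "first")
  }
  lab
}

#' Split touching objects with seeded random-walker segmentation
#'
#' Markers are placed at local maxima of the distance transform of the
#' (filled) mask with a minimum separation of `sqrt(minAreaCell / pi)` px by
#' default; every foreground pixel is then assigned to exactly one marker by
#' the probability that a random walker started there reaches that marker
#' first (combinatorial Dirichlet problem on the 4-connected pixel graph).
#' Components containing a single marker (or none) keep a single label, so
#' well-separated objects are never split.
#'
#' @param mask logical H x W matrix, interior-filled
#' @param gray optional grayscale used for edge weights
#'   `exp(-beta * dg^2)`; with `NULL` all edges weigh equally
#' @param params a [ContourParams-class] (`beta`, `markerMinSep`,
#'   `minAreaCell`)
#' @return integer H x W label matrix (0 = background)
#' @export
segmentTouching <- function(mask, gray = NULL, params = contourParams()) {
  labels <- cpp_label8(mask)
  if (max(labels) == 0L) return(labels)
  minSep <- params@markerMinSep
  if (is.na(minSep)) minSep <- sqrt(params@minAreaCell / pi)
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  comps <- split(idx, labels[idx])
  out <- matrix(0L, H, W)
  nextLab <- 0L
  for (pixIdx in comps) {
    ## work on a padded crop of this component only: the distance
    ## transform and marker search are local operations
    rc <- arrayInd(pixIdx, c(H, W))
    r0 <- max(1L, min(rc[, 1]) - 1L); r1 <- min(H, max(rc[, 1]) + 1L)
    c0 <- max(1L, min(rc[, 2]) - 1L); c1 <- min(W, max(rc[, 2]) + 1L)
    h <- r1 - r0 + 1L
    sub <- matrix(FALSE, h, c1 - c0 + 1L)
    subIdx <- (rc[, 1] - r0 + 1L) + (rc[, 2] - c0) * h
    sub[subIdx] <- TRUE
    markers <- .distanceMarkers(sub, minSep)
    if (nrow(markers) <= 1L) {
      nextLab <- nextLab + 1L
      out[pixIdx] <- nextLab
    } else {
      seeds <- markers[, 1] + (markers[, 2] - 1L) * h
      subGray <- if (is.null(gray)) NULL else
        gray[r0:r1, c0:c1, drop = FALSE]
      lab <- .randomWalkerComponent(subIdx, seeds, dim(sub), subGray,
                                    params@beta)
      out[pixIdx] <- nextLab + lab
      nextLab <- nextLab + length(seeds)
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Contour extraction
## ---------------------------------------------------------------------------

## distance of points (x, y) to a closed polygon given by hull vertices
.distToPolygon <- function(pts, poly) {
  m <- nrow(poly)
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(m)) {
    a <- poly[i, ]; b <- poly[if (i == m) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      d <- sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 +
                (pts[, 2] - (a[2] + t * ab[2]))^2)
    }
    dmin <- pmin(dmin, d)
  }
  dmin
}

## trace the outer boundary of one pixel set as an ordered (x, y) polygon:
## boundary pixels (those with a 4-neighbour outside the set) ordered by
## angle around the centroid; adequate for the near-convex blobs handled
## here and replaced by the convex hull when defects are deep
.traceBoundary <- function(pix) {
  if (nrow(pix) == 1L) return(cbind(x = pix[, 2], y = pix[, 1]))
  key <- paste(pix[, 1], pix[, 2])
  inSet <- function(r, c) paste(r, c) %in% key
  nb <- rbind(cbind(pix[, 1] - 1L, pix[, 2]), cbind(pix[, 1] + 1L, pix[, 2]),
              cbind(pix[, 1], pix[, 2] - 1L), cbind(pix[, 1], pix[, 2] + 1L))
  inn <- matrix(paste(nb[, 1], nb[, 2]) %in% key, nrow = nrow(pix))
  isB <- !(inn[, 1] & inn[, 2] & inn[, 3] & inn[, 4])
  b <- pix[isB, , drop = FALSE]
  ctr <- colMeans(pix)
  ang <- atan2(b[, 1] - ctr[1], b[, 2] - ctr[2])
  o <- order(ang, b[, 1], b[, 2])
  cbind(x = b[o, 2], y = b[o, 1])
}

#' Extract contours from a label matrix
#'
#' One contour per label: its pixel set, area (pixel count), centroid (mean
#' pixel position) and traced outer boundary. When the deepest convexity
#' defect of the boundary exceeds `hullDefectDepth`, the boundary polygon is
#' replaced by the convex hull; the pixel set and area are left unchanged.
#'
#' @param labels integer H x W label matrix
#' @param classLabel class recorded for every contour
#' @param params a [ContourParams-class]
#' @param imageIndex index recorded in the result
#' @return a [ContourSet-class]
#' @export
extractContours <- function(labels, classLabel, params = contourParams(),
                            imageIndex = 1L) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L) return(.emptyContourSet(imageIndex))
  rc <- arrayInd(idx, dim(labels))
  lab <- labels[idx]
  o <- order(lab)
  rc <- rc[o, , drop = FALSE]
  lab <- lab[o]
  splits <- split(seq_len(nrow(rc)), lab)
  n <- length(splits)
  pixels <- vector("list", n)
  boundary <- vector("list", n)
  info <- data.frame(contourId = seq_len(n), classLabel = classLabel,
                     area = 0L, x = 0, y = 0, hullAdjusted = FALSE)
  for (k in seq_len(n)) {
    pix <- rc[splits[[k]], , drop = FALSE]
    colnames(pix) <- c("row", "col")
    pixels[[k]] <- pix
    info$area[k] <- nrow(pix)
    info$x[k] <- mean(pix[, 2])
    info$y[k] <- mean(pix[, 1])
    bnd <- .traceBoundary(pix)
    if (nrow(bnd) >= 3L) {
      hullIdx <- grDevices::chull(bnd[, 1], bnd[, 2])
      hull <- bnd[hullIdx, , drop = FALSE]
      depth <- max(.distToPolygon(bnd, hull))
      if (depth > params@hullDefectDepth) {
        bnd <- hull
        info$hullAdjusted[k] <- TRUE
      }
    }
    boundary[[k]] <- bnd
  }
  new("ContourSet", info = info, pixels = pixels, boundary = boundary,
      imageIndex = as.integer(imageIndex))
}

.emptyContourSet <- function(imageIndex = 1L) {
  new("ContourSet",
      info = data.frame(contourId = integer(), classLabel = character(),
                        area = integer(), x = numeric(), y = numeric(),
                        hullAdjusted = logical()),
      pixels = list(), boundary = list(), imageIndex = as.integer(imageIndex))
}

.subsetContourSet <- function(cset, keep) {
  info <- cset@info[keep, , drop = FALSE]
  if (nrow(info)) info$contourId <- seq_len(nrow(info))
  rownames(info) <- NULL
  new("ContourSet", info = info, pixels = cset@pixels[keep],
      boundary = cset@boundary[keep], imageIndex = cset@imageIndex)
}

#' Filter contours by minimum area
#'
#' Retains contours with `area >= minArea` (inclusive); removed contours are
#' treated as debris and reported in the `"debris"` attribute of the result.
#' The filter is idempotent and order-independent.
#'
#' @param contours a [ContourSet-class]
#' @param minArea area threshold, px^2 (130 for cells, 150 for NP clusters)
#' @return filtered [ContourSet-class] with attribute `"debris"`
#' @export
filterByArea <- function(contours, minArea) {
  if (minArea <= 0) stop("minArea must be > 0")
  keep <- contours@info$area >= minArea
  out <- .subsetContourSet(contours, keep)
  attr(out, "debris") <- contours@info[!keep, , drop = FALSE]
  out
}

#' Merge contour sets from parallel class passes
#'
#' The per-class passes run independently, so one physical object whose
#' colour satisfies two boundaries (e.g. a bright "dying" cell inside both
#' the live and the overlap interval) is detected twice. Contours from
#' different classes whose centroids lie within `mergeRadius` px are treated
#' as one object and resolved by class precedence
#' overlap > dead > live > eu_np > tb_np; non-conflicting contours pass
#' through unchanged and ids are reassigned uniquely.
#'
#' @param perClassSets list of [ContourSet-class] from the same image
#' @param mergeRadius centroid distance threshold, px
#' @return a single merged [ContourSet-class]
#' @export
resolveClassConflicts <- function(perClassSets, mergeRadius = 5) {
  perClassSets <- perClassSets[vapply(perClassSets, nContours, 1L) > 0]
  if (length(perClassSets) == 0L) return(.emptyContourSet())
  if (length(perClassSets) == 1L) {
    out <- perClassSets[[1]]
    out@info$contourId <- seq_len(nrow(out@info))
    return(out)
  }
  imageIndex <- perClassSets[[1]]@imageIndex
  info <- do.call(rbind, lapply(perClassSets, function(s) s@info))
  pixels <- do.call(c, lapply(perClassSets, function(s) s@pixels))
  boundary <- do.call(c, lapply(perClassSets, function(s) s@boundary))
  rank <- match(info$classLabel, .CLASS_PRECEDENCE)
  rank[is.na(rank)] <- length(.CLASS_PRECEDENCE) + 1L
  o <- order(rank, info$y, info$x)
  keep <- logical(nrow(info))
  for (i in o) {
    ki <- which(keep)
    conflict <- length(ki) > 0L &&
      any(info$classLabel[ki] != info$classLabel[i] &
          (info$x[ki] - info$x[i])^2 + (info$y[ki] - info$y[i])^2 <
            mergeRadius^2)
    if (!conflict) keep[i] <- TRUE
  }
  ki <- which(keep)
  ki <- ki[order(info$y[ki], info$x[ki])]
  info <- info[ki, , drop = FALSE]
  info$contourId <- seq_len(nrow(info))
  rownames(info) <- NULL
  new("ContourSet", info = info, pixels = pixels[ki],
      boundary = boundary[ki], imageIndex = imageIndex)
}

## ---------------------------------------------------------------------------
## Per-class detection pass
## ---------------------------------------------------------------------------

## full contour pass for one colour class
.detectClassContours <- function(img, boundary, params, imageIndex = 1L) {
  mask <- buildColorMask(img, boundary)
  if (!any(mask)) return(.emptyContourSet(imageIndex))
  g <- medianSmooth(.luminance(img@pixels, mask), 3L)
  edges <- cannyEdges(g, params@cannyTMin, params@cannyTMax)
  closed <- morphDilate(edges, params@morphKernel, params@dilateIters)
  closed <- morphErode(closed, params@morphKernel, params@erodeIters)
  filled <- EBImage::fillHull(closed * 1L) > 0L
  labels <- segmentTouching(filled, gray = g, params = params)
  ## class membership is defined by the colour mask: clip each label to it,
  ## then hand uncovered mask pixels to the nearest label (edge localization
  ## sits a pixel or two inside the mask after two smoothing passes)
  labels[!mask] <- 0L
  labels <- cpp_label_complete(labels, mask, 3L)
  extractContours(labels, boundary@classLabel, params, imageIndex)
}

#' Detect contours of several colour classes in one image
#'
#' Runs one detection pass per class (mask, masked grayscale, Canny,
#' dilation, erosion, interior fill, random-walker segmentation, contour
#' extraction), applies the class-specific area threshold (`minAreaCell`
#' for live/dead/overlap, `minAreaNp` for nanoparticle classes) and merges
#' the passes with [resolveClassConflicts()].
#'
#' @param img an [OverlayImage-class]
#' @param boundaries named list of [ColorBoundary-class]
#' @param params a [ContourParams-class]
#' @param imageIndex index recorded in the result
#' @return a [ContourSet-class]
#' @export
detectContours <- function(img, boundaries = defaultColorBoundaries(),
                           params = contourParams(), imageIndex = 1L) {
  sets <- lapply(boundaries, function(b) {
    cs <- .detectClassContours(img, b, params, imageIndex)
    minA <- if (b@classLabel %in% .NP_CLASSES) params@minAreaNp
            else params@minAreaCell
    filterByArea(cs, minA)
  })
  resolveClassConflicts(sets, params@mergeRadius)
}
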