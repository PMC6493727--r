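#' @include AllClasses.R intensity.R
NULL

#' Build a synthetic-scene specification
#'
#' The defaults emulate the imaged droplet trapping device: a hexagonal trap
#' lattice at 360 um spacing (1 um/px calibration), one trapped droplet per
#' site with radius drawn from 25-50 um, 0-3 cells per droplet with mean
#' rendered area ~140 px^2, nanoparticle clusters ~170 px^2, debris blobs
#' below 130 px^2, bright droplet rims on a dark brightfield-like background
#' and i.i.d. Gaussian read noise. The seed fully determines the scene.
#'
#' @param imageSize (H, W) px
#' @param micronsPerPixel um per px
#' @param trapSpacing,trapRadius,margin lattice geometry (um, um, px)
#' @param dropletRadiusRange droplet radius range, um
#' @param occupancyProbs probabilities of 0..3 cells per droplet
#' @param classMix named cell-class probabilities
#' @param npClasses,npMix nanoparticle classes and their mix
#' @param coEncapsulationRate probability a droplet carries NP cluster(s)
#' @param cellAreaMean,cellAreaSd,cellAreaMin cell area distribution, px^2
#' @param npAreaMean,npAreaSd,npAreaMin NP area distribution, px^2
#' @param debrisPerImage,debrisAreaRange debris rate and area range
#' @param freeCellsPerImage expected free-floating cells per image
#' @param cellIntensityRange,npIntensityRange 16-bit class-channel intensity
#' @param noiseSigma Gaussian noise sd, grey units
#' @param backgroundLevel,dropletInterior,rimIntensity grey levels
#' @param rimWidth rim half-width, px
#' @param seed integer
#' @return a [SceneSpec-class]
#' @export
sceneSpec <- function(imageSize = c(1500L, 2048L), micronsPerPixel = 1,
                      trapSpacing = 360, trapRadius = 35, margin = 100,
                      dropletRadiusRange = c(25, 50),
                      occupancyProbs = c(0.62, 0.27, 0.09, 0.02),
                      classMix = c(live = 0.55, dead = 0.35, overlap = 0.10),
                      npClasses = character(0), npMix = numeric(0),
                      coEncapsulationRate = 0,
                      cellAreaMean = 140, cellAreaSd = 6, cellAreaMin = 131,
                      npAreaMean = 170, npAreaSd = 8, npAreaMin = 151,
                      debrisPerImage = 3, debrisAreaRange = c(20, 110),
                      freeCellsPerImage = 1,
                      cellIntensityRange = c(16000, 60000),
                      npIntensityRange = c(42000, 60000),
                      noiseSigma = 400, backgroundLevel = 4000,
                      dropletInterior = 2500, rimIntensity = 9500,
                      rimWidth = 1.5, seed = 1L) {
  new("SceneSpec", imageSize = as.integer(imageSize),
      micronsPerPixel = micronsPerPixel, trapSpacing = trapSpacing,
      trapRadius = trapRadius, margin = margin,
      dropletRadiusRange = dropletRadiusRange,
      occupancyProbs = occupancyProbs, classMix = classMix,
      npClasses = npClasses, npMix = npMix,
      coEncapsulationRate = coEncapsulationRate,
      cellAreaMean = cellAreaMean, cellAreaSd = cellAreaSd,
      cellAreaMin = cellAreaMin, npAreaMean = npAreaMean,
      npAreaSd = npAreaSd, npAreaMin = npAreaMin,
      debrisPerImage = debrisPerImage, debrisAreaRange = debrisAreaRange,
      freeCellsPerImage = freeCellsPerImage,
      cellIntensityRange = cellIntensityRange,
      npIntensityRange = npIntensityRange, noiseSigma = noiseSigma,
      backgroundLevel = backgroundLevel, dropletInterior = dropletInterior,
      rimIntensity = rimIntensity, rimWidth = rimWidth,
      seed = as.integer(seed))
}

## colour vector (B, G, R) of a rendered object: mu is the intensity of the
## class's readout channel; the other channels sit mid-range inside the
## class boundary and safely outside every other class boundary
.classColor <- function(classLabel, mu) {
  switch(classLabel,
    live    = c(0.10 * mu, mu, 0.10 * mu),
    dead    = c(0.10 * mu, 0.10 * mu, mu),
    overlap = c(0.10 * mu, mu, mu),
    eu_np   = c(mu, 0.08 * mu, 0.85 * mu),
    tb_np   = c(mu, 0.12 * mu, 0.12 * mu),
    stop("no colour model for class ", classLabel))
}

## hexagonal trap lattice centres within the margins
.latticeCenters <- function(spec) {
  H <- spec@imageSize[1]; W <- spec@imageSize[2]
  sp <- spec@trapSpacing / spec@micronsPerPixel
  dy <- sp * sqrt(3) / 2
  ys <- seq(spec@margin, H - spec@margin, by = dy)
  out <- NULL
  for (j in seq_along(ys)) {
    x0 <- spec@margin + if (j %% 2 == 0) sp / 2 else 0
    xs <- seq(x0, W - spec@margin, by = sp)
    if (length(xs)) out <- rbind(out, cbind(x = xs, y = ys[j]))
  }
  round(out)
}

## rasterize an ellipse of target area `A` at the origin; returns relative
## (dr, dc) offsets. Areas are enforced against `minA`/`maxA` by rescaling.
.ellipsePixels <- function(A, minA = 1, maxA = Inf) {
  q <- runif(1, 0.75, 1.3)
  a <- sqrt(A * q / pi); b <- A / (pi * a)
  phi <- runif(1, 0, pi)
  for (iter in 1:25) {
    m <- ceiling(max(a, b)) + 1L
    d <- seq(-m, m)
    dc <- rep(d, each = length(d)); dr <- rep(d, times = length(d))
    u <- (dc * cos(phi) + dr * sin(phi)) / a
    v <- (-dc * sin(phi) + dr * cos(phi)) / b
    inside <- u * u + v * v <= 1
    n <- sum(inside)
    if (n < minA) { a <- a * 1.04; b <- b * 1.04; next }
    if (n > maxA) { a <- a * 0.96; b <- b * 0.96; next }
    return(cbind(dr = dr[inside], dc = dc[inside]))
  }
  cbind(dr = dr[inside], dc = dc[inside])
}

#' Render one synthetic trap-array scene with ground truth
#'
#' Deterministic given `spec@seed` and `imageIndex`: the same pair always
#' yields a bit-identical image and truth table.
#'
#' @param spec a [SceneSpec-class]
#' @param imageIndex index of the image within its set (enters the seed)
#' @return list with elements `image` ([OverlayImage-class]) and `truth`
#'   ([SceneTruth-class])
#' @export
generateScene <- function(spec, imageIndex = 1L) {
  set.seed((spec@seed * 1009L + as.integer(imageIndex)) %% 2147483647L)
  H <- spec@imageSize[1]; W <- spec@imageSize[2]
  ch <- list(B = matrix(spec@backgroundLevel, H, W),
             G = matrix(spec@backgroundLevel, H, W),
             R = matrix(spec@backgroundLevel, H, W))
  centers <- .latticeCenters(spec)
  if (is.null(centers) || nrow(centers) == 0L)
    stop("trap lattice does not fit the image")
  rr <- spec@dropletRadiusRange / spec@micronsPerPixel

  drops <- data.frame(dropletId = integer(), x = numeric(), y = numeric(),
                      radius = numeric())
  objects <- list()
  objId <- 0L

  paintGrey <- function(rows, cols, value) {
    idx <- rows + (cols - 1L) * H
    for (nm in names(ch)) ch[[nm]][idx] <<- value
  }
  paintColor <- function(rows, cols, bgr) {
    idx <- rows + (cols - 1L) * H
    ch$B[idx] <<- bgr[1]; ch$G[idx] <<- bgr[2]; ch$R[idx] <<- bgr[3]
  }

  placed <- list()   # per droplet: matrix of (x, y, effRad) for overlap checks
  bgPlaced <- matrix(numeric(), 0L, 3L)  # objects in the open channel

  ## droplets at the lattice sites
  for (i in seq_len(nrow(centers))) {
    Rd <- round(runif(1, rr[1], rr[2]))
    cx <- centers[i, "x"] + sample(-3:3, 1)
    cy <- centers[i, "y"] + sample(-3:3, 1)
    m <- ceiling(Rd + spec@rimWidth)
    rws <- pmax(1L, cy - m):pmin(H, cy + m)
    cls <- pmax(1L, cx - m):pmin(W, cx + m)
    d <- sqrt(outer((rws - cy)^2, (cls - cx)^2, `+`))
    interior <- which(d < Rd - spec@rimWidth, arr.ind = TRUE)
    rim <- which(abs(d - Rd) <= spec@rimWidth, arr.ind = TRUE)
    paintGrey(rws[interior[, 1]], cls[interior[, 2]], spec@dropletInterior)
    paintGrey(rws[rim[, 1]], cls[rim[, 2]], spec@rimIntensity)
    drops <- rbind(drops, data.frame(dropletId = i, x = cx, y = cy,
                                     radius = Rd))
    placed[[i]] <- matrix(numeric(), 0L, 3L)
  }

  ## place an object inside droplet `di` (or free/background when di = NA);
  ## returns TRUE when rendered
  addObject <- function(type, classLabel, area, minA, maxA, mu, di) {
    pix <- .ellipsePixels(area, minA, maxA)
    eff <- max(abs(pix)) + 1
    for (try in 1:40) {
      if (!is.na(di)) {
        maxR <- drops$radius[di] - spec@rimWidth - eff - 2
        if (maxR <= 0) return(FALSE)
        r <- sqrt(runif(1)) * maxR
        th <- runif(1, 0, 2 * pi)
        ox <- round(drops$x[di] + r * cos(th))
        oy <- round(drops$y[di] + r * sin(th))
        other <- placed[[di]]
      } else {
        ox <- round(runif(1, spec@margin / 2, W - spec@margin / 2))
        oy <- round(runif(1, spec@margin / 2, H - spec@margin / 2))
        dd <- sqrt((drops$x - ox)^2 + (drops$y - oy)^2)
        if (type == "debris") {
          ## debris may sit inside a droplet or in the open channel, but
          ## never across a rim
          j <- which(dd < drops$radius + spec@rimWidth + eff + 2)
          if (length(j) == 1L && dd[j] + eff < drops$radius[j] - spec@rimWidth - 1) {
            other <- placed[[j]]
          } else if (length(j) == 0L) {
            other <- bgPlaced
            j <- NA_integer_
          } else next
          di2 <- j
        } else {
          ## free-floating cells stay clear of every droplet
          if (any(dd < drops$radius + eff + 6)) next
          other <- bgPlaced
          di2 <- NA_integer_
        }
      }
      if (nrow(other) > 0L &&
          any(sqrt((other[, 1] - ox)^2 + (other[, 2] - oy)^2) <
              other[, 3] + eff + 4)) next
      rows <- oy + pix[, "dr"]; cols <- ox + pix[, "dc"]
      if (any(rows < 1L | rows > H | cols < 1L | cols > W)) next
      paintColor(rows, cols, .classColor(classLabel, mu))
      objId <<- objId + 1L
      holder <- if (!is.na(di)) di else if (type == "debris") di2 else NA_integer_
      if (!is.na(holder))
        placed[[holder]] <<- rbind(placed[[holder]], c(ox, oy, eff))
      else
        bgPlaced <<- rbind(bgPlaced, c(ox, oy, eff))
      objects[[objId]] <<- data.frame(
        objectId = objId, type = type, classLabel = classLabel,
        x = mean(cols), y = mean(rows), area = nrow(pix),
        dropletId = if (type == "debris") NA_integer_ else holder,
        trueMeanIntensity = mu)
      return(TRUE)
    }
    FALSE
  }

  ## cells and NP clusters per droplet
  for (i in seq_len(nrow(drops))) {
    nCells <- sample(0:3, 1, prob = spec@occupancyProbs)
    for (k in seq_len(nCells)) {
      cl <- sample(names(spec@classMix), 1, prob = spec@classMix)
      A <- max(spec@cellAreaMin, round(rnorm(1, spec@cellAreaMean,
                                             spec@cellAreaSd)))
      mu <- round(runif(1, spec@cellIntensityRange[1],
                        spec@cellIntensityRange[2]))
      addObject("cell", cl, A, spec@cellAreaMin, Inf, mu, i)
    }
    if (length(spec@npClasses) && runif(1) < spec@coEncapsulationRate) {
      nNp <- sample(1:2, 1, prob = c(0.7, 0.3))
      for (k in seq_len(nNp)) {
        cl <- sample(spec@npClasses, 1, prob = spec@npMix)
        A <- max(spec@npAreaMin, round(rnorm(1, spec@npAreaMean,
                                             spec@npAreaSd)))
        mu <- round(runif(1, spec@npIntensityRange[1],
                          spec@npIntensityRange[2]))
        addObject("np", cl, A, spec@npAreaMin, Inf, mu, i)
      }
    }
  }

  ## free-floating cells (excluded from population counts downstream)
  nFree <- stats::rpois(1, spec@freeCellsPerImage)
  for (k in seq_len(nFree)) {
    cl <- sample(names(spec@classMix), 1, prob = spec@classMix)
    A <- max(spec@cellAreaMin, round(rnorm(1, spec@cellAreaMean,
                                           spec@cellAreaSd)))
    mu <- round(runif(1, spec@cellIntensityRange[1],
                      spec@cellIntensityRange[2]))
    addObject("cell", cl, A, spec@cellAreaMin, Inf, mu, NA_integer_)
  }

  ## sub-threshold debris
  nDebris <- stats::rpois(1, spec@debrisPerImage)
  for (k in seq_len(nDebris)) {
    allCls <- c(names(spec@classMix), spec@npClasses)
    cl <- sample(allCls, 1)
    A <- round(runif(1, spec@debrisAreaRange[1], spec@debrisAreaRange[2]))
    mu <- round(runif(1, spec@cellIntensityRange[1],
                      spec@cellIntensityRange[2]))
    if (cl %in% .NP_CLASSES)
      mu <- round(runif(1, spec@npIntensityRange[1],
                        spec@npIntensityRange[2]))
    addObject("debris", cl, A, 1, 126, mu, NA_integer_)
  }

  ## assemble the 16-bit (B, G, R) array with read noise
  px <- array(0, c(H, W, 3L))
  px[, , 1L] <- ch$B; px[, , 2L] <- ch$G; px[, , 3L] <- ch$R
  if (spec@noiseSigma > 0)
    px <- px + rnorm(length(px), 0, spec@noiseSigma)
  px <- round(pmin(pmax(px, 0), 65535))
  storage.mode(px) <- "integer"
  img <- new("OverlayImage", pixels = px, sourcePath = "",
             bitDepthOriginal = 16L)

  objDf <- if (objId > 0L) do.call(rbind, objects) else
    data.frame(objectId = integer(), type = character(),
               classLabel = character(), x = numeric(), y = numeric(),
               area = integer(), dropletId = integer(),
               trueMeanIntensity = numeric())
  truth <- new("SceneTruth", droplets = drops, objects = objDf,
               imageIndex = as.integer(imageIndex))
  list(image = img, truth = truth)
}

#' Generate a seeded set of scenes, optionally writing TIFFs and truth CSVs
#'
#' @param spec a [SceneSpec-class]
#' @param nImages number of images
#' @param outDir if non-`NULL`, writes `scene_###.tiff` plus truth CSVs there
#' @param keepImages keep the rendered images in the returned list (set
#'   `FALSE` with `outDir` to bound memory)
#' @return list with `truths` (per image) and, if kept, `images`
#' @export
simulateBatch <- function(spec, nImages, outDir = NULL, keepImages = TRUE) {
  truths <- vector("list", nImages)
  images <- if (keepImages) vector("list", nImages) else NULL
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  for (i in seq_len(nImages)) {
    sc <- generateScene(spec, i)
    truths[[i]] <- sc$truth
    if (keepImages) images[[i]] <- sc$image
    if (!is.null(outDir)) {
      writeImage16(sc$image, file.path(outDir, sprintf("scene_%03d.tiff", i)))
      writeTruth(sc$truth, outDir, sprintf("scene_%03d", i))
    }
  }
  out <- list(truths = truths)
  if (keepImages) out$images <- images
  out
}

#' Write ground truth tables as CSV
#'
#' Produces `<prefix>_truth_droplets.csv` and `<prefix>_truth_objects.csv`,
#' mirroring the pipeline's output schemas for field-by-field comparison.
#'
#' @param truth a [SceneTruth-class]
#' @param dir output directory
#' @param prefix file name prefix
#' @return the two paths, invisibly
#' @export
writeTruth <- function(truth, dir, prefix = "scene") {
  p1 <- file.path(dir, paste0(prefix, "_truth_droplets.csv"))
  p2 <- file.path(dir, paste0(prefix, "_truth_objects.csv"))
  exportTable(truth@droplets, p1, "csv")
  exportTable(truth@objects, p2, "csv")
  invisible(c(p1, p2))
}

#' Read ground truth tables written by [writeTruth()]
#'
#' @param dir directory
#' @param prefix file name prefix
#' @param imageIndex index recorded in the result
#' @return a [SceneTruth-class]
#' @export
readTruth <- function(dir, prefix = "scene", imageIndex = 1L) {
  dr <- utils::read.csv(file.path(dir, paste0(prefix, "_truth_droplets.csv")))
  ob <- utils::read.csv(file.path(dir, paste0(prefix, "_truth_objects.csv")))
  new("SceneTruth", droplets = dr, objects = ob,
      imageIndex = as.integer(imageIndex))
}

## aggregate ground-truth population counts over a list of SceneTruth
.truthCounts <- function(truths) {
  counts <- c(droplets = 0, live = 0, dead = 0, overlap = 0,
              eu_np = 0, tb_np = 0, sce = 0, mce = 0, empty = 0,
              cellOnly = 0, npOnly = 0, coSc = 0, coMc = 0)
  for (tr in truths) {
    counts["droplets"] <- counts["droplets"] + nrow(tr@droplets)
    ob <- tr@objects
    enc <- ob[!is.na(ob$dropletId) & ob$type != "debris", , drop = FALSE]
    for (cl in c("live", "dead", "overlap", "eu_np", "tb_np"))
      counts[cl] <- counts[cl] + sum(enc$classLabel == cl)
    cellsPer <- table(factor(enc$dropletId[enc$type == "cell"],
                             levels = tr@droplets$dropletId))
    npPer <- table(factor(enc$dropletId[enc$type == "np"],
                          levels = tr@droplets$dropletId))
    counts["sce"] <- counts["sce"] + sum(cellsPer == 1)
    counts["mce"] <- counts["mce"] + sum(cellsPer >= 2)
    counts["empty"] <- counts["empty"] + sum(cellsPer == 0)
    counts["cellOnly"] <- counts["cellOnly"] + sum(cellsPer > 0 & npPer == 0)
    counts["npOnly"] <- counts["npOnly"] + sum(cellsPer == 0 & npPer > 0)
    counts["coSc"] <- counts["coSc"] + sum(cellsPer == 1 & npPer > 0)
    counts["coMc"] <- counts["coMc"] + sum(cellsPer >= 2 & npPer > 0)
  }
  counts
}

## aggregate pipeline population counts over per-image results
.autoCounts <- function(perImage) {
  counts <- c(droplets = 0, live = 0, dead = 0, overlap = 0,
              eu_np = 0, tb_np = 0, sce = 0, mce = 0, empty = 0,
              cellOnly = 0, npOnly = 0, coSc = 0, coMc = 0)
  for (res in perImage) {
    s <- res$encapsulation@summary
    counts["droplets"] <- counts["droplets"] + s$nDroplets
    counts["live"] <- counts["live"] + s$nLive
    counts["dead"] <- counts["dead"] + s$nDead
    counts["overlap"] <- counts["overlap"] + s$nOverlap
    counts["eu_np"] <- counts["eu_np"] + s$nEuNp
    counts["tb_np"] <- counts["tb_np"] + s$nTbNp
    counts["sce"] <- counts["sce"] + s$nSce
    counts["mce"] <- counts["mce"] + s$nMce
    counts["empty"] <- counts["empty"] + s$nEmpty
    sub <- subpopulationCounts(res$encapsulation)
    counts["cellOnly"] <- counts["cellOnly"] + sub$cellOnly
    counts["npOnly"] <- counts["npOnly"] + sub$npOnly
    counts["coSc"] <- counts["coSc"] + sub$coSc
    counts["coMc"] <- counts["coMc"] + sub$coMc
  }
  counts
}

#' Score pipeline output against synthetic ground truth
#'
#' Counts are compared per category as percent agreement
#' `100 * (1 - |auto - truth| / truth)` (100 when both are zero). Objects
#' are additionally matched per image by class and centroid distance
#' (greedy nearest within `matchRadius`), yielding per-class precision and
#' recall, and — for matched cells — the mean relative agreement of the
#' measured and true mean intensities.
#'
#' @param perImage list of per-image pipeline results (elements of
#'   `runPipeline(...)$perImage`)
#' @param truths list of [SceneTruth-class] of the same images
#' @param matchRadius centroid match radius, px
#' @return list with `countAgreement` (named percent vector), `counts`
#'   (auto vs truth), `precision`, `recall`, `intensitySimilarity` and
#'   `nMatched`
#' @export
scoreAgainstTruth <- function(perImage, truths, matchRadius = 5) {
  stopifnot(length(perImage) == length(truths))
  auto <- .autoCounts(perImage)
  truth <- .truthCounts(truths)
  agree <- ifelse(truth == 0, ifelse(auto == 0, 100, 0),
                  100 * (1 - abs(auto - truth) / truth))
  names(agree) <- names(truth)

  classes <- c(.CELL_CLASSES, .NP_CLASSES)
  tp <- fp <- fn <- structure(numeric(length(classes)), names = classes)
  intAgree <- numeric(0)
  for (i in seq_along(perImage)) {
    ci <- perImage[[i]]$contours@info
    it <- perImage[[i]]$intensity
    ob <- truths[[i]]@objects
    ob <- ob[ob$type != "debris", , drop = FALSE]
    for (cl in classes) {
      a <- ci[ci$classLabel == cl, , drop = FALSE]
      t2 <- ob[ob$classLabel == cl, , drop = FALSE]
      if (nrow(a) == 0L && nrow(t2) == 0L) next
      matched <- .greedyMatch(a[, c("x", "y")], t2[, c("x", "y")],
                              matchRadius)
      tp[cl] <- tp[cl] + nrow(matched)
      fp[cl] <- fp[cl] + nrow(a) - nrow(matched)
      fn[cl] <- fn[cl] + nrow(t2) - nrow(matched)
      if (nrow(matched) && cl %in% .CELL_CLASSES && nrow(it)) {
        am <- it$mean[match(a$contourId[matched[, 1]], it$contourId)]
        tm <- t2$trueMeanIntensity[matched[, 2]]
        intAgree <- c(intAgree, 100 * (1 - abs(am - tm) / tm))
      }
    }
  }
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  list(countAgreement = agree,
       counts = data.frame(category = names(truth), auto = as.numeric(auto),
                           truth = as.numeric(truth)),
       precision = precision, recall = recall,
       intensitySimilarity = if (length(intAgree)) mean(intAgree) else NA_real_,
       nMatched = length(intAgree))
}

## greedy nearest matching of two point sets within maxDist; returns a
## 2-column matrix of (index in a, index in b)
.greedyMatch <- function(a, b, maxDist) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(integer(), 0L, 2L))
  d <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  d[d > maxDist^2] <- NA
  out <- NULL
  while (any(!is.na(d))) {
    k <- arrayInd(which.min(d), dim(d))
    out <- rbind(out, k)
    d[k[1], ] <- NA
    d[, k[2]] <- NA
  }
  if (is.null(out)) matrix(integer(), 0L, 2L) else out
}

## ---------------------------------------------------------------------------
## Canonical benchmark conditions
## ---------------------------------------------------------------------------

#' Benchmark scene specifications
#'
#' Three ready-made [SceneSpec-class] configurations mirroring the assay
#' types the pipeline is built for, used by the validation suite:
#'
#' * `viabilitySceneSpec()` - live/dead/overlap ("dying") cells across a
#'   full trap lattice with sub-threshold debris and moderate read noise;
#'   a 28-image set holds ~780 droplets and ~400 encapsulated cells.
#' * `trackingSceneSpec()` - RFP-class cells co-encapsulated with Eu- and
#'   Tb-doped nanoparticle clusters (~170 px^2) at a co-encapsulation rate
#'   of 0.3, for droplet-tracking subpopulation tables.
#' * `uptakeSceneSpec()` - singly encapsulated live-boundary cells with
#'   known per-cell mean intensities and noise at ~3% of the mid-range
#'   signal, for intensity-recovery benchmarks.
#'
#' @param seed integer seed driving all randomness of the set
#' @return a [SceneSpec-class]
#' @export
viabilitySceneSpec <- function(seed = 1L) sceneSpec(seed = seed)

#' @rdname viabilitySceneSpec
#' @export
trackingSceneSpec <- function(seed = 1L)
  sceneSpec(classMix = c(dead = 1), npClasses = c("eu_np", "tb_np"),
            npMix = c(0.5, 0.5), coEncapsulationRate = 0.3, seed = seed)

#' @rdname viabilitySceneSpec
#' @export
uptakeSceneSpec <- function(seed = 1L)
  sceneSpec(occupancyProbs = c(0.4, 0.6, 0, 0), classMix = c(live = 1),
            noiseSigma = 1140, seed = seed)

#' Class boundaries matching a benchmark scene specification
#'
#' @param spec a [SceneSpec-class]
#' @return named list of [ColorBoundary-class] covering the classes the
#'   scene can contain
#' @export
sceneBoundaries <- function(spec) {
  defaultColorBoundaries()[c(names(spec@classMix), spec@npClasses)]
}
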