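mkImage <- function(px8) {
  ## build an OverlayImage from an 8-bit (B,G,R) array
  normalizeBitDepth(px8, 8)
}

test_that("colour mask membership is exactly the componentwise interval test", {
  b <- defaultColorBoundaries()
  onePix <- function(bgr) mkImage(array(as.integer(bgr), c(1L, 1L, 3L)))
  expect_true(buildColorMask(onePix(c(0, 255, 0)), b$live)[1, 1])
  expect_false(buildColorMask(onePix(c(0, 255, 255)), b$live)[1, 1])   # R too high
  for (cls in names(b))
    expect_false(buildColorMask(onePix(c(0, 0, 0)), b[[cls]])[1, 1])

  ## property: random pixels vs random boundaries
  set.seed(31)
  for (i in 1:30) {
    lo <- as.integer(sample(0:200, 3)); up <- lo + sample(0:55, 3)
    bd <- colorBoundary("custom", lo, up)
    px <- array(sample(0:255, 60, replace = TRUE), c(4L, 5L, 3L))
    img <- mkImage(px)
    want <- matrix(TRUE, 4, 5)
    for (ch in 1:3)
      want <- want & px[, , ch] >= lo[ch] & px[, , ch] <= up[ch]
    expect_identical(buildColorMask(img, bd), want)
  }
})

test_that("masked grayscale zeroes excluded pixels and is monotone in luminance", {
  img <- mkImage(array(100L, c(6L, 6L, 3L)))
  allOff <- matrix(FALSE, 6, 6)
  expect_identical(maskedGrayscale(img, allOff, 3L), matrix(0L, 6, 6))
  u <- normalizeBitDepth(array(1000L, c(6L, 6L, 3L)) / 257, 16)
  u@pixels[] <- 1000L
  expect_identical(maskedGrayscale(u, matrix(TRUE, 6, 6), 3L),
                   matrix(1000L, 6, 6))   # weights sum to 1
  ## monotone in the G channel
  px <- array(0L, c(3L, 3L, 3L))
  px[2, 1, 2] <- 1000L; px[2, 3, 2] <- 2000L
  g <- normalizeBitDepth(px, 16)
  lum <- fluorodroplet:::.luminance(g@pixels)
  expect_gt(lum[2, 3], lum[2, 1])
  expect_error(maskedGrayscale(img, matrix(TRUE, 2, 2)), "shape")
})

test_that("Canny finds a single thin line at a step edge and nothing elsewhere", {
  expect_false(any(cannyEdges(matrix(5000L, 16, 16))))
  step <- cbind(matrix(0L, 16, 8), matrix(40000L, 16, 8))
  e <- cannyEdges(step)
  expect_true(any(e))
  cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_lte(diff(range(cols)), 1)         # thin vertical line
  expect_identical(max(fluorodroplet:::cpp_label8(e)), 1L)
  expect_false(any(cannyEdges(step, tMin = 1e7, tMax = 2e7)))
  expect_error(cannyEdges(step, tMin = 10, tMax = 5), "tMin")
})

test_that("morphology matches the set-theoretic definition", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  d1 <- morphDilate(m, 3L)
  expect_identical(which(d1), which(bruteDilate(m, 3L)))
  expect_identical(sum(d1), 9L)
  expect_identical(morphErode(d1, 3L), m)   # erosion of the dilated point

  set.seed(13)
  for (i in 1:8) {
    mm <- matrix(runif(32 * 32) < 0.35, 32, 32)
    k <- sample(c(3L, 5L), 1)
    expect_identical(morphDilate(mm, k), bruteDilate(mm, k))
    expect_identical(morphErode(mm, k), bruteErode(mm, k))
  }
})

test_that("closing bridges small gaps in a circle outline so it fills", {
  m <- matrix(FALSE, 40, 40)
  th <- seq(0, 2 * pi, length.out = 200)
  m[cbind(round(20 + 12 * sin(th)), round(20 + 12 * cos(th)))] <- TRUE
  m[19:20, 31:33] <- FALSE                 # cut a 2 px gap in the outline
  ## the broken outline no longer encloses its interior
  expect_lt(sum(EBImage::fillHull(m * 1L) > 0), 150)
  closed <- morphErode(morphDilate(m, 3L), 3L)
  expect_identical(max(fluorodroplet:::cpp_label8(closed)), 1L)
  filled <- EBImage::fillHull(closed * 1L) > 0
  expect_gt(sum(filled), pi * 10^2)        # interior filled again
})

test_that("random-walker segmentation separates touching disks of equal size", {
  m <- drawDisk(matrix(FALSE, 40, 40), 20, 14, 8)
  m2 <- drawDisk(m, 20, 26, 8)
  lab <- segmentTouching(m2)
  expect_identical(max(lab), 2L)
  sizes <- tabulate(lab[lab > 0])
  oneDisk <- sum(drawDisk(matrix(FALSE, 40, 40), 20, 14, 8))
  expect_true(all(abs(sizes - oneDisk) / oneDisk <= 0.15))

  ## disjoint disks keep one label each; empty mask yields none
  disj <- drawDisk(drawDisk(matrix(FALSE, 60, 60), 15, 15, 8), 45, 45, 8)
  expect_identical(max(segmentTouching(disj)), 2L)
  expect_identical(max(segmentTouching(matrix(FALSE, 10, 10))), 0L)
})

test_that("segmentation label count equals object count under moderate overlap", {
  set.seed(17)
  for (rep in 1:5) {
    m <- matrix(FALSE, 80, 80)
    centers <- cbind(c(20, 20, 55), c(20, 38, 55))  # two touching + one free
    for (i in 1:3) m <- drawDisk(m, centers[i, 1], centers[i, 2], 9)
    expect_identical(max(segmentTouching(m)), 3L)
  }
})

test_that("contour extraction reports pixel sets, centroids and hull adjustment", {
  lab <- matrix(0L, 20, 20)
  lab[5:16, 4:15] <- 1L                    # 12x12 square
  cs <- extractContours(lab, "live", contourParams())
  expect_identical(nContours(cs), 1L)
  expect_identical(contourTable(cs)$area, 144L)
  expect_equal(contourTable(cs)$x, 9.5)
  expect_equal(contourTable(cs)$y, 10.5)
  expect_false(contourTable(cs)$hullAdjusted)

  ## crescent: deep concavity triggers hull replacement, area unchanged
  cres <- drawDisk(matrix(FALSE, 40, 40), 20, 20, 12) &
          !drawDisk(matrix(FALSE, 40, 40), 20, 26, 9)
  labC <- matrix(0L, 40, 40); labC[cres] <- 1L
  csC <- extractContours(labC, "live", contourParams(hullDefectDepth = 4))
  expect_true(contourTable(csC)$hullAdjusted)
  expect_identical(contourTable(csC)$area, sum(cres))
  bnd <- csC@boundary[[1]]
  hull <- grDevices::chull(bnd[, 1], bnd[, 2])
  expect_identical(nrow(bnd), length(hull))   # boundary is its own hull

  ## a convex disk is left alone
  disk <- drawDisk(matrix(FALSE, 30, 30), 15, 15, 9)
  labD <- matrix(0L, 30, 30); labD[disk] <- 1L
  expect_false(contourTable(extractContours(labD, "live",
                                            contourParams()))$hullAdjusted)
})

test_that("area filtering keeps >= threshold inclusively and is idempotent", {
  mkSet <- function(areas, cls = "live") {
    pix <- lapply(areas, function(a) cbind(row = rep(1L, a),
                                           col = seq_len(a)))
    info <- data.frame(contourId = seq_along(areas),
                       classLabel = rep(cls, length(areas)),
                       area = as.integer(areas),
                       x = vapply(pix, function(p) mean(p[, 2]), 1),
                       y = rep(1, length(areas)),
                       hullAdjusted = rep(FALSE, length(areas)))
    new("ContourSet", info = info, pixels = pix,
        boundary = lapply(pix, function(p) cbind(x = p[, 2], y = p[, 1])),
        imageIndex = 1L)
  }
  cells <- filterByArea(mkSet(c(100, 129, 130, 150)), 130)
  expect_identical(contourTable(cells)$area, c(130L, 150L))
  expect_identical(attr(cells, "debris")$area, c(100L, 129L))
  nps <- filterByArea(mkSet(c(149, 150, 170), "eu_np"), 150)
  expect_identical(contourTable(nps)$area, c(150L, 170L))
  expect_identical(nContours(filterByArea(mkSet(integer(0)), 130)), 0L)
  ## idempotent
  twice <- filterByArea(cells, 130)
  expect_identical(contourTable(twice)$area, contourTable(cells)$area)
})

test_that("class conflicts resolve by precedence; disjoint contours pass through", {
  mkOne <- function(cls, x, y, id = 1L) {
    pix <- cbind(row = rep(round(y), 140), col = round(x) + 0:139 %/% 10)
    info <- data.frame(contourId = id, classLabel = cls, area = 140L,
                       x = mean(pix[, 2]), y = y, hullAdjusted = FALSE)
    new("ContourSet", info = info, pixels = list(pix),
        boundary = list(cbind(x = pix[, 2], y = pix[, 1])), imageIndex = 1L)
  }
  ## same object seen by live and overlap passes -> overlap wins
  merged <- resolveClassConflicts(list(mkOne("live", 50, 30),
                                       mkOne("overlap", 51.5, 30)),
                                  mergeRadius = 5)
  expect_identical(nContours(merged), 1L)
  expect_identical(contourTable(merged)$classLabel, "overlap")

  ## far-apart live and dead contours both survive
  both <- resolveClassConflicts(list(mkOne("live", 30, 20),
                                     mkOne("dead", 130, 90)), 5)
  expect_identical(nContours(both), 2L)
  expect_setequal(contourTable(both)$classLabel, c("live", "dead"))
  expect_identical(contourTable(both)$contourId, 1:2)

  ## single class in, identity out
  one <- mkOne("dead", 40, 40)
  expect_identical(contourTable(resolveClassConflicts(list(one), 5)),
                   contourTable(one))
})

test_that("noiseless scene contours recover every cell class and exclude debris", {
  spec <- smallSceneSpec(seed = 6L, noiseSigma = 0,
                         occupancyProbs = c(0, 0.4, 0.4, 0.2),
                         debrisPerImage = 4)
  sc <- generateScene(spec, 1L)
  cs <- detectContours(sc$image, defaultColorBoundaries()[c("live", "dead",
                                                            "overlap")])
  ob <- sc$truth@objects
  cells <- ob[ob$type == "cell", ]
  expect_identical(nContours(cs), nrow(cells))
  found <- contourTable(cs)
  for (i in seq_len(nrow(cells))) {
    d <- sqrt((found$x - cells$x[i])^2 + (found$y - cells$y[i])^2)
    j <- which.min(d)
    expect_lte(d[j], 3)
    expect_identical(found$classLabel[j], cells$classLabel[i])
  }
})
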