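test_that("median smoothing matches a brute-force neighbourhood median", {
  expect_identical(medianSmooth(matrix(500L, 7, 7), 3L),
                   matrix(500L, 7, 7))
  m <- matrix(0L, 5, 5); m[3, 3] <- 65535L
  expect_identical(medianSmooth(m, 3L), matrix(0L, 5, 5))
  set.seed(7)
  for (k in c(3L, 5L)) {
    img <- matrix(sample.int(65536L, 81L) - 1L, 9, 9)
    expect_identical(medianSmooth(img, k), bruteMedian(img, k))
  }
  expect_error(medianSmooth(matrix(0L, 5, 5), 4L), "odd")
})

test_that("a blank image yields no droplets", {
  dm <- circularHough(matrix(4000L, 120, 120), dropletParams(rMinUm = 20,
                                                            rMaxUm = 40))
  expect_identical(nDroplets(dm), 0L)
})

test_that("single and double annuli are recovered with tight centre/radius error", {
  img <- drawAnnulus(matrix(4000L, 200, 200), cy = 100, cx = 100, R = 30)
  dm <- circularHough(medianSmooth(img, 3L), dropletParams())
  expect_identical(nDroplets(dm), 1L)
  d <- dropletTable(dm)
  expect_lte(sqrt((d$x - 100)^2 + (d$y - 100)^2), 2)
  expect_lte(abs(d$radius - 30), 1)

  img2 <- drawAnnulus(matrix(4000L, 260, 460), 130, 120, 28)
  img2 <- drawAnnulus(img2, 130, 320, 45)
  dm2 <- circularHough(medianSmooth(img2, 3L), dropletParams())
  expect_identical(nDroplets(dm2), 2L)
  d2 <- dropletTable(dm2)
  expect_equal(sort(d2$radius), c(28, 45), tolerance = 1/28)
})

test_that("the droplet count is always the length of the droplet table", {
  for (seed in 1:3) {
    sc <- generateScene(smallSceneSpec(seed), 1L)
    gray <- maskedGrayscale(sc$image, NULL, 3L)
    dm <- deduplicateTraps(circularHough(gray, dropletParams()))
    expect_identical(nDroplets(dm), nrow(dropletTable(dm)))
  }
})

test_that("CHT agrees with an exhaustive accumulator oracle on small frames", {
  set.seed(42)
  cases <- list(
    list(circ = cbind(cy = 32, cx = 30, R = 11)),
    list(circ = cbind(cy = c(20, 44), cx = c(20, 44), R = c(10, 12))),
    list(circ = cbind(cy = c(16, 16, 48), cx = c(16, 48, 48), R = c(9, 10, 11))))
  params <- dropletParams(rMinUm = 8, rMaxUm = 14)
  for (cs in cases) {
    img <- matrix(4000L, 64, 64)
    for (i in seq_len(nrow(cs$circ)))
      img <- drawAnnulus(img, cs$circ[i, "cy"], cs$circ[i, "cx"],
                         cs$circ[i, "R"], rim = 1)
    sm <- medianSmooth(img, 3L)
    e <- fluorodroplet:::.gradientEdges(sm)
    fast <- dropletTable(circularHough(sm, params))
    slow <- oracleCht(e$edges, e$gx, e$gy, 8:14, 0.4, minDist = 16)
    expect_identical(nrow(fast), nrow(slow))
    if (nrow(fast)) {
      expect_identical(fast$x, slow$col + 1L)
      expect_identical(fast$y, slow$row + 1L)
      expect_identical(fast$radius, as.integer(slow$radius))
      expect_identical(fast$votes, as.integer(slow$votes))
    }
  }
})

test_that("detection is translation-equivariant within a pixel", {
  base <- matrix(4000L, 220, 220)
  img1 <- drawAnnulus(base, 90, 95, 32)
  img2 <- drawAnnulus(base, 90 + 7, 95 + 11, 32)
  d1 <- dropletTable(circularHough(medianSmooth(img1, 3L)))
  d2 <- dropletTable(circularHough(medianSmooth(img2, 3L)))
  expect_identical(nrow(d1), 1L)
  expect_identical(nrow(d2), 1L)
  expect_lte(abs(d2$x - d1$x - 11), 1)
  expect_lte(abs(d2$y - d1$y - 7), 1)
})

test_that("noiseless lattices of 1, 9 and 36 droplets are recovered exactly", {
  sizes <- list(`1` = c(300L, 300L), `9` = c(830L, 1120L),
                `36` = c(1760L, 2180L))
  for (n in names(sizes)) {
    spec <- sceneSpec(imageSize = sizes[[n]], noiseSigma = 0,
                      debrisPerImage = 0, freeCellsPerImage = 0,
                      seed = 5L)
    sc <- generateScene(spec, 1L)
    expect_identical(nrow(sc$truth@droplets), as.integer(n))
    gray <- maskedGrayscale(sc$image, NULL, 3L)
    dm <- deduplicateTraps(circularHough(gray, dropletParams()))
    expect_identical(nDroplets(dm), as.integer(n))
    ## every detection sits on a distinct true droplet
    d <- dropletTable(dm); tr <- sc$truth@droplets
    dist <- outer(d$y, tr$y, `-`)^2 + outer(d$x, tr$x, `-`)^2
    expect_true(all(apply(dist, 1, min) <= 4))
    expect_identical(anyDuplicated(apply(dist, 1, which.min)), 0L)
  }
})

test_that("CHT beats naive single-threshold edge counting on low-contrast speckled scenes", {
  ## two droplets, one at low rim contrast, plus speckle clumps whose edge
  ## strength matches the faint rim: any single threshold keeping the faint
  ## rim keeps the speckle too, and any threshold dropping the speckle
  ## drops the rim
  set.seed(9)
  img <- matrix(4000L, 300, 520)
  img <- drawAnnulus(img, 150, 130, 40)                      # full contrast
  img <- drawAnnulus(img, 150, 380, 40, rimVal = 6000L,
                     interiorVal = 4000L)                     # low contrast
  for (i in 1:120) {                                          # 3x3 speckle
    r <- sample(4:296, 1); c <- sample(4:516, 1)
    img[r:(r + 2), c:(c + 2)] <- img[r:(r + 2), c:(c + 2)] + 2500L
  }
  sm <- medianSmooth(img, 3L)
  dm <- deduplicateTraps(circularHough(sm, dropletParams()))
  expect_identical(nDroplets(dm), 2L)
  d <- dropletTable(dm)
  expect_true(all(abs(d$radius - 40) <= 2))
  expect_setequal(round(d$x / 10) * 10, c(130, 380))

  ## naive detector: one global gradient threshold; components (> 10 px)
  ## within 45 px of a true centre count as that droplet, the rest are
  ## false positives. No threshold recovers both droplets without false
  ## positives, because the speckle edges are as strong as the faint rim.
  g <- fluorodroplet:::cpp_sobel(matrix(as.numeric(sm), nrow(sm), ncol(sm)))
  mag <- sqrt(g$gx^2 + g$gy^2)
  naiveOk <- vapply(c(1000, 2000, 4000, 6000, 9000, 12000, 15000, 30000),
                    function(threshold) {
    lab <- fluorodroplet:::cpp_label8(mag >= threshold)
    sz <- tabulate(lab[lab > 0])
    hitA <- hitB <- FALSE; false <- 0L
    for (k in which(sz > 10)) {
      pix <- which(lab == k, arr.ind = TRUE)
      ctr <- colMeans(pix)
      dA <- sqrt((ctr[1] - 150)^2 + (ctr[2] - 130)^2)
      dB <- sqrt((ctr[1] - 150)^2 + (ctr[2] - 380)^2)
      if (dA <= 45) hitA <- TRUE
      else if (dB <= 45) hitB <- TRUE
      else false <- false + 1L
    }
    hitA && hitB && false == 0L
  }, TRUE)
  expect_false(any(naiveOk))
})

test_that("trap deduplication keeps the highest-vote detection per trap", {
  mk <- function(df) new("DropletMap", droplets = df, imageIndex = 1L)
  two <- data.frame(dropletId = 1:2, x = c(100, 115), y = c(100, 110),
                    radius = c(30L, 32L), votes = c(120L, 90L))
  out <- dropletTable(deduplicateTraps(mk(two), dropletParams()))
  expect_identical(nrow(out), 1L)
  expect_identical(out$votes, 120L)

  apart <- data.frame(dropletId = 1:2, x = c(100, 460), y = c(100, 100),
                      radius = c(30L, 40L), votes = c(120L, 90L))
  expect_identical(nrow(dropletTable(deduplicateTraps(mk(apart),
                                                      dropletParams()))), 2L)

  one <- mk(two[1, ])
  expect_identical(dropletTable(deduplicateTraps(one, dropletParams())),
                   dropletTable(one))

  ## lattice validation reports but never removes
  off <- data.frame(dropletId = 1:2, x = c(100, 300), y = c(100, 100),
                    radius = c(30L, 30L), votes = c(100L, 100L))
  expect_message(
    out2 <- deduplicateTraps(mk(off), dropletParams(latticeValidation = TRUE)),
    "off the trap lattice")
  expect_identical(nDroplets(out2), 2L)
})
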