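test_that("intensity statistics match closed forms", {
  g <- matrix(1000L, 10, 10)
  pix <- cbind(row = rep(2:5, each = 4), col = rep(2:5, 4))
  s <- contourIntensityStats(g, pix)
  expect_equal(unlist(s[c("mean", "min", "max", "variance")]),
               c(mean = 1000, min = 1000, max = 1000, variance = 0))

  g2 <- matrix(0L, 4, 4)
  g2[1, 1:2] <- 0L; g2[2, 1:2] <- 100L
  pix4 <- cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  s2 <- contourIntensityStats(g2, pix4)
  expect_equal(s2$mean, 50)
  expect_equal(s2$min, 0)
  expect_equal(s2$max, 100)
  expect_equal(s2$variance, 2500)             # population variance
  s2b <- contourIntensityStats(g2, pix4, "sample")
  expect_equal(s2b$variance, 2500 * 4 / 3)

  expect_error(contourIntensityStats(g, pix[0, , drop = FALSE]), "empty")
  expect_error(contourIntensityStats(g, cbind(11, 1)), "outside")
})

test_that("variance matches a two-pass oracle to 1e-6 relative", {
  set.seed(41)
  g <- matrix(sample.int(65536L, 400L, replace = TRUE) - 1L, 20, 20)
  pix <- which(matrix(runif(400) < 0.4, 20, 20), arr.ind = TRUE)
  s <- contourIntensityStats(g, pix)
  v <- as.numeric(g[pix])
  twoPass <- sum((v - sum(v) / length(v))^2) / length(v)
  expect_equal(s$variance, twoPass, tolerance = 1e-6)
  expect_true(s$min <= s$mean && s$mean <= s$max)
})

test_that("background is the droplet-interior median with a whole-image fallback", {
  g <- matrix(400L, 120, 120)
  dm <- new("DropletMap",
            droplets = data.frame(dropletId = 1L, x = 60, y = 60,
                                  radius = 40L, votes = 100L),
            imageIndex = 1L)
  pix <- cbind(row = rep(55:64, each = 10), col = rep(55:64, 10))
  g[pix] <- 2000L
  cs <- new("ContourSet",
            info = data.frame(contourId = 1L, classLabel = "live",
                              area = 100L, x = 59.5, y = 59.5,
                              hullAdjusted = FALSE),
            pixels = list(pix),
            boundary = list(cbind(x = pix[, 2], y = pix[, 1])),
            imageIndex = 1L)
  bg <- estimateBackground(g, dm, cs)
  expect_equal(bg$backgroundLevel, 400)
  expect_match(bg$method, "droplet-interior")

  noDrops <- new("DropletMap",
                 droplets = dm@droplets[0, ], imageIndex = 1L)
  g2 <- matrix(250L, 20, 20)
  pixIn <- cbind(row = 3:6, col = 3:6)
  g2[pixIn] <- 5000L
  csIn <- new("ContourSet",
              info = data.frame(contourId = 1L, classLabel = "live",
                                area = 4L, x = 4.5, y = 4.5,
                                hullAdjusted = FALSE),
              pixels = list(pixIn),
              boundary = list(cbind(x = pixIn[, 2], y = pixIn[, 1])),
              imageIndex = 1L)
  bg2 <- estimateBackground(g2, noDrops, csIn)
  expect_equal(bg2$backgroundLevel, 250)
  expect_match(bg2$method, "whole-image")
})

test_that("normalization is a ratio by default and scale-equivariant", {
  rec <- data.frame(nPixels = 10L, mean = 1000, min = 900, max = 1100,
                    variance = 100)
  bg <- list(backgroundLevel = 500, method = "t", nPixelsUsed = 10L)
  expect_equal(normalizeIntensity(rec, bg)$normalizedMean, 2)
  expect_equal(normalizeIntensity(transform(rec, mean = 500),
                                  bg)$normalizedMean, 1)
  expect_equal(normalizeIntensity(transform(rec, mean = 742),
                                  list(backgroundLevel = 371))$normalizedMean,
               2)
  expect_equal(normalizeIntensity(rec, bg, "subtract")$normalizedMean, 500)
  expect_error(normalizeIntensity(rec, list(backgroundLevel = 0)),
               "noise floor")
  ## multiplying image and background by k leaves the ratio unchanged
  k <- 7
  expect_equal(normalizeIntensity(transform(rec, mean = rec$mean * k),
                                  list(backgroundLevel = 500 * k))$normalizedMean,
               2)
})

test_that("the 8-bit-binned histogram conserves counts and bin edges", {
  g <- matrix(0L, 5, 5)
  pixAll <- which(matrix(TRUE, 5, 5), arr.ind = TRUE)
  h <- intensityHistogram(g, pixAll)
  expect_identical(sum(h$counts), 25L)
  expect_identical(h$counts[1], 25L)

  g2 <- matrix(c(0L, 65535L), 1, 2)
  h2 <- intensityHistogram(g2, cbind(row = c(1, 1), col = c(1, 2)))
  expect_identical(h2$counts[c(1, 256)], c(1L, 1L))
  expect_identical(sum(h2$counts), 2L)
  expect_length(h2$breaks, 257L)

  set.seed(3)
  g3 <- matrix(sample.int(65536L, 64L) - 1L, 8, 8)
  pix <- which(matrix(runif(64) < 0.6, 8, 8), arr.ind = TRUE)
  h3 <- intensityHistogram(g3, pix)
  expect_identical(sum(h3$counts), nrow(pix))
  expect_equal(h3$stats$variance,
               contourIntensityStats(g3, pix)$variance)
})

test_that("rendered cell means are recovered within sampling error", {
  ## mean estimate within 3*sigma/sqrt(n) of the true mean for >=95% of cells
  spec <- uptakeSceneSpec(seed = 8L)
  ok <- 0L; tot <- 0L
  cfg <- runConfig(boundaries = sceneBoundaries(spec), logLevel = "quiet")
  for (i in 1:3) {
    sc <- generateScene(spec, i)
    res <- analyzeImage(sc$image, cfg, i)
    it <- res$intensity
    truth <- sc$truth@objects
    truth <- truth[truth$type == "cell", ]
    for (j in seq_len(nrow(truth))) {
      d <- sqrt((res$contours@info$x - truth$x[j])^2 +
                (res$contours@info$y - truth$y[j])^2)
      k <- which.min(d)
      if (length(k) == 0L || d[k] > 5) next
      tot <- tot + 1L
      tol <- 3 * spec@noiseSigma / sqrt(it$nPixels[k])
      if (abs(it$mean[k] - truth$trueMeanIntensity[j]) <= tol + 1)
        ok <- ok + 1L
    }
  }
  expect_gte(tot, 30L)
  expect_gte(ok / tot, 0.95)
})
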