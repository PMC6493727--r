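## build a DropletMap and ContourSet directly for assignment-rule tests
mkDroplets <- function(x, y, radius) {
  new("DropletMap",
      droplets = data.frame(dropletId = seq_along(x), x = x, y = y,
                            radius = radius,
                            votes = rep(100L, length(x))),
      imageIndex = 1L)
}

mkContours <- function(x, y, cls) {
  n <- length(x)
  pix <- lapply(seq_len(n), function(i)
    cbind(row = round(y[i]) + rep(0:13, each = 10),
          col = round(x[i]) + rep(0:9, 14)))
  info <- data.frame(contourId = seq_len(n), classLabel = cls,
                     area = rep(140L, n), x = x, y = y,
                     hullAdjusted = rep(FALSE, n))
  new("ContourSet", info = info, pixels = pix,
      boundary = lapply(pix, function(p) cbind(x = p[, 2], y = p[, 1])),
      imageIndex = 1L)
}

test_that("contours are assigned by the droplet-radius scan with nearest-centre ties", {
  dm <- mkDroplets(x = c(100, 150), y = c(100, 100), radius = c(30, 30))
  ## inside the first droplet
  r1 <- assignContoursToDroplets(dm, mkContours(110, 100, "live"))
  expect_identical(r1@assignments$dropletId, 1L)
  ## 60 px from every centre with radii <= 50: free-floating
  r2 <- assignContoursToDroplets(dm, mkContours(100, 170, "live"))
  expect_true(is.na(r2@assignments$dropletId))
  ## equidistant between the two -> lower dropletId wins
  r3 <- assignContoursToDroplets(dm, mkContours(125, 100, "dead"))
  expect_identical(r3@assignments$dropletId, 1L)
})

test_that("occupancy counts cells only and NP-only droplets stay empty", {
  dm <- mkDroplets(c(100, 300, 500), c(100, 100, 100), c(40, 40, 40))
  cs <- mkContours(x = c(95, 300, 310, 505), y = c(100, 95, 105, 100),
                   cls = c("live", "live", "dead", "eu_np"))
  res <- classifyOccupancy(assignContoursToDroplets(dm, cs))
  rec <- res@records
  expect_identical(rec$occupancy, c("single_cell", "multi_cell", "empty"))
  expect_identical(rec$tracked, c(FALSE, FALSE, FALSE))
  s <- occupancySummary(res)
  expect_identical(s$nDroplets, 3L)
  expect_identical(s$nEmpty + s$nSce + s$nMce, s$nDroplets)
  expect_identical(s$nEuNp, 1L)
  expect_equal(s$viability, 2 / 3)
})

test_that("co-encapsulation table flags tracked droplets", {
  dm <- mkDroplets(c(100, 300, 500), c(100, 100, 100), c(40, 40, 40))
  cs <- mkContours(x = c(95, 110, 300, 310), y = c(100, 100, 100, 100),
                   cls = c("dead", "eu_np", "live", "dead"))
  res <- classifyOccupancy(assignContoursToDroplets(dm, cs))
  tab <- coEncapsulationTable(res)
  expect_identical(tab$tracked, c(TRUE, FALSE, FALSE))   # cell+NP, 2 cells+0 NP, empty
  expect_identical(tab$occupancy[3], "empty")
  expect_true(all(tab[3, c("nLive", "nDead", "nOverlap", "nEuNp",
                           "nTbNp")] == 0))
  sub <- subpopulationCounts(res)
  expect_identical(sub$coSc, 1L)
  expect_identical(sub$cellOnly, 1L)
  expect_identical(sub$empty, 1L)
})

test_that("assignment conserves contours and is invariant to droplet order", {
  set.seed(23)
  for (rep in 1:6) {
    nd <- sample(2:5, 1); nc <- sample(0:8, 1)
    dm <- mkDroplets(x = runif(nd, 50, 950), y = runif(nd, 50, 450),
                     radius = sample(25:50, nd, replace = TRUE))
    cls <- sample(c("live", "dead", "overlap", "eu_np"), max(nc, 1),
                  replace = TRUE)[seq_len(nc)]
    cs <- mkContours(x = runif(nc, 30, 970), y = runif(nc, 30, 470),
                     cls = cls)
    res <- classifyOccupancy(assignContoursToDroplets(dm, cs))
    s <- occupancySummary(res)
    expect_identical(s$nEmpty + s$nSce + s$nMce, s$nDroplets)
    assigned <- sum(!is.na(res@assignments$dropletId))
    expect_identical(assigned + s$nFreeContours, nc)

    ## shuffle droplet rows: ids are reassigned deterministically from the
    ## centre order, so per-contour droplet assignment must not change
    perm <- sample(nd)
    dd <- dm@droplets[perm, ]
    dd$dropletId <- seq_len(nd)   # ids as a fresh detector would assign
    o <- order(dd$y, dd$x)
    dd <- dd[o, ]; dd$dropletId <- seq_len(nd); rownames(dd) <- NULL
    dm2 <- new("DropletMap", droplets = dd, imageIndex = 1L)
    res2 <- classifyOccupancy(assignContoursToDroplets(dm2, cs))
    key1 <- paste(round(dm@droplets$x[match(res@assignments$dropletId,
                                            dm@droplets$dropletId)]),
                  round(dm@droplets$y[match(res@assignments$dropletId,
                                            dm@droplets$dropletId)]))
    key2 <- paste(round(dm2@droplets$x[match(res2@assignments$dropletId,
                                             dm2@droplets$dropletId)]),
                  round(dm2@droplets$y[match(res2@assignments$dropletId,
                                             dm2@droplets$dropletId)]))
    expect_identical(key1, key2)
  }
})

test_that("occupancy table equals ground truth on a noiseless scene", {
  spec <- smallSceneSpec(seed = 14L, noiseSigma = 0)
  sc <- generateScene(spec, 1L)
  cfg <- runConfig(boundaries = defaultColorBoundaries()[c("live", "dead",
                                                           "overlap")],
                   logLevel = "quiet")
  res <- analyzeImage(sc$image, cfg, 1L)
  sco <- scoreAgainstTruth(list(res), list(sc$truth))
  expect_true(all(sco$countAgreement == 100))
})
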