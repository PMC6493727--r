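#' @include AllClasses.R encapsulation.R
NULL

## channel used for intensity quantification per class: uptake readouts are
## single-channel, so each class maps to its dominant fluorescence channel
.DEFAULT_CLASS_CHANNELS <- c(live = "G", dead = "R", overlap = "G",
                             eu_np = "B", tb_np = "B")

#' Single-channel 16-bit grayscale of an overlay image
#'
#' @param img an [OverlayImage-class]
#' @param channel "B", "G", "R" or "luminance"
#' @return integer H x W matrix
#' @export
channelGrayscale <- function(img, channel = c("G", "B", "R", "luminance")) {
  channel <- match.arg(channel)
  if (channel == "luminance") return(.luminance(img@pixels))
  ch <- match(channel, c("B", "G", "R"))
  g <- img@pixels[, , ch]
  storage.mode(g) <- "integer"
  g
}

#' Intensity statistics within one contour
#'
#' Mean, minimum, maximum and variance of the 16-bit grayscale over the
#' contour's pixel set. The variance is the population variance (divide by
#' n) by default; sample variance is available for comparison with tools
#' that use n - 1.
#'
#' @param gray16 integer H x W grayscale matrix
#' @param pixels 2-column (row, col) matrix, the contour's pixel set
#' @param varianceMode "population" or "sample"
#' @return one-row data.frame `nPixels, mean, min, max, variance`
#' @export
contourIntensityStats <- function(gray16, pixels,
                                  varianceMode = c("population", "sample")) {
  varianceMode <- match.arg(varianceMode)
  if (is.null(dim(pixels)) || nrow(pixels) == 0L)
    stop("contour pixel set is empty")
  if (any(pixels[, 1] < 1L) || any(pixels[, 1] > nrow(gray16)) ||
      any(pixels[, 2] < 1L) || any(pixels[, 2] > ncol(gray16)))
    stop("contour pixels outside the image")
  v <- as.numeric(gray16[pixels[, 1] + (pixels[, 2] - 1L) * nrow(gray16)])
  n <- length(v)
  mu <- mean(v)
  va <- sum((v - mu)^2) / if (varianceMode == "population") n else max(1L, n - 1L)
  data.frame(nPixels = n, mean = mu, min = min(v), max = max(v),
             variance = va)
}

#' Estimate the image background level
#'
#' The background is the median grey value of pixels lying inside detected
#' droplets but outside every contour pixel set (the droplet carrier fluid).
#' When no droplet was detected it falls back to the median over all
#' non-contour pixels.
#'
#' @param gray16 integer H x W grayscale matrix
#' @param droplets a [DropletMap-class]
#' @param contours a [ContourSet-class]
#' @return list `backgroundLevel, method, nPixelsUsed`
#' @export
estimateBackground <- function(gray16, droplets, contours) {
  H <- nrow(gray16); W <- ncol(gray16)
  inContour <- matrix(FALSE, H, W)
  for (pix in contours@pixels)
    inContour[pix[, 1] + (pix[, 2] - 1L) * H] <- TRUE
  dd <- droplets@droplets
  if (nrow(dd) > 0L) {
    sel <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(dd))) {
      r0 <- max(1L, floor(dd$y[i] - dd$radius[i]))
      r1 <- min(H, ceiling(dd$y[i] + dd$radius[i]))
      c0 <- max(1L, floor(dd$x[i] - dd$radius[i]))
      c1 <- min(W, ceiling(dd$x[i] + dd$radius[i]))
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - dd$y[i])^2, (cc - dd$x[i])^2, `+`)
      sel[rr, cc] <- sel[rr, cc] | d2 <= dd$radius[i]^2
    }
    eligible <- sel & !inContour
    method <- "droplet-interior median"
  } else {
    eligible <- !inContour
    method <- "whole-image non-contour median"
  }
  if (!any(eligible)) stop("no eligible background pixels")
  list(backgroundLevel = stats::median(as.numeric(gray16[eligible])),
       method = method, nPixelsUsed = sum(eligible))
}

#' Background-normalize an intensity record
#'
#' The default is a ratio (`mean / backgroundLevel`), so scaling the whole
#' image leaves the normalized mean unchanged; subtraction
#' (`mean - backgroundLevel`) is available as an alternative convention.
#'
#' @param record data.frame with a `mean` column (see
#'   [contourIntensityStats()])
#' @param background list from [estimateBackground()]
#' @param method "ratio" or "subtract"
#' @return `record` with `background` and `normalizedMean` columns added
#' @export
normalizeIntensity <- function(record, background,
                               method = c("ratio", "subtract")) {
  method <- match.arg(method)
  bg <- background$backgroundLevel
  if (method == "ratio" && bg <= 0)
    stop("background level is 0; configure a noise floor before ",
         "ratio normalization")
  record$background <- bg
  record$normalizedMean <- if (method == "ratio") record$mean / bg
                           else record$mean - bg
  record
}

#' 8-bit-binned histogram of a contour's 16-bit intensities
#'
#' 256 uniform bins over `[0, 65535]` (the 8-bit binning of the 16-bit
#' range); counts sum to the contour pixel count. The annotation carries
#' the 16-bit min / max / variance so the histogram can be mapped back to
#' the full scale.
#'
#' @param gray16 integer H x W grayscale matrix
#' @param pixels 2-column (row, col) matrix
#' @return list `counts` (length 256), `breaks` (length 257), `stats`
#' @export
intensityHistogram <- function(gray16, pixels) {
  stats <- contourIntensityStats(gray16, pixels)
  v <- gray16[pixels[, 1] + (pixels[, 2] - 1L) * nrow(gray16)]
  bin <- pmin(255L, v %/% 256L)
  counts <- tabulate(bin + 1L, nbins = 256L)
  list(counts = counts, breaks = seq(0, 65536, by = 256), stats = stats)
}

#' Intensity table for all contours of one image
#'
#' Runs [contourIntensityStats()] on every contour (on its class-specific
#' fluorescence channel), estimates the background once per channel and
#' normalizes. Droplet assignment comes from `result`; free-floating
#' contours carry `dropletId = NA`.
#'
#' @param img an [OverlayImage-class]
#' @param contours a [ContourSet-class]
#' @param result a classified [EncapsulationResult-class]
#' @param droplets the [DropletMap-class] used for background estimation
#' @param classChannels named character mapping class -> channel
#' @param normalization "ratio" or "subtract"
#' @param varianceMode "population" or "sample"
#' @return data.frame, one row per contour
#' @export
intensityTable <- function(img, contours, result, droplets,
                           classChannels = .DEFAULT_CLASS_CHANNELS,
                           normalization = "ratio",
                           varianceMode = "population") {
  n <- nContours(contours)
  if (n == 0L)
    return(data.frame(contourId = integer(), image = integer(),
                      classLabel = character(), dropletId = integer(),
                      nPixels = integer(), mean = numeric(), min = numeric(),
                      max = numeric(), variance = numeric(),
                      background = numeric(), normalizedMean = numeric()))
  info <- contours@info
  chans <- classChannels[info$classLabel]
  chans[is.na(chans)] <- "luminance"
  rows <- vector("list", n)
  bgCache <- list()
  for (i in seq_len(n)) {
    ch <- chans[i]
    if (is.null(bgCache[[ch]])) {
      g <- channelGrayscale(img, ch)
      bgCache[[ch]] <- list(gray = g,
                            bg = estimateBackground(g, droplets, contours))
    }
    g <- bgCache[[ch]]$gray
    rec <- contourIntensityStats(g, contours@pixels[[i]], varianceMode)
    rec <- normalizeIntensity(rec, bgCache[[ch]]$bg, normalization)
    rows[[i]] <- cbind(contourId = info$contourId[i],
                       image = contours@imageIndex,
                       classLabel = info$classLabel[i],
                       dropletId = result@assignments$dropletId[i], rec)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
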