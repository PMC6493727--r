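## Brute-force reference implementations, kept deliberately naive and
## independent of the package's compiled kernels.

## k x k neighbourhood median with edge replication, direct per pixel
bruteMedian <- function(img, k) {
  h <- k %/% 2L
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      rr <- pmin(pmax(r + (-h:h), 1L), H)
      cc <- pmin(pmax(c + (-h:h), 1L), W)
      out[r, c] <- median(img[rr, cc])
    }
  }
  out
}

## set-theoretic Minkowski dilation/erosion with a k x k box; pixels
## outside the image are background
bruteDilate <- function(mask, k, iters = 1L) {
  h <- k %/% 2L
  for (it in seq_len(iters)) {
    H <- nrow(mask); W <- ncol(mask)
    out <- matrix(FALSE, H, W)
    for (r in seq_len(H)) {
      for (c in seq_len(W)) {
        rr <- (r - h):(r + h); cc <- (c - h):(c + h)
        rr <- rr[rr >= 1 & rr <= H]; cc <- cc[cc >= 1 & cc <= W]
        out[r, c] <- any(mask[rr, cc])
      }
    }
    mask <- out
  }
  mask
}

bruteErode <- function(mask, k, iters = 1L) {
  h <- k %/% 2L
  for (it in seq_len(iters)) {
    H <- nrow(mask); W <- ncol(mask)
    out <- matrix(FALSE, H, W)
    for (r in seq_len(H)) {
      for (c in seq_len(W)) {
        rr <- (r - h):(r + h); cc <- (c - h):(c + h)
        if (all(rr >= 1 & rr <= H) && all(cc >= 1 & cc <= W))
          out[r, c] <- all(mask[rr, cc])
      }
    }
    mask <- out
  }
  mask
}

## exhaustive (a, b, R) Hough accumulator sharing the CHT's definitions
## (votes along +/- gradient, 5x5 pooled peaks, perimeter-fraction
## threshold, greedy NMS) but written as plain R loops
oracleCht <- function(edges, gx, gy, radii, voteFrac, minDist) {
  H <- nrow(edges); W <- ncol(edges)
  ep <- which(edges, arr.ind = TRUE)
  cand <- NULL
  for (R in radii) {
    acc <- matrix(0L, H, W)
    for (i in seq_len(nrow(ep))) {
      r <- ep[i, 1]; c <- ep[i, 2]
      g <- sqrt(gx[r, c]^2 + gy[r, c]^2)
      if (g <= 0) next
      for (s in c(-1, 1)) {
        ## round half up, as C's lround does for positive values
        a <- floor(r + s * R * gy[r, c] / g + 0.5)
        b <- floor(c + s * R * gx[r, c] / g + 0.5)
        if (a >= 1 && a <= H && b >= 1 && b <= W)
          acc[a, b] <- acc[a, b] + 1L
      }
    }
    thr <- voteFrac * 2 * pi * R
    for (r in seq_len(H)) {
      for (c in seq_len(W)) {
        if (acc[r, c] == 0L) next
        rr <- max(1, r - 2):min(H, r + 2)
        cc <- max(1, c - 2):min(W, c + 2)
        v <- sum(acc[rr, cc])
        if (v >= thr)
          cand <- rbind(cand, c(row = r - 1L, col = c - 1L,
                                radius = R, votes = v))
      }
    }
  }
  if (is.null(cand))
    return(data.frame(row = integer(), col = integer(),
                      radius = integer(), votes = integer()))
  cand <- as.data.frame(cand)
  cand <- cand[order(-cand$votes, cand$row, cand$col), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ki <- which(keep)
    if (length(ki) == 0L ||
        all((cand$row[ki] - cand$row[i])^2 +
            (cand$col[ki] - cand$col[i])^2 >= minDist^2))
      keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$row, out$col), , drop = FALSE]
}

## paint a brightfield-like annulus (bright rim, darker interior) into a
## grey integer matrix
drawAnnulus <- function(img, cy, cx, R, rim = 1.5,
                        interiorVal = 2500L, rimVal = 9500L) {
  d <- sqrt(outer((seq_len(nrow(img)) - cy)^2,
                  (seq_len(ncol(img)) - cx)^2, `+`))
  img[d < R - rim] <- interiorVal
  img[abs(d - R) <= rim] <- rimVal
  img
}

## paint a filled disk
drawDisk <- function(mask, cy, cx, R) {
  d <- sqrt(outer((seq_len(nrow(mask)) - cy)^2,
                  (seq_len(ncol(mask)) - cx)^2, `+`))
  mask | d <= R
}

## a 2-droplet scene spec that analyses in well under a second
smallSceneSpec <- function(seed = 1L, ...) {
  sceneSpec(imageSize = c(420L, 560L), margin = 100, seed = seed, ...)
}
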