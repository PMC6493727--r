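#' @include AllClasses.R contours.R
NULL

#' Assign contours to droplets by centre-map overlay
#'
#' A contour belongs to droplet `d` when the Euclidean distance from its
#' centroid to the droplet centre is at most the droplet's detected radius
#' (each detected radius lies inside the configured 25-50 um scan range).
#' A contour inside several droplet detections goes to the nearest centre,
#' ties to the lower `dropletId`; contours inside no droplet are flagged
#' free-floating and excluded from all population counts.
#'
#' @param droplets a [DropletMap-class]
#' @param contours a [ContourSet-class] from the same image
#' @return an [EncapsulationResult-class] (occupancy still unset; see
#'   [classifyOccupancy()])
#' @export
assignContoursToDroplets <- function(droplets, contours) {
  dd <- droplets@droplets
  ci <- contours@info
  assign <- data.frame(contourId = ci$contourId, classLabel = ci$classLabel,
                       dropletId = rep(NA_integer_, nrow(ci)))
  if (nrow(ci) > 0L && nrow(dd) > 0L) {
    for (i in seq_len(nrow(ci))) {
      d <- sqrt((dd$x - ci$x[i])^2 + (dd$y - ci$y[i])^2)
      inside <- which(d <= dd$radius)
      if (length(inside)) {
        best <- inside[order(d[inside], dd$dropletId[inside])][1]
        assign$dropletId[i] <- dd$dropletId[best]
      }
    }
  }
  nd <- nrow(dd)
  records <- data.frame(dropletId = dd$dropletId,
                        occupancy = rep(NA_character_, nd),
                        nLive = integer(nd), nDead = integer(nd),
                        nOverlap = integer(nd), nEuNp = integer(nd),
                        nTbNp = integer(nd), tracked = logical(nd))
  countOf <- function(cls)
    as.integer(table(factor(assign$dropletId[assign$classLabel == cls],
                            levels = dd$dropletId)))
  if (nrow(dd) > 0L) {
    records$nLive <- countOf("live")
    records$nDead <- countOf("dead")
    records$nOverlap <- countOf("overlap")
    records$nEuNp <- countOf("eu_np")
    records$nTbNp <- countOf("tb_np")
  }
  new("EncapsulationResult", records = records, assignments = assign,
      summary = data.frame(), imageIndex = contours@imageIndex)
}

#' Classify droplet occupancy and summarise the population
#'
#' Occupancy counts only cell-class contours (live, dead, overlap):
#' 0 = empty, 1 = single_cell, >= 2 = multi_cell. Nanoparticle contours
#' never contribute to occupancy; a droplet is `tracked` when it holds at
#' least one cell and at least one NP contour. The summary satisfies
#' `nEmpty + nSce + nMce = nDroplets` and viability =
#' `nLive / (nLive + nDead + nOverlap)` exactly.
#'
#' @param result an [EncapsulationResult-class] from
#'   [assignContoursToDroplets()]
#' @return the result with occupancy filled in and a one-row summary
#' @export
classifyOccupancy <- function(result) {
  rec <- result@records
  nCells <- rec$nLive + rec$nDead + rec$nOverlap
  nNp <- rec$nEuNp + rec$nTbNp
  rec$occupancy <- ifelse(nCells == 0L, "empty",
                          ifelse(nCells == 1L, "single_cell", "multi_cell"))
  rec$tracked <- nCells > 0L & nNp > 0L
  free <- sum(is.na(result@assignments$dropletId))
  summ <- data.frame(
    nDroplets = nrow(rec),
    nEmpty = sum(rec$occupancy == "empty"),
    nSce = sum(rec$occupancy == "single_cell"),
    nMce = sum(rec$occupancy == "multi_cell"),
    nLive = sum(rec$nLive), nDead = sum(rec$nDead),
    nOverlap = sum(rec$nOverlap),
    nEuNp = sum(rec$nEuNp), nTbNp = sum(rec$nTbNp),
    nFreeContours = free,
    nTracked = sum(rec$tracked),
    viability = {
      tot <- sum(rec$nLive) + sum(rec$nDead) + sum(rec$nOverlap)
      if (tot > 0) sum(rec$nLive) / tot else NA_real_
    })
  new("EncapsulationResult", records = rec, assignments = result@assignments,
      summary = summ, imageIndex = result@imageIndex)
}

#' Per-droplet co-encapsulation (tracking) table
#'
#' One row per droplet with its cell counts by class, NP counts by class,
#' occupancy and the tracked flag (>= 1 cell and >= 1 NP cluster in the same
#' droplet). Suitable for [exportTable()].
#'
#' @param result a classified [EncapsulationResult-class]
#' @return data.frame
#' @export
coEncapsulationTable <- function(result) {
  rec <- result@records
  data.frame(dropletId = rec$dropletId, image = result@imageIndex,
             occupancy = rec$occupancy,
             nLive = rec$nLive, nDead = rec$nDead, nOverlap = rec$nOverlap,
             nEuNp = rec$nEuNp, nTbNp = rec$nTbNp, tracked = rec$tracked)
}

#' Droplet subpopulation counts for tracking experiments
#'
#' Splits the droplet population into empty / cell-only / NP-only /
#' co-encapsulated single-cell / co-encapsulated multi-cell, the categories
#' used to benchmark droplet tracking with co-encapsulated nanoparticles.
#'
#' @param result a classified [EncapsulationResult-class]
#' @return one-row data.frame `empty, cellOnly, npOnly, coSc, coMc`
#' @export
subpopulationCounts <- function(result) {
  rec <- result@records
  nCells <- rec$nLive + rec$nDead + rec$nOverlap
  nNp <- rec$nEuNp + rec$nTbNp
  data.frame(
    empty = sum(nCells == 0L & nNp == 0L),
    cellOnly = sum(nCells > 0L & nNp == 0L),
    npOnly = sum(nCells == 0L & nNp > 0L),
    coSc = sum(nCells == 1L & nNp > 0L),
    coMc = sum(nCells >= 2L & nNp > 0L))
}
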