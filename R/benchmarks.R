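#' @include pipeline.R
NULL

#' Run the pipeline over a seeded synthetic set and score it
#'
#' Generates `nImages` scenes from `spec` one at a time, analyzes each with
#' the class boundaries matching the scene (or `boundaries` when given) and
#' scores the pooled results against the ground truth. Images are discarded
#' after analysis so arbitrarily large sets run in bounded memory.
#'
#' @param spec a [SceneSpec-class]
#' @param nImages images in the set
#' @param boundaries class boundaries for the run (default:
#'   [sceneBoundaries()] of the spec)
#' @param matchRadius centroid match radius for object scoring, px
#' @return list: `score` (see [scoreAgainstTruth()]), `perImage`, `truths`,
#'   `analysisSeconds` (pipeline time excluding scene generation)
#' @export
benchmarkSet <- function(spec, nImages, boundaries = sceneBoundaries(spec),
                         matchRadius = 5) {
  cfg <- runConfig(boundaries = boundaries, logLevel = "quiet")
  perImage <- vector("list", nImages)
  truths <- vector("list", nImages)
  secs <- 0
  for (i in seq_len(nImages)) {
    sc <- generateScene(spec, i)
    truths[[i]] <- sc$truth
    t0 <- Sys.time()
    perImage[[i]] <- analyzeImage(sc$image, cfg, i)
    secs <- secs + as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  identities <- do.call(rbind, lapply(perImage, function(res) {
    s <- res$encapsulation@summary
    data.frame(nDroplets = s$nDroplets,
               occupancySum = s$nEmpty + s$nSce + s$nMce,
               nContours = nContours(res$contours),
               nAssigned = sum(!is.na(res$encapsulation@assignments$dropletId)),
               nFree = s$nFreeContours)
  }))
  list(score = scoreAgainstTruth(perImage, truths, matchRadius),
       perImage = perImage, truths = truths, identities = identities,
       analysisSeconds = secs)
}

## categories entering each headline benchmark
.CELL_COUNT_CATEGORIES <- c("live", "dead", "overlap", "sce", "mce")
.SUBPOP_CATEGORIES <- c("empty", "cellOnly", "npOnly", "coSc", "coMc")

#' Headline validation benchmarks
#'
#' Scaled-down analogues of the three assay-level validations, all on
#' seeded synthetic trap-array scenes with known ground truth:
#'
#' * `benchmarkCellCounting()` - a triplicate of image sets (28 images,
#'   ~780 droplets and >=275 encapsulated live/dead/overlap cells per set);
#'   reports the percent count agreement per category (encapsulated cells
#'   by class plus SCE/MCE droplets) averaged over the triplicate.
#' * `benchmarkTracking()` - duplicate runs of RFP-class cells with Eu/Tb
#'   nanoparticle clusters (~780 droplets per run, co-encapsulation rate
#'   0.3); reports percent agreement of the droplet subpopulation table
#'   (empty / cell-only / NP-only / co-encapsulated SC / co-encapsulated
#'   MC) averaged over the duplicate.
#' * `benchmarkIntensity()` - >=142 singly encapsulated cells with known
#'   mean intensities under ~3% read noise; reports the mean per-cell
#'   relative agreement `100 * (1 - |auto - truth| / truth)` of the mean
#'   intracellular fluorescence over matched cells.
#'
#' @param seed integer; set seeds are derived from it deterministically
#' @param nImages images per set
#' @param nSets number of replicate sets
#' @return list: `value` (the headline percent), `perCategory` or `nCells`,
#'   `perSet`, `analysisSeconds`, `n` (droplets or cells scored)
#' @export
benchmarkCellCounting <- function(seed = 1L, nImages = 28L, nSets = 3L) {
  sets <- lapply(seq_len(nSets), function(k)
    benchmarkSet(viabilitySceneSpec(seed * 100L + k), nImages))
  perSet <- t(vapply(sets, function(s)
    s$score$countAgreement[.CELL_COUNT_CATEGORIES],
    numeric(length(.CELL_COUNT_CATEGORIES))))
  nCells <- vapply(sets, function(s) {
    cc <- s$score$counts
    sum(cc$truth[cc$category %in% c("live", "dead", "overlap")])
  }, 1)
  list(value = mean(perSet), perCategory = colMeans(perSet), perSet = perSet,
       identities = do.call(rbind, lapply(sets, `[[`, "identities")),
       analysisSeconds = sum(vapply(sets, `[[`, 1, "analysisSeconds")),
       n = sum(vapply(sets, function(s)
         s$score$counts$truth[s$score$counts$category == "droplets"], 1)),
       nCells = nCells)
}

#' @rdname benchmarkCellCounting
#' @export
benchmarkTracking <- function(seed = 1L, nImages = 28L, nSets = 2L) {
  sets <- lapply(seq_len(nSets), function(k)
    benchmarkSet(trackingSceneSpec(seed * 100L + 10L + k), nImages))
  perSet <- t(vapply(sets, function(s)
    s$score$countAgreement[.SUBPOP_CATEGORIES],
    numeric(length(.SUBPOP_CATEGORIES))))
  list(value = mean(perSet), perCategory = colMeans(perSet), perSet = perSet,
       identities = do.call(rbind, lapply(sets, `[[`, "identities")),
       analysisSeconds = sum(vapply(sets, `[[`, 1, "analysisSeconds")),
       n = sum(vapply(sets, function(s)
         s$score$counts$truth[s$score$counts$category == "droplets"], 1)))
}

#' @rdname benchmarkCellCounting
#' @export
benchmarkIntensity <- function(seed = 1L, nImages = 12L) {
  s <- benchmarkSet(uptakeSceneSpec(seed * 100L + 21L), nImages)
  list(value = s$score$intensitySimilarity,
       nCells = s$score$nMatched,
       identities = s$identities,
       analysisSeconds = s$analysisSeconds,
       n = s$score$nMatched)
}
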