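#' Measure planted class-conditional nucleus areas through the full pipeline
#'
#' Validation workflow for the nucleus-area measurement chain: renders
#' replicate synthetic scenes, each planting \code{nCells} microglia of
#' one activity class with relative nucleus areas drawn from the
#' class-conditional distribution (see \code{\link{classAreaParameters}});
#' trains the pixel classifier on scribbles drawn from the first scene's
#' ground truth; then segments every scene, filters small objects,
#' detects nuclei by the dual-channel criterion and measures their
#' relative areas. The pipeline-measured class mean estimates the
#' planted distribution mean, with sampling error shrinking as
#' \code{nScenes} grows.
#'
#' @param class activity-state label to plant.
#' @param nCells cells per scene (the calibration table's per-class n is
#'   the natural choice).
#' @param nScenes number of replicate scenes to average over.
#' @param dim scene shape; larger scenes reduce relative pixelation
#'   error and ease non-overlapping placement of many cells.
#' @param seed integer seed governing scene generation, scribble
#'   sampling and classifier training.
#' @param scribblesPerClass training scribbles per class (default 400).
#' @param noiseSd scene noise level (default 0.05).
#' @return list: \code{measured} (per-cell measured relative areas, \%),
#'   \code{planted} (per-cell planted relative areas), \code{nDetected},
#'   \code{nPlanted}.
#' @export
measurePlantedClassAreas <- function(class, nCells, nScenes = 10,
                                     dim = c(512L, 512L), seed = 1L,
                                     scribblesPerClass = 400L,
                                     noiseSd = 0.05) {
  set.seed(seed)
  sceneSeeds <- sample.int(1000000000L, nScenes)
  scribSeed <- sample.int(1000000000L, 1L)
  trainSeed <- sample.int(1000000000L, 1L)
  measured <- numeric(0); planted <- numeric(0)
  nDetected <- 0L; nPlanted <- 0L
  models <- NULL
  for (k in seq_len(nScenes)) {
    sp <- sceneSpec(dim = dim, seed = sceneSeeds[k],
                    classes = rep(class, nCells), noiseSd = noiseSd)
    sc <- generateScene(sp)
    pr <- sc@projection
    if (is.null(models)) {
      set.seed(scribSeed)
      scribs <- lapply(c("nucleus", "microglia"), function(ch) {
        m <- sc@truthRasters[[ch]]
        idx <- c(sample(which(m == 1L), scribblesPerClass),
                 sample(which(m == 0L), scribblesPerClass))
        scribbleSet(row = (idx - 1L) %% nrow(m) + 1L,
                    col = (idx - 1L) %/% nrow(m) + 1L,
                    class = rep(c("object", "background"),
                                each = scribblesPerClass),
                    channel = ch)
      })
      models <- list(
        nucleus = trainPixelClassifier(extractFeatures(pr, "nucleus"),
                                       scribs[[1L]], seed = trainSeed),
        microglia = trainPixelClassifier(extractFeatures(pr, "microglia"),
                                         scribs[[2L]], seed = trainSeed))
    }
    nucMask <- filterSmallObjects(segmentChannel(pr, models$nucleus,
                                                 "nucleus"))
    gliMask <- filterSmallObjects(segmentChannel(pr, models$microglia,
                                                 "microglia"))
    rec <- detectNuclei(nucMask, gliMask)
    measured <- c(measured, rec$relative_area_pct)
    planted <- c(planted, truthCells(sc)$planted_rel_area_pct)
    nDetected <- nDetected + nrow(rec)
    nPlanted <- nPlanted + nCells
  }
  list(measured = measured, planted = planted, nDetected = nDetected,
       nPlanted = nPlanted)
}
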