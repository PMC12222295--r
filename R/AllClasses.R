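#' @import methods
NULL

.CHANNEL_LABELS <- c("nucleus", "microglia", "astrocyte", "neurofilament")

#' Multi-channel fluorescence Z-stack
#'
#' A registered multi-channel Z-stack: one 3-D array (rows x columns x
#' planes) per named channel. Channels are stored as separate named
#' intensity rasters, never as a fused RGB composite; display colours
#' (green Iba1, blue DAPI, red GFAP/neurofilament) are presentation, not
#' data. Absent channels are permitted so that single-stain and
#' double-stain images both load.
#'
#' @slot stack named list of 3-D numeric arrays, one per channel label in
#'   \code{c("nucleus", "microglia", "astrocyte", "neurofilament")}; all
#'   arrays share one raster shape and plane count.
#' @slot planeSpacingUm positive numeric, spacing of the planes along the
#'   Z axis in micrometres (default 0.24).
#' @slot pixelSizeUm positive numeric, lateral pixel size in micrometres
#'   (metadata only; measurements in this package are in pixels).
#' @slot maxPlanes integer, maximum admissible number of planes
#'   (default 30; acquisition protocols vary between 28 and 30 planes, so
#'   the cap is configurable rather than fixed).
#' @exportClass ChannelStack
setClass("ChannelStack",
  representation(
    stack = "list",
    planeSpacingUm = "numeric",
    pixelSizeUm = "numeric",
    maxPlanes = "integer"
  ),
  prototype(planeSpacingUm = 0.24, pixelSizeUm = NA_real_, maxPlanes = 30L)
)

setValidity("ChannelStack", function(object) {
  s <- object@stack
  if (length(s) == 0L) return("stack contains no channels")
  if (is.null(names(s)) || !all(names(s) %in% .CHANNEL_LABELS))
    return(sprintf("channel labels must be among: %s",
                   paste(.CHANNEL_LABELS, collapse = ", ")))
  if (anyDuplicated(names(s))) return("duplicated channel labels")
  dims <- lapply(s, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("each channel must be a 3-D array (rows x cols x planes)")
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    return("all channels must share one raster shape and plane count")
  if (d0[3L] < 1L) return("stack must contain at least one plane")
  if (d0[3L] > object@maxPlanes)
    return(sprintf("stack has %d planes, more than maxPlanes = %d",
                   d0[3L], object@maxPlanes))
  if (!is.finite(object@planeSpacingUm) || object@planeSpacingUm <= 0)
    return("planeSpacingUm must be a positive number")
  if (any(vapply(s, function(a) any(a < 0), logical(1))))
    return("intensities must be non-negative")
  TRUE
})

#' Maximum-intensity projection of a stack
#'
#' One 2-D intensity raster per channel, each pixel being the maximum over
#' the stack's planes at that position.
#'
#' @slot channels named list of 2-D numeric matrices, one per channel.
#' @slot pixelSizeUm lateral pixel size carried over from the stack.
#' @exportClass Projection
setClass("Projection",
  representation(channels = "list", pixelSizeUm = "numeric"),
  prototype(pixelSizeUm = NA_real_)
)

setValidity("Projection", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("projection contains no channels")
  if (is.null(names(ch)) || !all(names(ch) %in% .CHANNEL_LABELS))
    return("channel labels must be nucleus/microglia/astrocyte/neurofilament")
  dims <- lapply(ch, dim)
  d0 <- dims[[1L]]
  if (length(d0) != 2L) return("channels must be 2-D matrices")
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    return("all channels must share one raster shape")
  TRUE
})

#' Binary segmentation mask for one channel
#'
#' Object/background raster produced by the pixel classifier, together
#' with the small-object threshold that has been applied to it
#' (\code{minObjectSize = 0} until \code{\link{filterSmallObjects}} runs).
#'
#' @slot mask integer matrix of 0/1 (object = 1).
#' @slot minObjectSize non-negative integer; connected components smaller
#'   than this have been reassigned to background.
#' @slot channel source channel label.
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(mask = "matrix", minObjectSize = "integer",
                 channel = "character"),
  prototype(minObjectSize = 0L, channel = NA_character_)
)

setValidity("SegmentationMask", function(object) {
  m <- object@mask
  if (!all(m %in% c(0L, 1L))) return("mask must be binary (0/1)")
  if (length(object@minObjectSize) != 1L || is.na(object@minObjectSize) ||
      object@minObjectSize < 0L)
    return("minObjectSize must be a single non-negative integer")
  TRUE
})

#' Trained per-pixel object/background classifier
#'
#' A seeded random-forest ensemble over the per-pixel feature table.
#' Prediction is deterministic given identical features and seed, so
#' retraining with the same scribbles reproduces the identical mask.
#'
#' @slot forest the fitted \pkg{randomForest} object.
#' @slot featureRecipe identifier of the feature set the model was trained
#'   on; segmentation refuses feature tables with a different recipe.
#' @slot channel channel label the scribbles came from.
#' @slot training list with training metadata: \code{nObject},
#'   \code{nBackground}, \code{seed}, \code{accuracy} (training accuracy on
#'   the scribbled pixels).
#' @exportClass PixelClassifierModel
setClass("PixelClassifierModel",
  representation(forest = "ANY", featureRecipe = "character",
                 channel = "character", training = "list")
)

#' Annular zone of influence around a nucleus
#'
#' The ring in which microglial processes are counted: pixels whose
#' Euclidean distance d to the nucleus pixel set satisfies
#' \code{gapPx + 1 <= d < gapPx + widthPx + 1}, i.e. a ring of
#' \code{widthPx} pixels beginning after an open gap of \code{gapPx}
#' background pixels. Rings clipped at the image border are permitted and
#' flagged.
#'
#' @slot nucleusId id of the nucleus the ring belongs to.
#' @slot gapPx integer open gap between nucleus and ring (default 9).
#' @slot widthPx integer radial width of the ring (default 14).
#' @slot ring two-column integer matrix (row, col) of ring pixels.
#' @slot borderClipped logical, \code{TRUE} when part of the ideal ring
#'   falls outside the image.
#' @slot dim integer image dimensions (rows, cols).
#' @exportClass InfluenceZone
setClass("InfluenceZone",
  representation(nucleusId = "integer", gapPx = "integer",
                 widthPx = "integer", ring = "matrix",
                 borderClipped = "logical", dim = "integer")
)

setValidity("InfluenceZone", function(object) {
  if (object@gapPx < 0L) return("gapPx must be >= 0")
  if (object@widthPx < 1L) return("widthPx must be >= 1")
  if (nrow(object@ring) == 0L) return("ring is empty (entirely outside image?)")
  TRUE
})

#' Activity-state classifier with merged class intervals
#'
#' Nucleus-area intervals per activity state, merged wherever the 95\%
#' confidence intervals of two states overlap (transitive closure), with
#' decision boundaries at the midpoints of the gaps between adjacent merged
#' groups. Values below the lowest or above the highest interval clamp to
#' the extreme groups; a value exactly on a boundary goes to the lower
#' group.
#'
#' @slot states data.frame of the input states (label, n, mean, ci_low,
#'   ci_high), ordered by mean.
#' @slot groups data.frame of merged groups: \code{label} (member labels
#'   joined by \code{"+"}), \code{members}, \code{low}, \code{high},
#'   \code{n}, ordered by interval.
#' @slot boundaries numeric decision boundaries between adjacent groups
#'   (length \code{nrow(groups) - 1}).
#' @exportClass MergedClassifier
setClass("MergedClassifier",
  representation(states = "data.frame", groups = "data.frame",
                 boundaries = "numeric")
)

setValidity("MergedClassifier", function(object) {
  g <- object@groups
  if (nrow(g) == 0L) return("classifier has no groups")
  if (length(object@boundaries) != nrow(g) - 1L)
    return("number of boundaries must be one less than number of groups")
  if (nrow(g) > 1L) {
    if (any(g$low[-1L] <= g$high[-nrow(g)]))
      return("merged group intervals must be disjoint and ordered")
  }
  TRUE
})

#' Specification of a synthetic fluorescence scene
#'
#' Parameters from which \code{\link{generateScene}} renders a
#' multi-channel scene with planted ground truth. The per-cell table may
#' be given explicitly or sampled from class-conditional nucleus-area
#' distributions at generation time.
#'
#' @slot dim integer image shape (rows, cols).
#' @slot seed integer RNG seed; identical spec + seed gives bit-identical
#'   scenes.
#' @slot cells data.frame with one row per microglial cell: \code{class}
#'   (activity-state label), and optionally \code{row}, \code{col},
#'   \code{rel_area_pct} (target nucleus area as percent of image area),
#'   \code{arms} (radial process count), \code{arm_length_px},
#'   \code{arm_width_px}. Missing columns are sampled/defaulted.
#' @slot nAstrocyteFilaments integer count of random-walk astrocyte
#'   filaments.
#' @slot nNeuriteTracts integer count of parallel neurite tracts.
#' @slot neuriteDispersion non-negative numeric orientation dispersion of
#'   the tracts (radians; 0 = perfectly parallel).
#' @slot noiseSd numeric Gaussian noise standard deviation as a fraction
#'   of the dynamic range (default 0.05).
#' @slot poissonNoise logical, add Poisson shot noise.
#' @slot background numeric background intensity level (fraction of the
#'   dynamic range).
#' @slot somaAnnulusPx integer width of the Iba1-bright soma rim rendered
#'   around each nucleus (guarantees the green border).
#' @slot minSeparationPx numeric minimum distance between cell centres;
#'   \code{NA} means "somata must not overlap".
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    dim = "integer", seed = "integer", cells = "data.frame",
    nAstrocyteFilaments = "integer", nNeuriteTracts = "integer",
    neuriteDispersion = "numeric", noiseSd = "numeric",
    poissonNoise = "logical", background = "numeric",
    somaAnnulusPx = "integer", minSeparationPx = "numeric"
  )
)

setValidity("SceneSpec", function(object) {
  if (length(object@dim) != 2L || any(object@dim < 8L))
    return("dim must be two integers >= 8")
  if (!is.finite(object@noiseSd) || object@noiseSd < 0)
    return("noiseSd must be >= 0")
  if (object@background < 0 || object@background > 1)
    return("background must be in [0, 1]")
  if (nrow(object@cells) > 0L && !"class" %in% names(object@cells))
    return("cells table must have a 'class' column")
  TRUE
})

#' Rendered synthetic scene with planted ground truth
#'
#' @slot projection the rendered (noisy) \code{\linkS4class{Projection}}.
#' @slot truthRasters named list of binary matrices: the noise-free true
#'   object raster per channel.
#' @slot cells data.frame of per-cell ground truth: id, centre, nucleus
#'   radius, rasterised nucleus area (px and percent of image area), the
#'   planted (sampled) relative area, arm count and class label.
#' @slot spec the \code{\linkS4class{SceneSpec}} the scene was rendered
#'   from.
#' @slot entities internal list of rendered structures (pixel indices,
#'   intensity, channel, cell id) used by \code{\link{renderZstack}}.
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(projection = "Projection", truthRasters = "list",
                 cells = "data.frame", spec = "SceneSpec",
                 entities = "list")
)
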