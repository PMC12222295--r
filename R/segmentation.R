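.FEATURE_RECIPE <- "v1:raw+gauss(1,2)+gradmag+localvar(5)"

.ebi <- function(m) EBImage::Image(m)
.mat <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  m
}

.filter2rep <- function(m, kern)
  .mat(EBImage::filter2(.ebi(m), kern, boundary = "replicate"))

# separable Gaussian smoothing with the kernel clipped to the raster, so
# small images remain featurisable
.gaussBlur <- function(m, sigma) {
  h <- min(ceiling(3 * sigma), (min(dim(m)) - 1L) %/% 2L)
  if (h < 1L) return(m)
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  .filter2rep(m, outer(k, k))
}

#' Per-pixel feature table for trainable segmentation
#'
#' Computes a fixed-length feature vector for every pixel of one channel:
#' raw intensity, Gaussian-smoothed intensity at two scales (sigma 1 and
#' 2 px), gradient magnitude (Sobel), and local variance in a 5 x 5
#' window. This is the feature bank the scribble-trained pixel classifier
#' operates on; its identifier is recorded in the trained model so that
#' model and features cannot be mixed across recipes.
#'
#' @param projection a \code{\linkS4class{Projection}}.
#' @param channel channel label to featurise.
#' @return numeric matrix with one row per pixel (column-major pixel
#'   order) and one column per feature; attributes \code{recipe} and
#'   \code{dim} carry the recipe id and raster shape.
#' @export
extractFeatures <- function(projection, channel) {
  m <- getChannel(projection, channel)
  g1 <- .gaussBlur(m, 1)
  g2 <- .gaussBlur(m, 2)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- .filter2rep(m, sx)
  gy <- .filter2rep(m, t(sx))
  grad <- sqrt(gx^2 + gy^2)
  box <- matrix(1 / 25, 5, 5)
  mu <- .filter2rep(m, box)
  lv <- pmax(.filter2rep(m^2, box) - mu^2, 0)
  feat <- cbind(raw = as.vector(m), gauss1 = as.vector(g1),
                gauss2 = as.vector(g2), gradmag = as.vector(grad),
                localvar = as.vector(lv))
  attr(feat, "recipe") <- .FEATURE_RECIPE
  attr(feat, "rasterDim") <- dim(m)
  feat
}

#' Build a scribble set
#'
#' Scribbles are manually marked pixels labelling training examples of
#' the two classes the pixel classifier distinguishes: \code{object}
#' (stained structure) and \code{background}.
#'
#' @param row,col 1-based pixel coordinates.
#' @param class character vector of \code{"object"} / \code{"background"}.
#' @param channel the channel the scribbles annotate.
#' @return a data.frame of class \code{scribbleSet}.
#' @export
scribbleSet <- function(row, col, class, channel) {
  class <- as.character(class)
  if (!all(class %in% c("object", "background")))
    stop("scribble class must be 'object' or 'background'")
  out <- data.frame(row = as.integer(row), col = as.integer(col),
                    class = class, channel = channel,
                    stringsAsFactors = FALSE)
  class(out) <- c("scribbleSet", "data.frame")
  out
}

#' Read scribbles from CSV
#'
#' Expects columns \code{row}, \code{col} (or \code{x}, \code{y} with x =
#' column, y = row), \code{class} and \code{channel}.
#'
#' @param path CSV file path.
#' @return a \code{scribbleSet} data.frame.
#' @export
readScribbles <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"row" %in% names(d) && all(c("x", "y") %in% names(d))) {
    d$row <- d$y; d$col <- d$x
  }
  scribbleSet(d$row, d$col, d$class, d$channel)
}

#' Train the per-pixel object/background classifier
#'
#' Fits a seeded shallow random-forest ensemble on the feature vectors of
#' the scribbled pixels. Training is deterministic given identical
#' features, scribbles and seed, so the downstream mask is bit-exactly
#' reproducible.
#'
#' @param features feature table from \code{\link{extractFeatures}}.
#' @param scribbles a \code{\link{scribbleSet}} containing both classes.
#' @param seed integer RNG seed for the ensemble.
#' @param ntree number of trees (default 50).
#' @return a \code{\linkS4class{PixelClassifierModel}}; its
#'   \code{training$accuracy} element reports training accuracy on the
#'   scribbled pixels and \code{training$oobAccuracy} the out-of-bag
#'   accuracy (an honest generalisation estimate).
#' @export
trainPixelClassifier <- function(features, scribbles, seed = 1L,
                                 ntree = 50L) {
  dm <- attr(features, "rasterDim")
  if (any(scribbles$row < 1L | scribbles$row > dm[1L] |
          scribbles$col < 1L | scribbles$col > dm[2L]))
    stop("scribble coordinates fall outside the raster")
  classes <- unique(scribbles$class)
  if (length(classes) < 2L)
    stop("scribbles must contain both 'object' and 'background' pixels")
  idx <- (scribbles$col - 1L) * dm[1L] + scribbles$row
  x <- features[idx, , drop = FALSE]
  y <- factor(scribbles$class, levels = c("background", "object"))
  set.seed(seed)
  forest <- randomForest::randomForest(x, y, ntree = ntree)
  acc <- mean(stats::predict(forest, x) == y)
  new("PixelClassifierModel", forest = forest,
      featureRecipe = attr(features, "recipe"),
      channel = scribbles$channel[1L],
      training = list(nObject = sum(y == "object"),
                      nBackground = sum(y == "background"),
                      seed = as.integer(seed), ntree = as.integer(ntree),
                      accuracy = acc,
                      oobAccuracy = 1 - unname(forest$err.rate[ntree, "OOB"])))
}

setMethod("show", "PixelClassifierModel", function(object) {
  cat(sprintf(
    "PixelClassifierModel (%s)\nchannel: %s | scribbles: %d object / %d background | seed %d\ntraining accuracy: %.3f\n",
    object@featureRecipe, object@channel, object@training$nObject,
    object@training$nBackground, object@training$seed,
    object@training$accuracy))
})

#' Classify every pixel of a channel into object or background
#'
#' Applies a trained pixel classifier to a projection channel and returns
#' the raw (unfiltered) binary mask; apply
#' \code{\link{filterSmallObjects}} afterwards to suppress small pixel
#' groups.
#'
#' @param projection a \code{\linkS4class{Projection}}.
#' @param model a \code{\linkS4class{PixelClassifierModel}} trained on
#'   the same feature recipe.
#' @param channel channel to segment (default: the model's channel).
#' @return a \code{\linkS4class{SegmentationMask}} with
#'   \code{minObjectSize = 0}.
#' @export
segmentChannel <- function(projection, model, channel = model@channel) {
  feat <- extractFeatures(projection, channel)
  if (!identical(attr(feat, "recipe"), model@featureRecipe))
    stop("feature recipe mismatch: model was trained on ",
         model@featureRecipe)
  pred <- stats::predict(model@forest, feat)
  dm <- attr(feat, "rasterDim")
  mask <- matrix(as.integer(pred == "object"), dm[1L], dm[2L])
  new("SegmentationMask", mask = mask, minObjectSize = 0L,
      channel = channel)
}

#' Accessors for SegmentationMask objects
#'
#' @param x a \code{\linkS4class{SegmentationMask}}.
#' @name SegmentationMask-accessors
#' @aliases maskMatrix minObjectSize
NULL

#' @rdname SegmentationMask-accessors
setMethod("maskMatrix", "SegmentationMask", function(x) x@mask)

#' @rdname SegmentationMask-accessors
setMethod("minObjectSize", "SegmentationMask", function(x) x@minObjectSize)

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf(
    "SegmentationMask (%s): %d x %d px, %d object px (%.2f%%), minObjectSize = %d\n",
    object@channel, nrow(object@mask), ncol(object@mask),
    sum(object@mask), 100 * mean(object@mask), object@minObjectSize))
})

#' Build a SegmentationMask from a binary matrix
#'
#' @param mask binary (0/1 or logical) matrix, object = 1.
#' @param channel source channel label.
#' @param minObjectSize small-object threshold already applied (default 0).
#' @return a \code{\linkS4class{SegmentationMask}}.
#' @export
SegmentationMask <- function(mask, channel = NA_character_,
                             minObjectSize = 0L) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  new("SegmentationMask", mask = m, channel = channel,
      minObjectSize = as.integer(minObjectSize))
}

#' Suppress small pixel groups
#'
#' Connected components (8-neighbourhood) with strictly fewer than
#' \code{minSize} pixels are reassigned to background; components of
#' exactly \code{minSize} pixels survive. This is the background-error
#' filter applied before any area or object measurement; the default
#' threshold is 24 pixels.
#'
#' @param mask a \code{\linkS4class{SegmentationMask}}.
#' @param minSize non-negative integer pixel-count threshold (default 24).
#' @return the filtered \code{\linkS4class{SegmentationMask}} with
#'   \code{minObjectSize} updated.
#' @examples
#' m <- matrix(0, 10, 10); m[1:3, 1] <- 1
#' sm <- filterSmallObjects(SegmentationMask(m), minSize = 3)
#' sum(maskMatrix(sm))  # the 3-px component survives
#' @export
filterSmallObjects <- function(mask, minSize = 24L) {
  minSize <- as.integer(minSize)
  if (is.na(minSize) || minSize < 0L) stop("minSize must be >= 0")
  m <- mask@mask
  if (minSize > 1L && any(m > 0L)) {
    lab <- .labelComponents(m)
    sizes <- .componentSizes(lab)
    drop <- which(sizes < minSize)
    if (length(drop)) m[lab %in% drop] <- 0L
  }
  new("SegmentationMask", mask = m,
      minObjectSize = max(minSize, mask@minObjectSize),
      channel = mask@channel)
}

#' Percentage of the image covered by segmented objects
#'
#' @param x a \code{\linkS4class{SegmentationMask}}.
#' @return percent of total image area in [0, 100].
#' @export
#' @name areaFraction
setMethod("areaFraction", "SegmentationMask", function(x) {
  n <- length(x@mask)
  if (n == 0L) stop("zero-area image")
  100 * sum(x@mask) / n
})
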