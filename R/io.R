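#' Construct a ChannelStack from channel arrays
#'
#' @param stack named list of 3-D numeric arrays (rows x cols x planes) or
#'   2-D matrices (treated as single-plane stacks), one per channel label
#'   among \code{nucleus}, \code{microglia}, \code{astrocyte},
#'   \code{neurofilament}.
#' @param planeSpacingUm Z spacing in micrometres (default 0.24).
#' @param pixelSizeUm lateral pixel size in micrometres (metadata only).
#' @param maxPlanes maximum admissible plane count (default 30).
#' @return a \code{\linkS4class{ChannelStack}}.
#' @examples
#' cs <- ChannelStack(list(nucleus = array(1, c(8, 8, 3))))
#' nPlanes(cs)
#' @export
ChannelStack <- function(stack, planeSpacingUm = 0.24, pixelSizeUm = NA_real_,
                         maxPlanes = 30L) {
  stack <- lapply(stack, function(a) {
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
    storage.mode(a) <- "double"
    a
  })
  new("ChannelStack", stack = stack, planeSpacingUm = planeSpacingUm,
      pixelSizeUm = pixelSizeUm, maxPlanes = as.integer(maxPlanes))
}

#' Accessors for ChannelStack objects
#'
#' \code{channelNames} returns the channel labels present;
#' \code{getChannel} extracts one channel's plane array; \code{nPlanes}
#' the number of Z planes; \code{planeSpacing} the Z spacing in
#' micrometres.
#'
#' @param x a \code{\linkS4class{ChannelStack}} or
#'   \code{\linkS4class{Projection}}.
#' @param channel channel label.
#' @name ChannelStack-accessors
#' @aliases channelNames getChannel nPlanes planeSpacing
NULL

.checkChannel <- function(x, channel, have) {
  if (!channel %in% have)
    stop(sprintf("channel '%s' is absent (present: %s)", channel,
                 paste(have, collapse = ", ")), call. = FALSE)
}

#' @rdname ChannelStack-accessors
setMethod("channelNames", "ChannelStack", function(x) names(x@stack))

#' @rdname ChannelStack-accessors
setMethod("getChannel", "ChannelStack", function(x, channel) {
  .checkChannel(x, channel, names(x@stack))
  x@stack[[channel]]
})

#' @rdname ChannelStack-accessors
setMethod("nPlanes", "ChannelStack", function(x) dim(x@stack[[1L]])[3L])

#' @rdname ChannelStack-accessors
setMethod("planeSpacing", "ChannelStack", function(x) x@planeSpacingUm)

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@stack[[1L]])
  cat(sprintf("ChannelStack: %d x %d px, %d plane(s), dz = %g um\n",
              d[1L], d[2L], d[3L], object@planeSpacingUm))
  cat("channels:", paste(names(object@stack), collapse = ", "), "\n")
})

#' Read a multi-page TIFF / OME-TIFF into a ChannelStack
#'
#' Pages are assigned to channels through \code{channelMap}, a named list
#' giving for each channel label the 1-based page indices of its Z planes
#' (in Z order). 8-bit images are up-scaled to the 16-bit range (x 257);
#' 16-bit images are kept as stored. Channels absent from the map are
#' simply absent from the stack.
#'
#' @param path path to a readable (OME-)TIFF file.
#' @param channelMap named list, e.g.
#'   \code{list(nucleus = 1:28, microglia = 29:56)}.
#' @param planeSpacingUm,maxPlanes see \code{\link{ChannelStack}}.
#' @return a \code{\linkS4class{ChannelStack}}.
#' @export
readStack <- function(path, channelMap, planeSpacingUm = 0.24,
                      maxPlanes = 30L) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(names(channelMap)) ||
      !all(names(channelMap) %in% .CHANNEL_LABELS))
    stop("channelMap names must be among: ",
         paste(.CHANNEL_LABELS, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # collapse grey-stored-as-RGB
    p
  })
  maxval <- max(vapply(pages, max, 0))
  scale <- if (maxval <= 255) 257 else 1      # 8-bit -> 16-bit range
  stack <- lapply(channelMap, function(idx) {
    idx <- as.integer(idx)
    if (any(idx < 1L | idx > length(pages)))
      stop("channelMap page index out of range (file has ",
           length(pages), " pages)")
    planes <- pages[idx]
    d <- dim(planes[[1L]])
    if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1))))
      stop("planes differ in shape within one channel")
    array(unlist(planes, use.names = FALSE) * scale, c(d, length(planes)))
  })
  dims <- lapply(stack, dim)
  if (!all(vapply(dims, function(d) identical(d[1:2], dims[[1L]][1:2]),
                  logical(1))))
    stop("planes differ in shape across channels")
  ChannelStack(stack, planeSpacingUm = planeSpacingUm, maxPlanes = maxPlanes)
}

#' Maximum-intensity projection
#'
#' Collapses a Z-stack to one 2-D raster per channel by taking, at every
#' pixel, the maximum intensity over all planes. The projection is
#' invariant under permutation of the planes and idempotent (projecting a
#' single-plane stack returns the plane).
#'
#' @param x a \code{\linkS4class{ChannelStack}}.
#' @param ... unused.
#' @return a \code{\linkS4class{Projection}}.
#' @examples
#' cs <- ChannelStack(list(microglia = array(c(0, 3, 5, 2), c(1, 2, 2))))
#' getChannel(maxIntensityProjection(cs), "microglia")
#' @export
#' @name maxIntensityProjection
setMethod("maxIntensityProjection", "ChannelStack", function(x, ...) {
  channels <- lapply(x@stack, function(a) {
    d <- dim(a)
    out <- a[, , 1L, drop = FALSE]
    dim(out) <- d[1:2]
    if (d[3L] > 1L)
      for (k in 2L:d[3L]) out <- pmax(out, matrix(a[, , k], d[1L], d[2L]))
    out
  })
  new("Projection", channels = channels, pixelSizeUm = x@pixelSizeUm)
})

#' Construct a Projection directly from 2-D channel matrices
#'
#' @param channels named list of 2-D numeric matrices.
#' @param pixelSizeUm lateral pixel size (metadata).
#' @return a \code{\linkS4class{Projection}}.
#' @export
Projection <- function(channels, pixelSizeUm = NA_real_) {
  new("Projection", channels = channels, pixelSizeUm = pixelSizeUm)
}

#' Accessors for Projection objects
#'
#' \code{imageAreaPx} is the total pixel count (rows x columns) of the
#' raster, the denominator of all area-fraction measurements.
#'
#' @param x a \code{\linkS4class{Projection}}.
#' @name Projection-accessors
#' @aliases imageAreaPx
NULL

#' @rdname Projection-accessors
setMethod("imageAreaPx", "Projection",
          function(x) prod(dim(x@channels[[1L]])))

#' @rdname ChannelStack-accessors
setMethod("channelNames", "Projection", function(x) names(x@channels))

#' @rdname ChannelStack-accessors
setMethod("getChannel", "Projection", function(x, channel) {
  .checkChannel(x, channel, names(x@channels))
  x@channels[[channel]]
})

setMethod("show", "Projection", function(object) {
  d <- dim(object@channels[[1L]])
  cat(sprintf("Projection: %d x %d px (%d px total)\n", d[1L], d[2L],
              prod(d)))
  cat("channels:", paste(names(object@channels), collapse = ", "), "\n")
})

#' Write projection channels as single-page 16-bit TIFFs
#'
#' @param projection a \code{\linkS4class{Projection}}.
#' @param path output file; with more than one channel, the channel label
#'   is inserted before the extension.
#' @param channels channel labels to write (default: all present).
#' @return invisibly, the paths written.
#' @export
writeProjection <- function(projection, path,
                            channels = channelNames(projection)) {
  top <- max(1, max(vapply(projection@channels[channels], max, 0)))
  scale <- if (top <= 1) 1 else 65535
  paths <- character(0)
  for (ch in channels) {
    p <- if (length(channels) > 1L)
      sub("(\\.[^.]+)$", sprintf("_%s\\1", ch), path) else path
    img <- pmin(projection@channels[[ch]] / scale, 1)
    tiff::writeTIFF(img, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  invisible(paths)
}
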