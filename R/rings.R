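#' Build the zone-of-influence ring around a nucleus
#'
#' The ring is placed by the Euclidean distance transform from the
#' nucleus pixel set: with an open gap of \code{gapPx} pixels and a
#' radial width of \code{widthPx} pixels, ring pixels are those at
#' distance \code{d} with \code{gapPx + 1 <= d < gapPx + widthPx + 1}.
#' In pixel-counting terms, \code{gapPx} background pixels separate the
#' nucleus from the ring and the ring spans the next \code{widthPx}
#' pixel shells. Defaults are a 9-pixel gap and a 14-pixel width. Rings
#' clipped at the image border are returned with \code{borderClipped}
#' set.
#'
#' @param nucleus either one row of the table returned by
#'   \code{\link{detectNuclei}} or a 2-column (row, col) pixel matrix.
#' @param dim image dimensions (rows, cols); defaults to the
#'   \code{imageDim} attribute of a record table row.
#' @param gapPx open gap in pixels (>= 0, default 9).
#' @param widthPx radial ring width in pixels (>= 1, default 14).
#' @param metric distance metric passed to the distance transform,
#'   \code{"euclidean"} (default) or \code{"manhattan"}.
#' @return an \code{\linkS4class{InfluenceZone}}.
#' @export
buildInfluenceZone <- function(nucleus, dim = NULL, gapPx = 9L,
                               widthPx = 14L, metric = "euclidean") {
  gapPx <- as.integer(gapPx); widthPx <- as.integer(widthPx)
  if (gapPx < 0L) stop("gapPx must be >= 0")
  if (widthPx < 1L) stop("widthPx must be >= 1")
  if (is.data.frame(nucleus)) {
    if (is.null(dim)) dim <- attr(nucleus, "imageDim")
    if (is.null(dim) && all(c("img_rows", "img_cols") %in% names(nucleus)))
      dim <- c(nucleus$img_rows[1L], nucleus$img_cols[1L])
    id <- as.integer(nucleus$id[1L])
    pix <- nucleus$pixels[[1L]]
  } else {
    pix <- nucleus
    id <- NA_integer_
  }
  if (is.null(dim)) stop("image dimensions must be supplied")
  dim <- as.integer(dim)
  if (is.null(nrow(pix)) || nrow(pix) == 0L) stop("nucleus pixel set is empty")

  # local crop large enough to hold the whole ideal ring, so that
  # clipping at the image border is detected exactly
  reach <- gapPx + widthPx + 1L
  r0 <- min(pix[, 1L]) - reach; r1 <- max(pix[, 1L]) + reach
  c0 <- min(pix[, 2L]) - reach; c1 <- max(pix[, 2L]) + reach
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  loc <- matrix(1, nr, nc)
  loc[cbind(pix[, 1L] - r0 + 1L, pix[, 2L] - c0 + 1L)] <- 0
  d <- .mat(EBImage::distmap(.ebi(loc), metric = metric))
  sel <- which(d >= gapPx + 1L & d < gapPx + widthPx + 1L)
  ringLocal <- cbind((sel - 1L) %% nr + 1L, (sel - 1L) %/% nr + 1L)
  ring <- cbind(ringLocal[, 1L] + r0 - 1L, ringLocal[, 2L] + c0 - 1L)
  inside <- ring[, 1L] >= 1L & ring[, 1L] <= dim[1L] &
            ring[, 2L] >= 1L & ring[, 2L] <= dim[2L]
  clipped <- any(!inside)
  ring <- ring[inside, , drop = FALSE]
  if (nrow(ring) == 0L) stop("ring lies entirely outside the image")
  new("InfluenceZone", nucleusId = id, gapPx = gapPx, widthPx = widthPx,
      ring = ring, borderClipped = clipped, dim = dim)
}

#' Accessors for InfluenceZone objects
#'
#' @param x an \code{\linkS4class{InfluenceZone}}.
#' @name InfluenceZone-accessors
#' @aliases ringPixels borderClipped
NULL

#' @rdname InfluenceZone-accessors
setMethod("ringPixels", "InfluenceZone", function(x) x@ring)

#' @rdname InfluenceZone-accessors
setMethod("borderClipped", "InfluenceZone", function(x) x@borderClipped)

setMethod("show", "InfluenceZone", function(object) {
  cat(sprintf(
    "InfluenceZone (nucleus %s): gap %d px, width %d px, %d ring px%s\n",
    object@nucleusId, object@gapPx, object@widthPx, nrow(object@ring),
    if (object@borderClipped) " [clipped at border]" else ""))
})

#' Count microglial processes crossing the influence zone
#'
#' Processes are contiguous runs of microglia-channel object pixels
#' inside the ring: the count is the number of 8-connected components of
#' the intersection of the (filtered) microglia mask with the ring pixel
#' set, computed within the ring subgraph, so that green runs separated
#' by background pixels count as separate processes. The
#' nucleus's own pixels are never part of the ring (the ring is disjoint
#' from the nucleus set by construction).
#'
#' @param zone an \code{\linkS4class{InfluenceZone}}.
#' @param microgliaMask \code{\linkS4class{SegmentationMask}} of the
#'   microglia channel, built on the same image.
#' @return non-negative integer process count.
#' @export
countProcesses <- function(zone, microgliaMask) {
  gm <- maskMatrix(microgliaMask)
  if (!identical(dim(gm), as.integer(zone@dim)) &&
      !identical(dim(gm), zone@dim))
    stop("mask shape does not match the zone's image dimensions")
  ring <- zone@ring
  hit <- ring[gm[ring] > 0L, , drop = FALSE]
  if (nrow(hit) == 0L) return(0L)
  # label within a local crop of the ring's bounding box; only ring
  # pixels are present, so components are those of the ring subgraph
  r0 <- min(hit[, 1L]); c0 <- min(hit[, 2L])
  loc <- matrix(0L, max(hit[, 1L]) - r0 + 1L, max(hit[, 2L]) - c0 + 1L)
  loc[cbind(hit[, 1L] - r0 + 1L, hit[, 2L] - c0 + 1L)] <- 1L
  max(.labelComponents(loc))
}

#' Score all microglia of one projection
#'
#' For every accepted nucleus, builds the influence zone and counts the
#' processes crossing it. Rings overlapping another cell's ring or
#' nucleus are flagged (\code{overlap_flag}) so users can filter; the
#' processes found there are still counted, since a neighbouring cell's
#' processes inside the ring are not distinguishable without lineage
#' information.
#'
#' @param nuclei nucleus table from \code{\link{detectNuclei}}.
#' @param microgliaMask filtered \code{\linkS4class{SegmentationMask}} of
#'   the microglia channel.
#' @param gapPx,widthPx,metric ring geometry, see
#'   \code{\link{buildInfluenceZone}}.
#' @return data.frame: the nucleus columns plus \code{process_count},
#'   \code{border_clipped}, \code{overlap_flag} and an
#'   \code{activity_class} column initialised to \code{NA} (assigned only
#'   by \code{\link{classifyCell}}).
#' @export
scoreMicroglia <- function(nuclei, microgliaMask, gapPx = 9L,
                           widthPx = 14L, metric = "euclidean") {
  dm <- attr(nuclei, "imageDim")
  if (is.null(dm)) dm <- dim(maskMatrix(microgliaMask))
  n <- nrow(nuclei)
  out <- nuclei
  out$process_count <- integer(n)
  out$border_clipped <- logical(n)
  out$overlap_flag <- logical(n)
  out$activity_class <- rep(NA_character_, n)
  if (n == 0L) return(out)
  zones <- vector("list", n)
  occ <- matrix(0L, dm[1L], dm[2L])
  for (i in seq_len(n)) {
    z <- buildInfluenceZone(nuclei[i, ], dim = dm, gapPx = gapPx,
                            widthPx = widthPx, metric = metric)
    zones[[i]] <- z
    occ[z@ring] <- occ[z@ring] + 1L
    occ[nuclei$pixels[[i]]] <- occ[nuclei$pixels[[i]]] + 1L
    out$process_count[i] <- countProcesses(z, microgliaMask)
    out$border_clipped[i] <- z@borderClipped
  }
  for (i in seq_len(n))
    out$overlap_flag[i] <- any(occ[zones[[i]]@ring] > 1L)
  attr(out, "imageDim") <- dm
  out
}
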