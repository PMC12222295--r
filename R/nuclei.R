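#' Detect microglial nuclei by the dual-channel border criterion
#'
#' Candidate nuclei are connected components of the nucleus-channel mask
#' (8-neighbourhood); touching candidates are optionally split by a
#' distance-transform watershed. Candidates below the small-object
#' threshold are discarded, consistent with the global background rule.
#' A candidate is accepted as a microglial nucleus when at least
#' \code{borderFractionMin} of its boundary shell -- the 1-pixel outward
#' dilation ring -- lies on microglia-channel object pixels, i.e. the
#' dark nucleus is rimmed by Iba1-positive cytoplasm.
#'
#' @param nucleusMask \code{\linkS4class{SegmentationMask}} of the
#'   nucleus channel.
#' @param microgliaMask \code{\linkS4class{SegmentationMask}} of the
#'   microglia channel, same shape.
#' @param borderFractionMin minimum green fraction of the boundary shell
#'   for acceptance, in [0, 1]; default 0.5 (the source protocol states
#'   the border criterion qualitatively only, so the threshold is an
#'   explicit configuration value).
#' @param minSizePx minimum candidate size in pixels (default 24, shared
#'   with the background filter).
#' @param splitTouching split touching candidates by watershed on the
#'   Euclidean distance transform (default TRUE).
#' @param watershedTolerance intensity tolerance of the watershed split
#'   (default 1).
#' @return data.frame with one row per accepted nucleus: \code{id},
#'   centroid \code{row}/\code{col}, \code{area_px},
#'   \code{relative_area_pct} (percent of total image area),
#'   \code{border_green_fraction}, \code{split} (TRUE when the candidate
#'   came out of a watershed split), and a list column \code{pixels}
#'   (2-column row/col matrices). The image dimensions are attached as
#'   attribute \code{imageDim}.
#' @export
detectNuclei <- function(nucleusMask, microgliaMask,
                         borderFractionMin = 0.5, minSizePx = 24L,
                         splitTouching = TRUE, watershedTolerance = 1) {
  nm <- maskMatrix(nucleusMask)
  gm <- maskMatrix(microgliaMask)
  if (!identical(dim(nm), dim(gm)))
    stop("nucleus and microglia masks differ in shape")
  if (!is.finite(borderFractionMin) || borderFractionMin < 0 ||
      borderFractionMin > 1)
    stop("borderFractionMin must be in [0, 1]")
  dm <- dim(nm)
  imageArea <- prod(dm)

  comp <- .labelComponents(nm)
  ncomp <- max(comp)
  empty <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      img_rows = integer(0), img_cols = integer(0),
                      area_px = integer(0), relative_area_pct = numeric(0),
                      border_green_fraction = numeric(0),
                      split = logical(0))
  empty$pixels <- list()
  attr(empty, "imageDim") <- dm
  if (ncomp == 0L) return(empty)

  if (splitTouching) {
    dmap <- EBImage::distmap(.ebi(matrix(as.numeric(nm != 0), dm[1L], dm[2L])))
    ws <- .mat(EBImage::watershed(dmap, tolerance = watershedTolerance))
    # watershed labels refine the 8-connected components; a component is
    # flagged split when it contains more than one watershed label
    cand <- ws
    splitOf <- tapply(ws[ws > 0], comp[ws > 0],
                      function(v) length(unique(v)) > 1L)
  } else {
    cand <- comp
    splitOf <- NULL
  }

  labs <- sort(unique(cand[cand > 0]))
  records <- list()
  id <- 0L
  for (lb in labs) {
    idx <- which(cand == lb)
    if (length(idx) < minSizePx) next
    pix <- cbind((idx - 1L) %% dm[1L] + 1L, (idx - 1L) %/% dm[1L] + 1L)
    shell <- .dilationShell(pix, dm)
    bgf <- if (nrow(shell)) mean(gm[shell] > 0) else 0
    if (bgf < borderFractionMin) next
    id <- id + 1L
    parent <- comp[idx[1L]]
    records[[id]] <- data.frame(
      id = id, row = mean(pix[, 1L]), col = mean(pix[, 2L]),
      img_rows = dm[1L], img_cols = dm[2L],
      area_px = length(idx),
      relative_area_pct = 100 * length(idx) / imageArea,
      border_green_fraction = bgf,
      split = if (!is.null(splitOf)) isTRUE(splitOf[[as.character(parent)]])
              else FALSE)
    records[[id]]$pixels <- list(pix)
  }
  if (id == 0L) return(empty)
  out <- do.call(rbind, records)
  attr(out, "imageDim") <- dm
  out
}

#' Count accepted microglial nuclei
#'
#' @param records nucleus table from \code{\link{detectNuclei}} (one
#'   projection's worth).
#' @return integer count.
#' @export
countMicroglia <- function(records) {
  if (anyDuplicated(records$id))
    stop("duplicated nucleus ids in record table")
  nrow(records)
}

#' Relative nucleus area
#'
#' The nucleus area expressed as a percentage of the total image area,
#' the quantity the activity-state classifier operates on.
#'
#' @param areaPx nucleus area(s) in pixels.
#' @param imageAreaPx total image area in pixels (> 0).
#' @return numeric percentage(s).
#' @examples
#' nucleusRelativeArea(70, 10000)  # 0.7
#' @export
nucleusRelativeArea <- function(areaPx, imageAreaPx) {
  if (!is.finite(imageAreaPx) || imageAreaPx <= 0)
    stop("imageAreaPx must be positive")
  100 * areaPx / imageAreaPx
}
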