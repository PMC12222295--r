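# Connected-component labeling with 8-neighbourhood connectivity.
# EBImage::bwlabel is 4-connected; diagonal-touching fluorescent pixels
# belong to one structure here, so 4-connected labels are merged across
# diagonal adjacencies with a union-find pass.

.labelComponents <- function(mask, connectivity = 8L) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m)))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),   # \ diag
      cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L]))    # / diag
    )
    pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    pairs <- unique(pairs)
    if (nrow(pairs)) {
      parent <- seq_len(nlab)
      findRoot <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        a <- findRoot(pairs[k, 1L]); b <- findRoot(pairs[k, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(nlab), findRoot, numeric(1))
      remap <- match(root, sort(unique(root)))
      pos <- lab > 0
      lab[pos] <- remap[lab[pos]]
    }
  }
  storage.mode(lab) <- "integer"
  lab
}

# sizes[k] = pixel count of component k
.componentSizes <- function(lab) tabulate(lab[lab > 0L])

# 1-pixel outward dilation shell of the pixel set `pix` (2-col row/col
# matrix), 8-neighbourhood, clipped to the image. Returns a 2-col matrix.
.dilationShell <- function(pix, dm) {
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  cand <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
    cbind(pix[, 1L] + off$dr[k], pix[, 2L] + off$dc[k])))
  cand <- cand[cand[, 1L] >= 1L & cand[, 1L] <= dm[1L] &
               cand[, 2L] >= 1L & cand[, 2L] <= dm[2L], , drop = FALSE]
  cand <- unique(cand)
  inSet <- paste(cand[, 1L], cand[, 2L]) %in% paste(pix[, 1L], pix[, 2L])
  cand[!inSet, , drop = FALSE]
}
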