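# Shared fixture builders: everything is generated in code at test time.

# disk pixel set (2-col row/col matrix) for ring-geometry tests
diskPixels <- function(centre, r, dm) {
  which(outer((seq_len(dm[1]) - centre[1])^2,
              (seq_len(dm[2]) - centre[2])^2, "+") <= r^2, arr.ind = TRUE)
}

# binary matrix with one disk
diskMask <- function(centre, r, dm) {
  m <- matrix(0L, dm[1], dm[2])
  m[diskPixels(centre, r, dm)] <- 1L
  m
}

# scribbles sampled from a scene's planted truth raster
truthScribbles <- function(scene, channel, n = 300, seed = 99) {
  m <- scene@truthRasters[[channel]]
  set.seed(seed)
  idx <- c(sample(which(m == 1L), n), sample(which(m == 0L), n))
  scribbleSet(row = (idx - 1L) %% nrow(m) + 1L,
              col = (idx - 1L) %/% nrow(m) + 1L,
              class = rep(c("object", "background"), each = n),
              channel = channel)
}

# match detected records to planted cells by nearest centre
matchToTruth <- function(records, truth) {
  vapply(seq_len(nrow(records)), function(i)
    which.min((truth$row - records$row[i])^2 +
              (truth$col - records$col[i])^2), integer(1))
}

# a scene of well-separated cells with explicit arm counts, for exact
# ring-count recovery
separatedCellScene <- function(seed, arms, dim = c(400L, 400L),
                               relArea = 0.9, noiseSd = 0) {
  sp <- sceneSpec(dim = dim, seed = seed,
                  cells = data.frame(class = "bushy", arms = arms,
                                     rel_area_pct = relArea,
                                     stringsAsFactors = FALSE),
                  minSeparationPx = 120, noiseSd = noiseSd)
  generateScene(sp)
}

# independent Euclidean distance of every pixel to a pixel set (brute
# force; used as the distance-transform oracle on small images)
bruteDistToSet <- function(pix, dm) {
  d <- matrix(Inf, dm[1], dm[2])
  for (r in seq_len(dm[1])) for (c in seq_len(dm[2]))
    d[r, c] <- sqrt(min((pix[, 1] - r)^2 + (pix[, 2] - c)^2))
  d
}
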