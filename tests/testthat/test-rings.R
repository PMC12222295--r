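test_that("unit ring: 1-px nucleus, gap 0, width 1 gives the 8-neighbour shell", {
  z <- buildInfluenceZone(cbind(10L, 10L), dim = c(20L, 20L),
                          gapPx = 0, widthPx = 1)
  ring <- ringPixels(z)
  # pixels at Euclidean distance in [1, 2): the 8 immediate neighbours
  expect_equal(nrow(ring), 8L)
  expect_true(all(abs(ring[, 1] - 10) <= 1 & abs(ring[, 2] - 10) <= 1))
  expect_false(borderClipped(z))
})

test_that("default ring matches a brute-force distance oracle on a disk nucleus", {
  dm <- c(120L, 120L)
  pix <- diskPixels(c(60, 60), 10, dm)
  z <- buildInfluenceZone(pix, dim = dm)
  d <- bruteDistToSet(pix, dm)
  oracle <- which(d >= 10 & d < 24, arr.ind = TRUE)
  expect_equal(nrow(ringPixels(z)), nrow(oracle))
  expect_setequal(paste(ringPixels(z)[, 1], ringPixels(z)[, 2]),
                  paste(oracle[, 1], oracle[, 2]))
  # measured open gap 9 px and radial width 14 px
  dr <- d[ringPixels(z)]
  expect_equal(round(min(dr) - 1), 9)
  expect_equal(round(max(dr) - min(dr)), 14)
  # ring disjoint from the nucleus set
  expect_false(any(paste(ringPixels(z)[, 1], ringPixels(z)[, 2]) %in%
                   paste(pix[, 1], pix[, 2])))
})

test_that("rings near the border are clipped and flagged; degenerate input errors", {
  z <- buildInfluenceZone(cbind(5L, 5L), dim = c(100L, 100L))
  expect_true(borderClipped(z))
  expect_true(all(ringPixels(z)[, 1] >= 1 & ringPixels(z)[, 2] >= 1))
  expect_error(buildInfluenceZone(matrix(integer(0), 0, 2),
                                  dim = c(10L, 10L)), "empty")
  expect_error(buildInfluenceZone(cbind(5L, 5L), dim = c(100L, 100L),
                                  gapPx = -1), "gapPx")
})

test_that("process counting: empty mask, planted radial arms, and a forking branch", {
  dm <- c(200L, 200L)
  ctr <- c(100, 100)
  pix <- diskPixels(ctr, 8, dm)
  z <- buildInfluenceZone(pix, dim = dm)
  expect_equal(countProcesses(z, SegmentationMask(matrix(0L, dm[1], dm[2]))), 0L)

  # 4 straight radial arms longer than gap + width
  gm <- matrix(0L, dm[1], dm[2])
  for (a in c(0.3, 1.8, 3.4, 5.1))
    gm[gliaScore:::.armIdx(ctr, 9, 40, 3, a, dm)] <- 1L
  expect_equal(countProcesses(z, SegmentationMask(gm)), 4L)

  # one connected structure whose two branches cross the ring at
  # distinct places (joined by an arc outside the ring): each crossing
  # is a separate contiguous run within the ring, so the count is 2
  gm2 <- matrix(0L, dm[1], dm[2])
  gm2[gliaScore:::.armIdx(ctr, 9, 30, 3, 0.4, dm)] <- 1L
  gm2[gliaScore:::.armIdx(ctr, 9, 30, 3, 1.0, dm)] <- 1L
  t1 <- ctr + 39 * c(cos(0.4), sin(0.4))
  t2 <- ctr + 39 * c(cos(1.0), sin(1.0))
  ang <- atan2(t2[2] - t1[2], t2[1] - t1[1])
  gm2[gliaScore:::.armIdx(t1, 0, sqrt(sum((t2 - t1)^2)), 3, ang, dm)] <- 1L
  expect_equal(max(gliaScore:::.labelComponents(gm2)), 1L)  # one structure
  expect_equal(countProcesses(z, SegmentationMask(gm2)), 2L)
})

test_that("ring construction is rotation-equivariant for symmetric nuclei", {
  dm <- c(151L, 151L)
  ctr <- c(76, 76)
  pix <- diskPixels(ctr, 7, dm)
  gm <- matrix(0L, dm[1], dm[2])
  for (a in c(0.2, 2.1, 4.0)) gm[gliaScore:::.armIdx(ctr, 8, 45, 3, a, dm)] <- 1L
  z <- buildInfluenceZone(pix, dim = dm)
  n0 <- countProcesses(z, SegmentationMask(gm))
  for (k in 1:3) {
    gm <- t(gm[dm[1]:1, ])   # 90-degree rotation of the scene
    zr <- buildInfluenceZone(diskPixels(ctr, 7, dm), dim = dm)
    expect_equal(countProcesses(zr, SegmentationMask(gm)), n0)
  }
})

test_that("counts are invariant to translating the whole scene", {
  sc <- separatedCellScene(17, arms = c(3, 5))
  gm <- maskMatrix(truthMask(sc, "microglia"))
  nuc <- detectNuclei(truthMask(sc, "nucleus"), truthMask(sc, "microglia"))
  s0 <- scoreMicroglia(nuc, truthMask(sc, "microglia"))
  dm <- dim(gm)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, dm[1], dm[2])
    out[(1 + dr):dm[1], (1 + dc):dm[2]] <- m[1:(dm[1] - dr), 1:(dm[2] - dc)]
    out
  }
  nmS <- SegmentationMask(shift(maskMatrix(truthMask(sc, "nucleus")), 9, 4))
  gmS <- SegmentationMask(shift(gm, 9, 4))
  s1 <- scoreMicroglia(detectNuclei(nmS, gmS), gmS)
  expect_equal(sort(s1$process_count), sort(s0$process_count))
})

test_that("planted straight-arm counts are recovered exactly across 100 seeds", {
  totalCells <- 0L; exact <- 0L
  for (s in 1:100) {
    set.seed(s)
    arms <- sample(0:6, 2, replace = TRUE)
    sc <- separatedCellScene(2000 + s, arms = arms, dim = c(400L, 400L))
    nuc <- detectNuclei(truthMask(sc, "nucleus"), truthMask(sc, "microglia"))
    sco <- scoreMicroglia(nuc, truthMask(sc, "microglia"))
    m <- matchToTruth(sco, truthCells(sc))
    totalCells <- totalCells + nrow(sco)
    exact <- exact + sum(sco$process_count == truthCells(sc)$arms[m])
  }
  expect_equal(exact, totalCells)
  expect_gte(totalCells, 190L)
})

test_that("scoring returns one record per nucleus and the image mean is the arithmetic mean", {
  sc <- separatedCellScene(29, arms = c(1, 6))
  gm <- truthMask(sc, "microglia")
  nuc <- detectNuclei(truthMask(sc, "nucleus"), gm)
  sco <- scoreMicroglia(nuc, gm)
  expect_equal(nrow(sco), nrow(nuc))
  expect_true(all(is.na(sco$activity_class)))
  expect_equal(mean(sco$process_count),
               sum(sco$process_count) / nrow(sco))
  empty <- scoreMicroglia(nuc[0, ], gm)
  expect_equal(nrow(empty), 0L)
})
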