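test_that("feature extraction behaves on degenerate and constructed images", {
  # constant image -> every pixel's feature vector is identical
  pr <- Projection(list(microglia = matrix(0.4, 12, 12)))
  f <- extractFeatures(pr, "microglia")
  expect_true(all(apply(f, 2, function(v) diff(range(v)) == 0)))
  expect_equal(unname(f[1, "raw"]), 0.4)
  expect_equal(unname(f[1, "localvar"]), 0)

  # step edge -> gradient magnitude maximal on the edge columns
  m <- cbind(matrix(0, 10, 5), matrix(1, 10, 5))
  fe <- extractFeatures(Projection(list(microglia = m)), "microglia")
  grad <- matrix(fe[, "gradmag"], 10, 10)
  expect_true(all(which(grad == max(grad), arr.ind = TRUE)[, 2] %in% 5:6))

  # smoothing converges to the identity as sigma -> 0: the sigma-1
  # feature of a smooth ramp stays close to raw, closer than sigma-2
  ramp <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  fr <- extractFeatures(Projection(list(microglia = ramp)), "microglia")
  inner <- as.vector(matrix(seq_len(400), 20, 20)[5:16, 5:16])
  err1 <- max(abs(fr[inner, "gauss1"] - fr[inner, "raw"]))
  err2 <- max(abs(fr[inner, "gauss2"] - fr[inner, "raw"]))
  expect_lt(err1, 0.01)
  expect_lte(err1, err2)

  expect_error(extractFeatures(pr, "astrocyte"), "absent")
})

test_that("classifier separates a separable image perfectly and reproducibly", {
  m <- matrix(0.1, 30, 30)
  m[10:20, 10:20] <- 0.9
  pr <- Projection(list(microglia = m))
  f <- extractFeatures(pr, "microglia")
  # scribbles cover interior, object boundary and the adjacent halo, as
  # a user tracing the structure would mark them
  obj <- rbind(cbind(12:16, 12:16), cbind(rep(10, 6), 10:15),
               cbind(rep(20, 6), 15:20), cbind(10:15, rep(20, 6)))
  bg <- rbind(cbind(2:6, 2:6), cbind(rep(9, 6), 9:14),
              cbind(rep(21, 6), 15:20), cbind(10:15, rep(21, 6)),
              cbind(25:29, 5:9))
  scr <- scribbleSet(row = c(obj[, 1], bg[, 1]), col = c(obj[, 2], bg[, 2]),
                     class = rep(c("object", "background"),
                                 c(nrow(obj), nrow(bg))),
                     channel = "microglia")
  mod <- trainPixelClassifier(f, scr, seed = 5)
  expect_equal(mod@training$accuracy, 1.0)
  mask <- segmentChannel(pr, mod)
  truth <- matrix(0L, 30, 30); truth[10:20, 10:20] <- 1L
  expect_equal(maskMatrix(mask), truth)
  expect_equal(minObjectSize(mask), 0L)

  # bit-exact retrain with identical scribbles and seed
  mod2 <- trainPixelClassifier(f, scr, seed = 5)
  expect_identical(maskMatrix(segmentChannel(pr, mod2)), maskMatrix(mask))

  # single-class scribbles violate the precondition
  expect_error(trainPixelClassifier(
    f, scribbleSet(1:4, 1:4, rep("object", 4), "microglia"), seed = 1),
    "both")
  expect_error(trainPixelClassifier(
    f, scribbleSet(31, 1, "object", "microglia"), seed = 1), "outside")
})

test_that("overlapping-class training tracks a nearest-centroid oracle", {
  set.seed(31)
  n <- 200
  # object and background intensities with substantially overlapping
  # supports; constant-texture fields so intensity is the only signal
  objv <- rnorm(n, 0.60, 0.15)
  bgv <- rnorm(n, 0.40, 0.15)
  m <- matrix(0.5, 40, 40)
  # disjoint pixel sets interleaved over the whole field, so intensity
  # is the only class signal
  pick <- sample(1600, 2 * n)
  oidx <- arrayInd(pick[1:n], c(40, 40))
  bidx <- arrayInd(pick[(n + 1):(2 * n)], c(40, 40))
  m[oidx] <- objv; m[bidx] <- bgv
  pr <- Projection(list(microglia = m))
  f <- extractFeatures(pr, "microglia")
  scr <- scribbleSet(c(oidx[, 1], bidx[, 1]), c(oidx[, 2], bidx[, 2]),
                     rep(c("object", "background"), each = n), "microglia")
  mod <- trainPixelClassifier(f, scr, seed = 2)
  # oracle: classify each scribbled pixel by the nearer class-mean raw
  # intensity; the ensemble's out-of-bag accuracy (its honest accuracy
  # estimate) must track it
  co <- mean(objv); cb <- mean(bgv)
  oracleAcc <- mean(c(abs(objv - co) < abs(objv - cb),
                      abs(bgv - cb) < abs(bgv - co)))
  expect_lt(abs(mod@training$oobAccuracy - oracleAcc), 0.05)
})

test_that("small-object filter applies a strictly-below threshold", {
  # horizontal bars of 23 and 24 px, min size 24
  m <- matrix(0L, 10, 40)
  m[2, 1:23] <- 1L
  m[6, 1:24] <- 1L
  out <- maskMatrix(filterSmallObjects(SegmentationMask(m), minSize = 24))
  expect_equal(sum(out[2, ]), 0)    # 23 px removed
  expect_equal(sum(out[6, ]), 24)   # 24 px retained
  # min size 0 leaves any mask unchanged
  expect_equal(maskMatrix(filterSmallObjects(SegmentationMask(m), 0)), m)
  expect_error(filterSmallObjects(SegmentationMask(m), -1), ">= 0")
})

test_that("filtering is idempotent and every surviving component is large enough", {
  set.seed(12)
  m <- matrix(rbinom(120 * 120, 1, 0.35), 120, 120)
  f1 <- filterSmallObjects(SegmentationMask(m), minSize = 10)
  f2 <- filterSmallObjects(f1, minSize = 10)
  expect_identical(maskMatrix(f1), maskMatrix(f2))
  lab <- gliaScore:::.labelComponents(maskMatrix(f1))
  if (max(lab) > 0)
    expect_true(all(gliaScore:::.componentSizes(lab) >= 10))
})

test_that("diagonally touching pixels form one 8-connected component", {
  m <- matrix(0L, 6, 6)
  m[cbind(1:4, 1:4)] <- 1L   # a pure diagonal
  lab <- gliaScore:::.labelComponents(m)
  expect_equal(max(lab), 1L)
  # under the strictly-below rule the 4-px diagonal survives minSize 4
  out <- filterSmallObjects(SegmentationMask(m), minSize = 4)
  expect_equal(sum(maskMatrix(out)), 4)
})

test_that("area fraction has the right bounds and is monotone under union", {
  dm <- c(20, 20)
  expect_equal(areaFraction(SegmentationMask(matrix(0L, 20, 20))), 0)
  expect_equal(areaFraction(SegmentationMask(matrix(1L, 20, 20))), 100)
  half <- matrix(0L, 20, 20); half[, 1:10] <- 1L
  expect_equal(areaFraction(SegmentationMask(half)), 50)
  set.seed(5)
  for (k in 1:20) {
    a <- matrix(rbinom(400, 1, runif(1)), 20, 20)
    b <- matrix(rbinom(400, 1, runif(1)), 20, 20)
    u <- pmax(a, b)
    expect_gte(areaFraction(SegmentationMask(u)),
               areaFraction(SegmentationMask(a)))
    expect_lte(areaFraction(SegmentationMask(a)), 100)
  }
})

test_that("segmentation of a synthetic scene recovers the planted raster and area fraction", {
  sp <- sceneSpec(dim = c(256, 256), seed = 21,
                  cells = data.frame(class = rep("bushy", 4), arms = 3,
                                     rel_area_pct = 1.2),
                  nAstrocyteFilaments = 0)
  sc <- generateScene(sp)
  pr <- sc@projection
  mod <- trainPixelClassifier(extractFeatures(pr, "microglia"),
                              truthScribbles(sc, "microglia"), seed = 4)
  mask <- filterSmallObjects(segmentChannel(pr, mod))
  truth <- truthMask(sc, "microglia")
  agree <- mean(maskMatrix(mask) == maskMatrix(truth))
  expect_gte(agree, 0.95)
  expect_lt(abs(areaFraction(mask) - areaFraction(truth)), 2)
})

test_that("scribbles read back from CSV", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "marks.csv")
  write.csv(data.frame(x = c(3, 4), y = c(5, 6),
                       class = c("object", "background"),
                       channel = "microglia"), path, row.names = FALSE)
  s <- readScribbles(path)
  expect_equal(s$row, c(5L, 6L))
  expect_equal(s$col, c(3L, 4L))
})
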