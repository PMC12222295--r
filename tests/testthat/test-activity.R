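test_that("state intervals: zero-variance and closed-form t-interval cases", {
  # constant samples give a degenerate CI at the value
  st <- fitStateIntervals(rep(0.3, 5), rep("bushy", 5))
  expect_equal(st$mean, 0.3)
  expect_equal(st$ci_low, 0.3)
  expect_equal(st$ci_high, 0.3)

  # n = 4 hand-computed t-interval: mean 0.25 +/- t(0.975,3) * s / 2
  st4 <- fitStateIntervals(c(0.1, 0.2, 0.3, 0.4), rep("amoeboid", 4))
  expect_equal(st4$mean, 0.25)
  expect_equal(st4$ci_low, 0.0445740, tolerance = 1e-6)
  expect_equal(st4$ci_high, 0.4554260, tolerance = 1e-6)

  expect_error(fitStateIntervals(c(0.1, 0.2, 0.3), c("a", "a", "b")),
               "at least 2")
})

test_that("samples drawn at the calibration parameters are fitted within the printed CIs", {
  pars <- classAreaParameters()
  ref <- referenceNucleusAreaStates()
  set.seed(77)
  vals <- c(); labs <- c()
  for (i in seq_len(nrow(pars))) {
    vals <- c(vals, rnorm(pars$n[i], pars$mean[i], pars$sd[i]))
    labs <- c(labs, rep(pars$label[i], pars$n[i]))
  }
  fit <- fitStateIntervals(vals, labs)
  for (i in seq_len(nrow(ref))) {
    f <- fit[fit$label == ref$label[i], ]
    # the fitted CI must overlap the printed CI and the fitted mean
    # must sit close to the printed mean
    expect_lte(f$ci_low, ref$ci_high[i])
    expect_gte(f$ci_high, ref$ci_low[i])
    expect_lt(abs(f$mean - ref$mean[i]), 0.06)
  }
})

test_that("CI-overlap merging yields three groups on the calibration table", {
  cls <- mergeOverlapping(referenceNucleusAreaStates())
  g <- activityGroups(cls)
  expect_equal(nrow(g), 3L)
  expect_equal(g$label[1], "hyper_ramified+ramified")
  expect_setequal(g$members[[1]], c("ramified", "hyper_ramified"))
  expect_equal(g$label[2:3], c("bushy", "amoeboid"))
  # boundaries at the midpoints of the inter-interval gaps
  expect_equal(decisionBoundaries(cls), c((0.25 + 0.39) / 2,
                                          (0.44 + 0.59) / 2))
})

test_that("merging handles disjoint and identical intervals, is idempotent and order-independent", {
  four <- data.frame(label = letters[1:4], n = rep(10L, 4),
                     mean = c(1, 2, 3, 4), ci_low = c(0.9, 1.9, 2.9, 3.9),
                     ci_high = c(1.1, 2.1, 3.1, 4.1))
  expect_equal(nrow(activityGroups(mergeOverlapping(four))), 4L)

  same <- transform(four, ci_low = 0.5, ci_high = 4.5)
  expect_equal(nrow(activityGroups(mergeOverlapping(same))), 1L)

  # order independence
  cls1 <- mergeOverlapping(referenceNucleusAreaStates())
  cls2 <- mergeOverlapping(referenceNucleusAreaStates()[c(3, 1, 4, 2), ])
  expect_equal(activityGroups(cls1)$label, activityGroups(cls2)$label)
  expect_equal(decisionBoundaries(cls1), decisionBoundaries(cls2))

  # idempotence: merging the merged groups changes nothing
  g <- activityGroups(cls1)
  again <- mergeOverlapping(data.frame(label = g$label, n = g$n,
                                       mean = (g$low + g$high) / 2,
                                       ci_low = g$low, ci_high = g$high))
  expect_equal(nrow(activityGroups(again)), nrow(g))
})

test_that("cells classify into the expected merged groups, with midpoint tie to the lower group", {
  cls <- mergeOverlapping(referenceNucleusAreaStates())
  expect_equal(classifyCell(0.70, cls), "amoeboid")
  expect_equal(classifyCell(0.41, cls), "bushy")
  expect_equal(classifyCell(0.32, cls), "hyper_ramified+ramified")
  # extremes clamp to the end groups
  expect_equal(classifyCell(0.01, cls), "hyper_ramified+ramified")
  expect_equal(classifyCell(5, cls), "amoeboid")
  expect_error(classifyCell(NA_real_, cls), "finite")
  # total monotone step function
  x <- seq(0.05, 1.2, by = 0.01)
  lab <- classifyCell(x, cls)
  ord <- match(lab, activityGroups(cls)$label)
  expect_true(all(diff(ord) >= 0))
})

test_that("classifier survives a JSON round trip", {
  cls <- mergeOverlapping(referenceNucleusAreaStates())
  path <- file.path(withr::local_tempdir(), "classifier.json")
  classifierToJSON(cls, path)
  back <- classifierFromJSON(path)
  expect_equal(activityGroups(back)$label, activityGroups(cls)$label)
  expect_equal(decisionBoundaries(back), decisionBoundaries(cls))
  expect_equal(classifyCell(c(0.2, 0.41, 0.7), back),
               classifyCell(c(0.2, 0.41, 0.7), cls))
})

test_that("nonparametric validation is calibrated under the null and powered under separation", {
  # identical-distribution groups: p approximately uniform across seeds
  set.seed(5)
  ps <- replicate(200, {
    v <- rnorm(40, 0.4, 0.1)
    validateSeparation(v, rep(c("a", "b"), each = 20))$pairwise$p[1]
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  expect_gt(mean(ps > 0.5), 0.3)

  # disjoint supports at n = 20: decisive rejection
  set.seed(6)
  v <- c(runif(20, 0.1, 0.2), runif(20, 0.6, 0.8))
  rep2 <- validateSeparation(v, rep(c("lo", "hi"), each = 20))
  expect_lt(rep2$pairwise$p[1], 0.01)
  expect_lt(rep2$kruskal$p.value, 0.01)

  expect_error(validateSeparation(rnorm(10), rep("a", 10)), ">= 2 states")
  expect_error(validateSeparation(rep(1, 10), rep(c("a", "b"), 5)),
               "tied")
})

test_that("cells planted at calibration class means end in the planted merged group end-to-end", {
  cls <- mergeOverlapping(referenceNucleusAreaStates())
  pars <- classAreaParameters()
  groupOf <- function(lab)
    activityGroups(cls)$label[vapply(activityGroups(cls)$members,
                                     function(m) lab %in% m, logical(1))]
  hits <- 0L; total <- 0L
  for (s in 1:50) {
    lab <- pars$label[(s %% 4) + 1]
    sp <- sceneSpec(dim = c(420, 420), seed = 4000 + s,
                    cells = data.frame(class = lab,
                                       rel_area_pct = pars$mean[pars$label == lab],
                                       arms = 2)[rep(1, 3), ],
                    minSeparationPx = 110)
    sc <- generateScene(sp)
    rec <- detectNuclei(truthMask(sc, "nucleus"), truthMask(sc, "microglia"))
    got <- classifyCell(rec$relative_area_pct, cls)
    total <- total + nrow(rec)
    hits <- hits + sum(got == groupOf(lab))
  }
  expect_gte(hits / total, 0.95)
})
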