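test_that("Otsu threshold separates a bimodal image and matches the brute-force oracle", {
  v <- c(rep(10, 50), rep(100, 50))
  img <- intensityImage(matrix(v, 10, 10), "NADPH")
  t <- thresholdOtsu(img)
  expect_gt(t, 10); expect_lt(t, 100)
  expect_equal(t, oracleOtsu(v))
  expect_error(thresholdOtsu(intensityImage(matrix(5, 3, 3), "FAD")),
               "constant")
  for (seed in 1:20) {
    set.seed(seed)
    v <- sample(0:30, 60, replace = TRUE)
    expect_equal(thresholdOtsu(v), oracleOtsu(v))
    expect_gt(thresholdOtsu(v), min(v))
    expect_lt(thresholdOtsu(v), max(v))
  }
})

test_that("minimum-cross-entropy threshold matches its oracle and scales with the correction factor", {
  v <- c(rep(10, 50), rep(100, 50))
  img <- intensityImage(matrix(v, 10, 10), "TMRE")
  t1 <- thresholdMinCrossEntropy(img, 1)
  expect_gt(t1, 10); expect_lt(t1, 100)
  expect_equal(thresholdMinCrossEntropy(img, 2), 2 * t1)
  expect_equal(t1, oracleLi(v))
  expect_error(thresholdMinCrossEntropy(img, 0), "positive")
  expect_error(
    thresholdMinCrossEntropy(intensityImage(matrix(5, 3, 3), "TMRE")),
    "constant")
  for (seed in 1:20) {
    set.seed(100 + seed)
    v <- sample(1:40, 80, replace = TRUE)
    t <- thresholdMinCrossEntropy(v)
    expect_equal(t, oracleLi(v))
    expect_gt(t, min(v)); expect_lt(t, max(v))
    f <- runif(1, 0.5, 3)
    expect_equal(thresholdMinCrossEntropy(v, f), f * t)
  }
})

test_that("threshold specs dispatch to the named method with its factor", {
  v <- c(rep(2, 30), rep(20, 30))
  expect_equal(applyThresholdSpec(thresholdSpec("otsu", 2), v),
               2 * thresholdOtsu(v))
  expect_equal(
    applyThresholdSpec(thresholdSpec("min_cross_entropy", 2), v),
    thresholdMinCrossEntropy(v, 2))
  expect_equal(
    applyThresholdSpec(thresholdSpec("manual", 3, manualValue = 5), v),
    15)
  expect_error(thresholdSpec("manual"), "manualValue")
})

test_that("propagation fills a single component from one seed", {
  seeds <- matrix(0L, 8, 8); seeds[4, 4] <- 1L
  fg <- matrix(FALSE, 8, 8); fg[2:7, 2:7] <- TRUE
  guide <- intensityImage(matrix(1, 8, 8), "TMRE")
  out <- labels2d(propagateCells(labelImage(seeds), guide, fg))
  expect_true(all(out[fg] == 1L))
  expect_true(all(out[!fg] == 0L))
})

test_that("two symmetric seeds split a uniform strip at the midline, ties to the lower label", {
  seeds <- matrix(0L, 3, 9)
  seeds[2, 2] <- 1L; seeds[2, 8] <- 2L
  fg <- matrix(TRUE, 3, 9)
  guide <- intensityImage(matrix(5, 3, 9), "TMRE")
  out <- labels2d(propagateCells(labelImage(seeds), guide, fg))
  expect_true(all(out[, 1:4] == 1L))
  expect_true(all(out[, 6:9] == 2L))
  expect_true(all(out[, 5] == 1L))    # equidistant column: lower label
  expect_equal(out, oracleDijkstra(seeds, pixels(guide), fg, 0.05))
})

test_that("propagation labels match the Dijkstra geodesic oracle on random scenes", {
  for (seed in 1:10) {
    sc <- randomPropagationScene(seed)
    got <- labels2d(propagateCells(labelImage(sc$seeds),
                                   intensityImage(sc$guide, "TMRE"),
                                   sc$fg, regularization = 0.05))
    expect_equal(got, oracleDijkstra(sc$seeds, sc$guide, sc$fg, 0.05),
                 info = paste("scene", seed))
  }
})

test_that("propagation output partitions the reachable foreground and keeps seeds", {
  for (lambda in c(0, 0.05, 1, 10)) {
    sc <- randomPropagationScene(99)
    out <- labels2d(propagateCells(labelImage(sc$seeds),
                                   intensityImage(sc$guide, "TMRE"),
                                   sc$fg, regularization = lambda))
    # seeds never detach from their own label
    expect_true(all(out[sc$seeds > 0] == sc$seeds[sc$seeds > 0]))
    # non-foreground stays background
    expect_true(all(out[!(sc$fg | sc$seeds > 0)] == 0L))
  }
  expect_error(propagateCells(labelImage(matrix(0L, 4, 4)),
                              intensityImage(matrix(1, 4, 4), "TMRE"),
                              matrix(TRUE, 4, 4)), "no objects")
})

test_that("cytoplasm is the cell minus its nucleus, labels preserved", {
  ce <- matrix(0L, 7, 7); ce[2:6, 2:6] <- 4L
  nu <- matrix(0L, 7, 7); nu[3:5, 3:5] <- 4L
  cy <- labels2d(deriveCytoplasm(labelImage(ce), labelImage(nu)))
  expect_equal(sum(cy == 4L), 16L)              # 5x5 minus 3x3 ring
  expect_true(all(cy[nu > 0] == 0L))

  # nuclei identical to cells -> empty cytoplasm
  cy2 <- labels2d(deriveCytoplasm(labelImage(ce), labelImage(ce)))
  expect_true(all(cy2 == 0L))

  # disjoint nucleus id errors; stray nucleus pixel warns and clips
  nuBad <- nu; nuBad[1, 1] <- 9L
  expect_error(deriveCytoplasm(labelImage(ce), labelImage(nuBad)),
               "no matching cell")
  nuStray <- nu; nuStray[1, 1] <- 4L
  expect_warning(cyS <- deriveCytoplasm(labelImage(ce),
                                        labelImage(nuStray)),
                 "outside")
  expect_equal(labels2d(cyS), cy)
})

test_that("mitochondrial masking keeps cytoplasm pixels at or above the global threshold", {
  ce <- matrix(0L, 9, 9); ce[2:8, 2:8] <- 1L
  nu <- matrix(0L, 9, 9); nu[4:6, 4:6] <- 1L
  cy <- labels2d(deriveCytoplasm(labelImage(ce), labelImage(nu)))

  # uniform TMRE above a manual threshold: mask = cytoplasm
  tm <- intensityImage(matrix(50, 9, 9), "TMRE")
  hi <- maskMitochondria(labelImage(cy), tm,
                         thresholdSpec("manual", manualValue = 10))
  expect_equal(labels2d(hi), cy)
  expect_length(attr(hi, "empty_cells"), 0)

  # uniform TMRE below the threshold: all cells flagged empty
  lo <- maskMitochondria(labelImage(cy), tm,
                         thresholdSpec("manual", manualValue = 100))
  expect_true(all(labels2d(lo) == 0L))
  expect_equal(attr(lo, "empty_cells"), 1L)

  # bright puncta on a dim cytosol: mask = puncta within cytoplasm
  tmv <- matrix(10, 9, 9)
  puncta <- matrix(FALSE, 9, 9)
  puncta[c(2, 3, 7), c(2, 6)] <- TRUE
  tmv[puncta] <- 200
  mi <- maskMitochondria(labelImage(cy),
                         intensityImage(tmv, "TMRE"),
                         thresholdSpec("otsu"))
  expect_equal(labels2d(mi) > 0, puncta & cy > 0)
  # constant TMRE with a computed method propagates the threshold error
  expect_error(maskMitochondria(labelImage(cy), tm,
                                thresholdSpec("otsu")), "constant")
})

test_that("compartment measurement reduces to per-object count, mean and integral", {
  l <- matrix(0L, 4, 4); l[1, 1:4] <- 1L
  img <- intensityImage(matrix(0, 4, 4), "TMRE")
  img@pixels[1, ] <- c(1, 2, 3, 4)
  m <- measureCompartments(labelImage(l), img)
  expect_equal(m$n_pixels, 4L)
  expect_equal(m$mean, 2.5)
  expect_equal(m$integrated, 10)

  # empty label set gives an empty table
  empty <- measureCompartments(labelImage(matrix(0L, 3, 3)),
                               intensityImage(matrix(1, 3, 3), "FAD"))
  expect_equal(nrow(empty), 0L)

  # agreement with per-pixel accumulation on random scenes, and rows
  # independent across disjoint objects
  set.seed(5)
  lab <- matrix(sample(0:4, 100, replace = TRUE), 10, 10)
  vals <- matrix(runif(100, 0, 9), 10, 10)
  m2 <- measureCompartments(labelImage(lab),
                            intensityImage(vals, "NADPH"))
  for (k in 1:4) {
    expect_equal(m2$integrated[m2$object_id == k],
                 sum(vals[lab == k]))
    expect_equal(m2$mean[m2$object_id == k], mean(vals[lab == k]))
  }
})

test_that("segmentation results enforce the structural compartment contract", {
  nu <- matrix(0L, 6, 6); nu[2:3, 2:3] <- 1L
  ce <- matrix(0L, 6, 6); ce[1:5, 1:5] <- 1L
  cy <- ce; cy[nu > 0] <- 0L
  mi <- matrix(0L, 6, 6); mi[5, 5] <- 1L
  expect_s4_class(segmentationResult(labelImage(nu), labelImage(ce),
                                     labelImage(cy), labelImage(mi)),
                  "SegmentationResult")
  # nucleus outside its cell
  nuBad <- nu; nuBad[6, 6] <- 1L
  expect_error(segmentationResult(labelImage(nuBad), labelImage(ce),
                                  labelImage(cy), labelImage(mi)),
               "nucleus pixel")
  # mitochondria outside the cytoplasm
  miBad <- mi; miBad[2, 2] <- 1L
  expect_error(segmentationResult(labelImage(nu), labelImage(ce),
                                  labelImage(cy), labelImage(miBad)),
               "mitochondria")
  # cytoplasm not equal to cell minus nucleus
  expect_error(segmentationResult(labelImage(nu), labelImage(ce),
                                  labelImage(ce), labelImage(mi)),
               "cytoplasm")
})
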