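test_that("cell scenes are deterministic under a fixed seed", {
  cfg <- simConfig(seed = 3, imageSize = 96, nCells = 4)
  a <- generateCellScene(cfg)
  b <- generateCellScene(cfg)
  expect_identical(pixels(channels(a)$nadph), pixels(channels(b)$nadph))
  expect_identical(pixels(channels(a)$tmre), pixels(channels(b)$tmre))
  expect_identical(labels2d(cells(segmentation(a))),
                   labels2d(cells(segmentation(b))))
  expect_identical(truth(a), truth(b))
})

test_that("scene ground truth follows the inverse Nernst relation", {
  # delta psi of -61.5 at rt 61.5 means a tenfold TMRE accumulation
  sc <- generateCellScene(simConfig(seed = 5, imageSize = 96,
                                    nCells = 4, deltaPsi = -61.5))
  expect_equal(truth(sc)$fi_m / truth(sc)$fi_n, rep(10, 4))
  # zero potential: mitochondrial and nuclear means equal
  sc0 <- generateCellScene(simConfig(seed = 5, imageSize = 96,
                                     nCells = 4, deltaPsi = 0))
  expect_equal(truth(sc0)$fi_m, truth(sc0)$fi_n)
  # per-cell ORR truth is the ratio of the generating channel means
  expect_equal(truth(sc)$orr, truth(sc)$i_nadph / truth(sc)$i_fad)
})

test_that("ground-truth masks always satisfy the segmentation contract", {
  for (seed in 1:4) {
    sc <- generateCellScene(simConfig(seed = seed, imageSize = 128,
                                      nCells = 8))
    seg <- segmentation(sc)
    expect_true(validObject(seg))       # nucleus/cell/cyto/mito contract
    expect_equal(sort(unique(as.vector(labels2d(cells(seg))))),
                 0:8)
    # every cell has mitochondrial pixels to measure
    expect_equal(sort(setdiff(unique(as.vector(
      labels2d(mitochondria(seg)))), 0L)), 1:8)
  }
})

test_that("scene channel images carry Poisson counts around the configured means", {
  cfg <- simConfig(seed = 8, imageSize = 128, nCells = 6, cellCV = 0)
  sc <- generateCellScene(cfg)
  seg <- segmentation(sc)
  cy <- labels2d(cytoplasm(seg)) > 0 &
    labels2d(mitochondria(seg)) == 0
  bg <- labels2d(cells(seg)) == 0
  nadph <- pixels(channels(sc)$nadph)
  expect_true(all(nadph == round(nadph)))
  expect_lt(abs(mean(nadph[bg]) - cfg@background), 0.2)
  # cytosolic NAD(P)H close to the configured baseline (no cell CV)
  expect_lt(abs(mean(nadph[cy]) / cfg@baselineNadph - 1), 0.05)
  tmre <- pixels(channels(sc)$tmre)
  mito <- labels2d(mitochondria(seg)) > 0
  expect_lt(abs(mean(tmre[mito]) / (cfg@baselineTmre * 10) - 1), 0.05)
})

test_that("plate generators return exact percents at zero noise", {
  w <- generatePlateTable("wst1", c(control = 0.8, treated = 0.528),
                          nReplicates = 4L, noiseSd = 0, seed = 1)
  res <- wst1PercentViability(w)
  expect_equal(res$percent_of_control[res$condition == "treated"], 66)
  cnt <- generatePlateTable("count", c(control = 300, treated = 232),
                            nReplicates = 4L, noiseSd = 0,
                            baselineMean = 100, seed = 1)
  g <- cellCountPercentOfControl(cnt[cnt$role == "sample", ],
                                 cnt$count[cnt$role == "baseline"])
  expect_equal(g$percent_of_control[g$condition == "treated"], 66)
  cyt <- generatePlateTable("cytoid", c(control = 0.1, treated = 0.13),
                            nReplicates = 4L, noiseSd = 0, seed = 1)
  expect_equal(cytoidNormalized(cyt)$conditions$mean_value,
               c(0.1, 0.13))
  # determinism
  expect_identical(w, generatePlateTable("wst1",
    c(control = 0.8, treated = 0.528), nReplicates = 4L, noiseSd = 0,
    seed = 1))
})

test_that("WST-1 percent recovery stays within sampling error at realistic noise", {
  sdw <- 0.02; nrep <- 16L
  set.seed(17)
  pct <- replicate(30, {
    w <- generatePlateTable("wst1", c(control = 0.8, treated = 0.528),
                            nReplicates = nrep, noiseSd = sdw,
                            seed = sample.int(1e6, 1))
    r <- wst1PercentViability(w)
    r$percent_of_control[r$condition == "treated"]
  })
  expect_gt(sd(pct), 0)                 # distinct seeds, distinct draws
  se <- sd(pct) / sqrt(length(pct))
  expect_lt(abs(mean(pct) - 66), 4 * se + 0.5)
})

test_that("group-sample generation is seeded and honors configured shifts", {
  g <- generateGroupSamples(c(control = 0, a = 0, b = 10), n = 30,
                            sd = 1, seed = 2)
  expect_identical(g, generateGroupSamples(c(control = 0, a = 0, b = 10),
                                           n = 30, sd = 1, seed = 2))
  dt <- dunnettTest(g, control = "control", alpha = 0.01)
  expect_true(dt$significant[dt$comparison == "b - control"])
  expect_false(dt$significant[dt$comparison == "a - control"])
  # null p-values look uniform across seeds (coarse calibration check)
  ps <- vapply(1:40, function(s) {
    gs <- generateGroupSamples(c(control = 0, t = 0), n = 10, seed = s)
    anovaOneway(gs)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 1e-3)
})
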