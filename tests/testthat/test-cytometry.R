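test_that("percent positive counts DAPI objects sharing pixels with marker objects", {
  sc <- generateColocScene(nDapi = 20L, nPositiveKi67 = 7L,
                           nPositiveCc3 = 0L, seed = 4)
  res <- percentPositive(sc$dapi, sc$ki67)
  expect_equal(res$n_total, 20L)
  expect_equal(res$n_positive, 7L)
  expect_equal(res$pct, 35)

  # no marker objects -> 0 %; marker covering everything -> 100 %
  expect_equal(percentPositive(sc$dapi, sc$cc3)$pct, 0)
  full <- labelImage(matrix(1L, nrow(labels2d(sc$dapi)),
                            ncol(labels2d(sc$dapi))))
  expect_equal(percentPositive(sc$dapi, full)$pct, 100)
  empty <- labelImage(matrix(0L, 4, 4))
  expect_error(percentPositive(empty, empty), "no DAPI")
})

test_that("adding marker pixels never decreases the percent positive", {
  sc <- generateColocScene(nDapi = 16L, nPositiveKi67 = 5L,
                           nPositiveCc3 = 0L, seed = 9)
  base <- percentPositive(sc$dapi, sc$ki67)$pct
  grown <- labels2d(sc$ki67)
  d <- labels2d(sc$dapi)
  grown[d > 0 & grown == 0L] <- d[d > 0 & grown == 0L]  # cover all
  expect_gte(percentPositive(sc$dapi, labelImage(grown))$pct, base)
  expect_equal(percentPositive(sc$dapi, labelImage(grown))$pct, 100)
})

test_that("colocalization summary reports both markers against one DAPI set", {
  sc <- generateColocScene(nDapi = 10L, nPositiveKi67 = 4L,
                           nPositiveCc3 = 2L, seed = 2)
  s <- colocSummary(sc$dapi, sc$ki67, sc$cc3)
  expect_equal(s$n_dapi, 10L)
  expect_equal(s$pct_ki67, 40)
  expect_equal(s$pct_cc3, 20)
})

test_that("cell growth percent subtracts baseline and references control", {
  post <- data.frame(condition = rep(c("control", "treated"), each = 3),
                     count = c(300, 300, 300, 232, 232, 232))
  res <- cellCountPercentOfControl(post, baselineCounts = rep(100, 4))
  expect_equal(res$percent_of_control[res$condition == "control"], 100)
  expect_equal(res$percent_of_control[res$condition == "treated"], 66)

  # post equal to baseline -> zero net growth; below -> negative
  post2 <- data.frame(condition = c("control", "control", "dead", "dead"),
                      count = c(300, 300, 80, 80))
  res2 <- cellCountPercentOfControl(post2, rep(100, 4))
  expect_equal(res2$percent_of_control[res2$condition == "dead"], -10)
  expect_error(cellCountPercentOfControl(post, numeric(0)), "empty")
})

test_that("WST-1 viability subtracts phenol-red and blank backgrounds", {
  mkwells <- function(ctrlSig, trtSig) {
    rbind(data.frame(condition = "control", replicate = 1:4,
                     role = "sample", a450 = 0.05 + 0.1 + ctrlSig,
                     a650 = 0.05),
          data.frame(condition = "treated", replicate = 1:4,
                     role = "sample", a450 = 0.05 + 0.1 + trtSig,
                     a650 = 0.05),
          data.frame(condition = "blank", replicate = 1:4,
                     role = "blank", a450 = 0.15, a650 = 0.05))
  }
  res <- wst1PercentViability(mkwells(0.8, 0.8))
  expect_equal(res$percent_of_control, c(100, 100))
  res2 <- wst1PercentViability(mkwells(0.8, 0.8 * 0.66))
  expect_equal(res2$percent_of_control[res2$condition == "treated"], 66)
  expect_equal(res2$corrected_signal[res2$condition == "control"], 0.8)
  noBlank <- mkwells(0.8, 0.5)
  noBlank <- noBlank[noBlank$role != "blank", ]
  expect_error(wst1PercentViability(noBlank), "blank")
})

test_that("CytoID normalization divides by Hoechst and is scale invariant", {
  w <- data.frame(condition = rep(c("a", "b"), each = 3),
                  replicate = rep(1:3, 2),
                  cytoid = c(10, 10, 10, 30, 30, 30),
                  hoechst = c(10, 10, 10, 20, 20, 20))
  res <- cytoidNormalized(w)
  expect_equal(res$conditions$mean_value, c(1, 1.5))
  w2 <- w; w2$cytoid <- 2 * w$cytoid; w2$hoechst <- 2 * w$hoechst
  expect_equal(cytoidNormalized(w2)$conditions$mean_value,
               res$conditions$mean_value)
  w3 <- w; w3$hoechst[1] <- 0
  expect_error(cytoidNormalized(w3), "> 0")
})

test_that("senescence percent is the positive fraction of counted cells", {
  expect_equal(senescencePercent(0, 50), 0)
  expect_equal(senescencePercent(28, 100), 28)
  expect_equal(senescencePercent(2, 8), 25)
  expect_error(senescencePercent(3, 0), "> 0")
  expect_error(senescencePercent(9, 8), "0, total")
})

test_that("plate reductions are invariant to well ordering", {
  set.seed(77)
  w <- generatePlateTable("wst1", c(control = 0.8, treated = 0.5),
                          nReplicates = 6L, noiseSd = 0.02, seed = 3)
  shuf <- w[sample(nrow(w)), ]
  expect_equal(wst1PercentViability(shuf), wst1PercentViability(w))
  cnt <- generatePlateTable("count", c(control = 300, treated = 232),
                            nReplicates = 6L, noiseSd = 4,
                            baselineMean = 100, seed = 3)
  post <- cnt[cnt$role == "sample", ]
  bas <- cnt$count[cnt$role == "baseline"]
  expect_equal(
    cellCountPercentOfControl(post[sample(nrow(post)), ], bas),
    cellCountPercentOfControl(post, bas))
})
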