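test_that("one-way ANOVA matches the textbook sum-of-squares decomposition", {
  # groups {1,2,3} and {4,5,6}: SSB = 13.5, SSW = 4, F = 13.5
  res <- anovaOneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$F, 13.5)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)

  # identical groups: no between-group variance
  same <- anovaOneway(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  # location invariance
  set.seed(2)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  g2 <- lapply(g, `+`, 100)
  expect_equal(anovaOneway(g)$F, anovaOneway(g2)$F)
  expect_error(anovaOneway(list(a = 1:3)), "two groups")
  expect_error(anovaOneway(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("two-group Dunnett reduces to the pooled two-sided t-test", {
  set.seed(10)
  g <- list(control = rnorm(15, 0), drug = rnorm(15, 0.8))
  dt <- dunnettTest(g, control = "control", alpha = 0.05)
  tt <- t.test(g$drug, g$control, var.equal = TRUE)
  expect_equal(dt$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(dt$p_adjusted, tt$p.value, tolerance = 0.01)
  expect_equal(dt$p_unadjusted, tt$p.value, tolerance = 1e-10)
})

test_that("Dunnett adjusted p-values agree with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  set.seed(42)
  g <- list(control = rnorm(12, 0), a = rnorm(12, 0.6),
            b = rnorm(12, 1.1), c = rnorm(12, -0.4))
  dt <- dunnettTest(g, control = "control", alpha = 0.01, B = 2e5)
  dat <- data.frame(y = unlist(g),
                    grp = factor(rep(names(g), lengths(g)),
                                 levels = names(g)))
  ref <- summary(multcomp::glht(stats::aov(y ~ grp, dat),
                                linfct = multcomp::mcp(grp = "Dunnett")))
  refP <- as.vector(ref$test$pvalues)
  expect_equal(dt$statistic, unname(as.vector(ref$test$tstat)),
               tolerance = 1e-8)
  expect_equal(dt$p_adjusted, refP, tolerance = 0.02)
})

test_that("Dunnett respects ordering, affine invariance and the unadjusted lower bound", {
  set.seed(7)
  g <- list(control = rnorm(10), a = rnorm(10, 0.5), b = rnorm(10, 2),
            c = rnorm(10, -1))
  dt <- dunnettTest(g, control = "control")
  expect_true(all(dt$p_adjusted >= dt$p_unadjusted))
  expect_true(all(dt$p_adjusted <= 1))
  # common affine transform leaves the t statistics unchanged
  g2 <- lapply(g, function(x) 3 * x + 50)
  dt2 <- dunnettTest(g2, control = "control")
  expect_equal(dt2$statistic, dt$statistic)

  # an extreme shift is flagged, null groups are not
  pooled <- attr(dt, "pooled_sd")
  g3 <- list(control = rnorm(10), a = rnorm(10), b = rnorm(10))
  g3$b <- g3$b + 10 * sd(unlist(g3[c("control", "a")]))
  dt3 <- dunnettTest(g3, control = "control", alpha = 0.01)
  expect_true(dt3$significant[dt3$comparison == "b - control"])
  expect_false(dt3$significant[dt3$comparison == "a - control"])
})

test_that("the Monte-Carlo null sample is deterministic and design-dependent", {
  a <- dunnettNullSample(c(10, 10, 10), B = 5e3, seed = 1)
  b <- dunnettNullSample(c(10, 10, 10), B = 5e3, seed = 1)
  expect_identical(a, b)
  expect_equal(attr(a, "df"), 27)
  wide <- dunnettNullSample(c(10, 10, 10, 10, 10), B = 5e3, seed = 1)
  # more comparisons push the max-|t| distribution upward
  expect_gt(median(wide), median(a))
})

test_that("z-scores standardize treatment shifts by the control spread", {
  d <- data.frame(variable = "orr",
                  condition = rep(c("control", "t1", "t2"), each = 4),
                  value = c(1, 2, 3, 4, 1, 2, 3, 4, 11, 12, 13, 14))
  z <- zScoreSummary(d)
  expect_equal(z$z[z$condition == "t1"], 0)
  expect_equal(z$z[z$condition == "t2"], 10 / sd(c(1, 2, 3, 4)))

  # treatment shifted by one control SD gives z = 1
  s <- sd(c(1, 2, 3, 4))
  d2 <- data.frame(variable = "v",
                   condition = rep(c("control", "t"), each = 4),
                   value = c(1, 2, 3, 4, c(1, 2, 3, 4) + s))
  expect_equal(zScoreSummary(d2)$z, 1)

  # sign matches the sign of the mean difference on random fixtures
  set.seed(6)
  for (i in 1:5) {
    shift <- runif(1, -3, 3)
    di <- data.frame(variable = "v",
                     condition = rep(c("control", "t"), each = 10),
                     value = c(rnorm(10), rnorm(10, shift)))
    zi <- zScoreSummary(di)$z
    dm <- mean(di$value[di$condition == "t"]) -
      mean(di$value[di$condition == "control"])
    expect_equal(sign(zi), sign(dm))
  }
  zc <- data.frame(variable = "v", condition = rep(c("control", "t"),
                                                   each = 2),
                   value = c(1, 1, 2, 3))
  expect_error(zScoreSummary(zc), "zero")

  m <- zScoreMatrix(d)
  expect_equal(dim(m), c(1L, 2L))
  expect_equal(m["orr", "t1"], 0)
})
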