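# Group statistics: one-way ANOVA, Dunnett's many-to-one comparisons
# with a single pooled variance, and z-score summaries.

.asGroupList <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$condition)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  lapply(groups, as.numeric)
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition across groups,
#' with the p-value from the F distribution. Identical groups give
#' F = 0, p = 1; F is invariant to adding a constant to all
#' observations.
#'
#' @param groups named list of numeric vectors (each n >= 2), or a
#'   data.frame with columns \code{condition}, \code{value}.
#' @return list(\code{F}, \code{p}, \code{df_between},
#'   \code{df_within}).
#' @export
anovaOneway <- function(groups) {
  g <- .asGroupList(groups)
  if (length(g) < 2L) stop("need at least two groups")
  if (any(lengths(g) < 2L)) stop("each group needs n >= 2")
  x <- unlist(g, use.names = FALSE)
  f <- factor(rep(names(g), lengths(g)), levels = names(g))
  fit <- stats::anova(stats::lm(x ~ f))
  Fv <- fit$`F value`[1L]
  p <- fit$`Pr(>F)`[1L]
  if (fit$`Sum Sq`[1L] == 0) { Fv <- 0; p <- 1 }   # identical groups
  list(F = Fv, p = p, df_between = fit$Df[1L], df_within = fit$Df[2L])
}

.restoreSeed <- function() {
  old <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Monte-Carlo null sample of the Dunnett max-|t| statistic
#'
#' Simulates the joint null distribution of the maximal absolute
#' many-to-one t statistic for given group sizes under a shared pooled
#' variance: group means are drawn as independent normals with variance
#' 1/n, the pooled variance as chi-squared with N - k degrees of
#' freedom, and each comparison statistic is formed against the control
#' group. The sample is reused across calls to [dunnettTest()] with the
#' same design, which keeps adjusted p-values and critical values
#' consistent.
#'
#' @param n integer vector of group sizes (control included).
#' @param controlIndex position of the control group in \code{n}.
#' @param B number of Monte-Carlo draws (default 1e5).
#' @param seed RNG seed used locally (the global RNG state is
#'   restored).
#' @return Sorted numeric vector of B max-|t| draws, with the residual
#'   degrees of freedom in attribute \code{"df"}.
#' @export
dunnettNullSample <- function(n, controlIndex = 1L, B = 1e5,
                              seed = 20260925) {
  k <- length(n) - 1L
  if (k < 1L) stop("need a control and at least one treatment group")
  df <- sum(n) - length(n)
  seed <- as.integer(seed %% .Machine$integer.max)
  restore <- .restoreSeed()
  on.exit(restore())
  set.seed(seed)
  z0 <- stats::rnorm(B, sd = sqrt(1 / n[controlIndex]))
  s2 <- stats::rchisq(B, df) / df
  idx <- setdiff(seq_along(n), controlIndex)
  maxT <- rep(0, B)
  for (j in idx) {
    zj <- stats::rnorm(B, sd = sqrt(1 / n[j]))
    tj <- abs(zj - z0) / sqrt(s2 * (1 / n[j] + 1 / n[controlIndex]))
    maxT <- pmax(maxT, tj)
  }
  out <- sort(maxT)
  attr(out, "df") <- df
  out
}

#' Dunnett's many-to-one comparisons with a single pooled variance
#'
#' Compares every treatment group against the shared control using the
#' variance pooled over all groups (control included). Each statistic
#' is \code{t_i = (mean_i - mean_ctrl) / SE_i} with
#' \code{SE_i = sqrt(s2_pooled (1/n_i + 1/n_ctrl))}; the two-sided
#' family-wise adjusted p-value is the null probability that the
#' maximal absolute statistic across all comparisons exceeds |t_i|,
#' evaluated on the Monte-Carlo sample of [dunnettNullSample()] (which
#' captures the common-control correlation between comparisons). The
#' adjusted p is clamped from below by the unadjusted pooled-variance
#' t-test p, which it can never fall under; with a single treatment
#' group the test reduces to that t-test.
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   columns \code{condition}, \code{value}.
#' @param control name of the control group.
#' @param alpha two-sided family-wise significance level (default
#'   0.01).
#' @param B Monte-Carlo draws for the null sample.
#' @param nullSample optional precomputed [dunnettNullSample()] for
#'   this design (group sizes in \code{groups} order, control first
#'   argument order preserved); supplying it makes repeated testing of
#'   one design fast.
#' @param seed RNG seed forwarded to [dunnettNullSample()].
#' @return data.frame(\code{comparison}, \code{diff}, \code{se},
#'   \code{statistic}, \code{p_unadjusted}, \code{p_adjusted},
#'   \code{significant}) with attributes \code{"df"},
#'   \code{"pooled_sd"}, \code{"alpha"} and \code{"critical_t"}.
#' @export
dunnettTest <- function(groups, control = "control", alpha = 0.01,
                        B = 1e5, nullSample = NULL, seed = 20260925) {
  g <- .asGroupList(groups)
  if (!control %in% names(g)) stop("control group '", control,
                                   "' not present")
  if (any(lengths(g) < 2L)) stop("each group needs n >= 2")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  trt <- setdiff(names(g), control)
  if (length(trt) == 0L) stop("no treatment groups")
  n <- lengths(g)
  df <- sum(n) - length(n)
  s2 <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0)) / df
  m0 <- mean(g[[control]]); n0 <- n[[control]]
  if (is.null(nullSample))
    nullSample <- dunnettNullSample(
      c(n0, unname(n[trt])), controlIndex = 1L, B = B, seed = seed)
  Bn <- length(nullSample)
  diff <- vapply(trt, function(a) mean(g[[a]]) - m0, 0)
  se <- vapply(trt, function(a) sqrt(s2 * (1 / n[[a]] + 1 / n0)), 0)
  tstat <- diff / se
  pAdj <- vapply(abs(tstat), function(tt)
    (Bn - findInterval(tt, nullSample)) / Bn, 0)
  pUn <- 2 * stats::pt(-abs(tstat), df)
  pAdj <- pmax(pAdj, pUn)                      # exact lower bound
  out <- data.frame(comparison = paste(trt, "-", control),
                    diff = unname(diff), se = unname(se),
                    statistic = unname(tstat),
                    p_unadjusted = unname(pUn),
                    p_adjusted = unname(pAdj),
                    significant = unname(pAdj) < alpha,
                    row.names = NULL)
  attr(out, "df") <- df
  attr(out, "pooled_sd") <- sqrt(s2)
  attr(out, "alpha") <- alpha
  attr(out, "critical_t") <- stats::quantile(nullSample, 1 - alpha,
                                             names = FALSE)
  out
}

#' z-score summary of treatments against control
#'
#' For every variable and treatment,
#' \code{z = (mean_treatment - mean_control) / sd_control}; a treatment
#' sample equal to the control gives z = 0.
#'
#' @param data data.frame with columns \code{variable},
#'   \code{condition}, \code{value}.
#' @param control control condition label (n >= 2 and positive
#'   standard deviation per variable).
#' @return data.frame(\code{variable}, \code{condition}, \code{z}).
#' @export
zScoreSummary <- function(data, control = "control") {
  stopifnot(all(c("variable", "condition", "value") %in% names(data)))
  out <- do.call(rbind, lapply(split(data, data$variable), function(d) {
    ctrl <- d$value[d$condition == control]
    if (length(ctrl) < 2L) stop("control needs n >= 2 per variable")
    s <- stats::sd(ctrl)
    if (!is.finite(s) || s == 0)
      stop("control standard deviation is zero for variable '",
           d$variable[1L], "'")
    trt <- setdiff(unique(d$condition), control)
    data.frame(variable = d$variable[1L], condition = trt,
               z = vapply(trt, function(a)
                 (mean(d$value[d$condition == a]) - mean(ctrl)) / s, 0),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' z-score matrix (variables x treatments)
#'
#' Reshapes [zScoreSummary()] output into the heatmap-ready matrix with
#' one row per variable and one column per treatment.
#'
#' @inheritParams zScoreSummary
#' @return numeric matrix.
#' @export
zScoreMatrix <- function(data, control = "control") {
  z <- zScoreSummary(data, control)
  vars <- unique(z$variable); trts <- unique(z$condition)
  m <- matrix(NA_real_, length(vars), length(trts),
              dimnames = list(vars, trts))
  m[cbind(match(z$variable, vars), match(z$condition, trts))] <- z$z
  m
}
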