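# Independent brute-force oracles used to pin down the thresholding
# and propagation operations. These deliberately avoid the vectorized
# code paths of the package: plain loops over explicit candidate
# splits, and a per-seed Dijkstra run on the full distance matrix.

# Otsu: maximize between-class variance, explicit two-class means.
oracleOtsu <- function(v) {
  u <- sort(unique(v))
  best <- -Inf; bestT <- NA
  for (i in seq_len(length(u) - 1L)) {
    lo <- v[v <= u[i]]; hi <- v[v > u[i]]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; bestT <- (u[i] + u[i + 1L]) / 2 }
  }
  bestT
}

# Li minimum cross-entropy: minimize -(A0 log mu0 + A1 log mu1).
oracleLi <- function(v) {
  u <- sort(unique(v))
  best <- Inf; bestT <- NA
  for (i in seq_len(length(u) - 1L)) {
    lo <- v[v <= u[i]]; hi <- v[v > u[i]]
    t0 <- if (sum(lo) > 0) sum(lo) * log(mean(lo)) else 0
    t1 <- if (sum(hi) > 0) sum(hi) * log(mean(hi)) else 0
    crit <- -(t0 + t1)
    if (crit < best) { best <- crit; bestT <- (u[i] + u[i + 1L]) / 2 }
  }
  bestT
}

# Geodesic label assignment: one full Dijkstra per seed label over the
# 4-connected foreground graph, then argmin cost with ties to the
# lower label.
oracleDijkstra <- function(seeds, guide, fg, lambda) {
  h <- nrow(seeds); w <- ncol(seeds); n <- h * w
  fg <- fg | seeds > 0
  ids <- sort(setdiff(unique(as.vector(seeds)), 0L))
  distForLabel <- function(lab) {
    d <- rep(Inf, n)
    d[which(seeds == lab)] <- 0
    visited <- rep(FALSE, n)
    repeat {
      cand <- which(!visited & is.finite(d))
      if (!length(cand)) break
      i <- cand[which.min(d[cand])]
      visited[i] <- TRUE
      r <- (i - 1L) %% h + 1L; c <- (i - 1L) %/% h + 1L
      for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + off[1L]; cc <- c + off[2L]
        if (rr < 1L || rr > h || cc < 1L || cc > w) next
        j <- (cc - 1L) * h + rr
        if (!fg[rr, cc] || seeds[rr, cc] > 0) next
        step <- sqrt(lambda^2 + (guide[r, c] - guide[rr, cc])^2)
        if (d[i] + step < d[j]) d[j] <- d[i] + step
      }
    }
    d
  }
  D <- vapply(ids, distForLabel, numeric(n))
  out <- integer(n)
  for (i in seq_len(n)) {
    if (!fg[(i - 1L) %% h + 1L, (i - 1L) %/% h + 1L] &&
        seeds[i] == 0) next
    finite <- which(is.finite(D[i, ]))
    if (!length(finite)) next
    best <- finite[D[i, finite] == min(D[i, finite])]
    out[i] <- ids[min(best)]
  }
  matrix(out, h, w)
}

# Random labeled scene for propagation oracle tests: a few rectangular
# seeds on a noisy guide with a random foreground.
randomPropagationScene <- function(seed, size = 16L, nSeeds = 3L) {
  set.seed(seed)
  seeds <- matrix(0L, size, size)
  for (k in seq_len(nSeeds)) {
    r <- sample(size - 2L, 1L); c <- sample(size - 2L, 1L)
    seeds[r:(r + 1L), c:(c + 1L)] <- k
  }
  guide <- matrix(stats::runif(size * size, 0, 1), size, size)
  fg <- matrix(stats::runif(size * size) < 0.85, size, size)
  list(seeds = seeds, guide = guide, fg = fg)
}
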