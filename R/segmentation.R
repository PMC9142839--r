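# Global thresholding and nucleus-seeded cell segmentation.

.imageValues <- function(img) {
  if (is(img, "IntensityImage")) as.vector(pixels(img)) else as.vector(img)
}

#' Otsu's global threshold
#'
#' Exhaustive scan over the image's sorted unique values, maximizing the
#' between-class variance of the induced two-class split. The returned
#' threshold is the midpoint between the two values flanking the best
#' split, so it always lies strictly between min and max.
#'
#' @param img an [IntensityImage-class] or numeric matrix/vector with at
#'   least two distinct values.
#' @return The threshold (scalar); binarize with \code{pixels >= t}.
#' @seealso [thresholdMinCrossEntropy()]
#' @export
thresholdOtsu <- function(img) {
  v <- .imageValues(img)
  u <- sort(unique(v))
  if (length(u) < 2L) stop("cannot threshold a constant image")
  cnt <- tabulate(match(v, u))
  p <- cnt / sum(cnt)
  w0 <- cumsum(p)
  mu <- cumsum(p * u)
  muT <- mu[length(mu)]
  k <- seq_len(length(u) - 1L)              # split after u[k]
  w1 <- 1 - w0[k]
  bcv <- (muT * w0[k] - mu[k])^2 / (w0[k] * w1)
  i <- which.max(bcv)
  (u[i] + u[i + 1L]) / 2
}

#' Minimum-cross-entropy (Li) global threshold
#'
#' Exhaustive scan over the sorted unique values minimizing the
#' cross-entropy criterion of Li & Lee: for a split into classes with
#' intensity masses A0, A1 and means mu0, mu1, the criterion is
#' \code{-(A0*log(mu0) + A1*log(mu1))} (a zero-mass class contributes
#' 0). The threshold is the midpoint between the flanking values of the
#' best split, multiplied by \code{correctionFactor} — the corrected
#' threshold is exactly factor times the uncorrected one.
#'
#' @param img an [IntensityImage-class] or numeric data with at least
#'   two distinct values.
#' @param correctionFactor positive multiplier (the reference pipeline
#'   uses 2 to restrict the foreground to bright, cell-dense signal).
#' @return The corrected threshold (scalar).
#' @export
thresholdMinCrossEntropy <- function(img, correctionFactor = 1) {
  if (length(correctionFactor) != 1L || !is.finite(correctionFactor) ||
      correctionFactor <= 0)
    stop("correctionFactor must be a positive number")
  v <- .imageValues(img)
  u <- sort(unique(v))
  if (length(u) < 2L) stop("cannot threshold a constant image")
  cnt <- tabulate(match(v, u))
  A <- cumsum(cnt * u)                      # intensity mass up to u[k]
  N <- cumsum(cnt)
  AT <- A[length(A)]; NT <- N[length(N)]
  k <- seq_len(length(u) - 1L)
  mu0 <- A[k] / N[k]
  mu1 <- (AT - A[k]) / (NT - N[k])
  t0 <- ifelse(A[k] > 0, A[k] * log(mu0), 0)
  t1 <- ifelse(AT - A[k] > 0, (AT - A[k]) * log(mu1), 0)
  crit <- -(t0 + t1)
  i <- which.min(crit)
  correctionFactor * (u[i] + u[i + 1L]) / 2
}

#' Apply a threshold specification
#'
#' Computes the global threshold named by a [ThresholdSpec-class]
#' (including its correction factor) on the supplied values.
#'
#' @param spec a [ThresholdSpec-class].
#' @param values image or numeric data to threshold.
#' @return The corrected threshold (scalar).
#' @export
applyThresholdSpec <- function(spec, values) {
  switch(spec@method,
    otsu = spec@correctionFactor * thresholdOtsu(values),
    min_cross_entropy =
      thresholdMinCrossEntropy(values, spec@correctionFactor),
    manual = spec@correctionFactor * spec@manualValue)
}

#' Propagate cell labels outward from nucleus seeds
#'
#' Multi-source geodesic propagation over the 4-connected pixel graph:
#' a step between neighboring pixels p, q costs
#' \code{sqrt(lambda^2 + (I(p) - I(q))^2)} on the guide image, so label
#' fronts travel freely through flat intensity and stall across edges.
#' Every foreground pixel reachable from a seed takes the label of the
#' seed with minimal total path cost; cost ties go to the lower label
#' id. Seed pixels always keep their own label; pixels outside the
#' foreground (or unreachable within it) stay 0.
#'
#' @param nuclei a nonempty [LabelImage-class] of seed objects.
#' @param guide an [IntensityImage-class] steering the propagation
#'   (typically the smoothed cell-body channel).
#' @param foreground logical matrix of candidate cell pixels; seed
#'   pixels are always treated as foreground.
#' @param regularization lambda >= 0, the per-step base cost balancing
#'   Euclidean distance against intensity difference (default 0.05).
#' @return A [LabelImage-class] of cell labels.
#' @export
propagateCells <- function(nuclei, guide, foreground,
                           regularization = 0.05) {
  seeds <- labels2d(nuclei)
  g <- pixels(guide)
  if (!identical(dim(seeds), dim(g)) ||
      !identical(dim(seeds), dim(foreground)))
    stop("nuclei, guide and foreground must share one shape")
  if (all(seeds == 0)) stop("seed image contains no objects")
  if (length(regularization) != 1L || regularization < 0)
    stop("regularization must be >= 0")
  fg <- foreground | seeds > 0
  storage.mode(fg) <- "logical"
  out <- .propagate_cpp(seeds, g, fg, as.numeric(regularization))
  labelImage(out)
}

#' Derive the cytoplasm mask
#'
#' The cytoplasm of cell k is the cell minus its nucleus, labels
#' preserved. A nucleus id with no matching cell id is an error; a
#' nucleus pixel lying outside its own cell is reported with a warning
#' and clipped.
#'
#' @param cells,nucs [LabelImage-class] masks sharing label ids.
#' @return The cytoplasm [LabelImage-class].
#' @export
deriveCytoplasm <- function(cells, nucs) {
  ce <- labels2d(cells); nu <- labels2d(nucs)
  if (!identical(dim(ce), dim(nu))) stop("shape mismatch")
  nucIds <- setdiff(unique(as.vector(nu)), 0L)
  cellIds <- setdiff(unique(as.vector(ce)), 0L)
  missing <- setdiff(nucIds, cellIds)
  if (length(missing))
    stop("nucleus id(s) with no matching cell: ",
         paste(missing, collapse = ", "))
  stray <- nu > 0 & ce != nu
  if (any(stray))
    warning(sum(stray), " nucleus pixel(s) outside their cell; clipped")
  cy <- ce
  cy[nu > 0] <- 0L
  labelImage(cy)
}

#' Mask the mitochondrial compartment inside the cytoplasm
#'
#' Applies a single global TMRE threshold that separates the bright
#' mitochondrial signal from the cytosolic background; the threshold is
#' computed over cytoplasmic pixels only (where mitochondria live), so
#' image background does not drag it down. Mitochondria of cell k are
#' the cytoplasm pixels of k at or above the corrected threshold. Cells
#' whose mitochondrial mask comes out empty are flagged in the
#' \code{"empty_cells"} attribute.
#'
#' @param cyto cytoplasm [LabelImage-class].
#' @param tmre TMRE [IntensityImage-class] of the same shape.
#' @param spec a [ThresholdSpec-class] (default Otsu, factor 1).
#' @return A [LabelImage-class] with attributes \code{"threshold"} and
#'   \code{"empty_cells"}.
#' @export
maskMitochondria <- function(cyto, tmre, spec = thresholdSpec("otsu")) {
  cy <- labels2d(cyto); tm <- pixels(tmre)
  if (!identical(dim(cy), dim(tm))) stop("shape mismatch")
  inCyto <- cy > 0
  thr <- if (spec@method == "manual")
    spec@correctionFactor * spec@manualValue
  else applyThresholdSpec(spec, tm[inCyto])
  mi <- cy
  mi[!(inCyto & tm >= thr)] <- 0L
  ids <- setdiff(unique(as.vector(cy)), 0L)
  keptIds <- setdiff(unique(as.vector(mi)), 0L)
  out <- labelImage(mi)
  attr(out, "threshold") <- thr
  attr(out, "empty_cells") <- setdiff(ids, keptIds)
  out
}

#' Per-object intensity measurements
#'
#' One row per label id >= 1 with pixel count, mean and integrated
#' intensity over the object's support (mean = integrated / count).
#' Pixels where the image is undefined (NA) are excluded.
#'
#' @param lbl a [LabelImage-class].
#' @param img an [IntensityImage-class] of the same shape.
#' @return data.frame(\code{object_id}, \code{n_pixels}, \code{mean},
#'   \code{integrated}); empty when the mask has no objects.
#' @export
measureCompartments <- function(lbl, img) {
  l <- labels2d(lbl); m <- pixels(img)
  if (!identical(dim(l), dim(m))) stop("shape mismatch")
  keep <- l > 0 & !is.na(m)
  if (!any(keep))
    return(data.frame(object_id = integer(0), n_pixels = integer(0),
                      mean = numeric(0), integrated = numeric(0)))
  ids <- l[keep]; vals <- m[keep]
  f <- factor(ids)
  integ <- as.vector(rowsum(vals, f))
  n <- as.vector(table(f))
  data.frame(object_id = as.integer(levels(f)), n_pixels = n,
             mean = integ / n, integrated = integ)
}

#' Nucleus-seeded segmentation into all four compartments
#'
#' Convenience chain producing a validated
#' [SegmentationResult-class]: propagate cells from the nuclei over the
#' foreground, subtract nuclei to get the cytoplasm, and (when a TMRE
#' image is given) mask the mitochondrial compartment.
#'
#' @param nucs nucleus seed [LabelImage-class].
#' @param guide guide [IntensityImage-class] for the propagation.
#' @param foreground logical matrix of cell-candidate pixels.
#' @param tmre optional TMRE [IntensityImage-class] for the
#'   mitochondrial mask.
#' @param mitoSpec [ThresholdSpec-class] for [maskMitochondria()].
#' @param regularization propagation lambda (see [propagateCells()]).
#' @return A [SegmentationResult-class]; the mitochondrial mask carries
#'   the attributes described in [maskMitochondria()].
#' @export
segmentCells <- function(nucs, guide, foreground, tmre = NULL,
                         mitoSpec = thresholdSpec("otsu"),
                         regularization = 0.05) {
  cellsL <- propagateCells(nucs, guide, foreground, regularization)
  cytoL <- deriveCytoplasm(cellsL, nucs)
  mitoL <- if (is.null(tmre)) NULL else
    maskMitochondria(cytoL, tmre, mitoSpec)
  res <- segmentationResult(nucs, cellsL, cytoL, mitoL)
  if (!is.null(mitoL)) {
    attr(res, "mito_threshold") <- attr(mitoL, "threshold")
    attr(res, "mito_empty_cells") <- attr(mitoL, "empty_cells")
  }
  res
}
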