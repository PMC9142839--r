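# Optical redox ratio: per-pixel maps, per-cell cytoplasmic values,
# control normalization and fold-change summaries.

#' Per-pixel optical redox ratio map
#'
#' The optical redox ratio (ORR) is the NAD(P)H autofluorescence
#' intensity divided by the FAD intensity, computed pixelwise. Pixels
#' with zero FAD signal are undefined (NA) and excluded from any
#' downstream aggregate; all other pixels are unaffected by them.
#'
#' @param nadph,fad [IntensityImage-class] objects of identical shape.
#' @return An [IntensityImage-class] with channel \code{"ORR"}.
#' @export
orrMap <- function(nadph, fad) {
  n <- pixels(nadph); f <- pixels(fad)
  if (!identical(dim(n), dim(f))) stop("shape mismatch")
  r <- n / f
  r[f == 0] <- NA_real_
  intensityImage(r, "ORR")
}

#' Per-cell cytoplasmic redox measurements
#'
#' For each cell, the cytoplasmic NAD(P)H and FAD means and the ORR.
#' The primary per-cell ORR is the ratio of cytoplasmic means
#' (\code{orr}), which is robust to isolated zero-FAD pixels; the mean
#' of per-pixel ratios over defined pixels is reported alongside
#' (\code{orr_pixel_mean}). Cells with zero mean FAD are excluded and
#' reported in the \code{"excluded_cells"} attribute.
#'
#' @param cyto cytoplasm [LabelImage-class].
#' @param nadph,fad [IntensityImage-class] objects, same shape.
#' @return data.frame(\code{cell_id}, \code{i_nadph}, \code{i_fad},
#'   \code{orr}, \code{orr_pixel_mean}) with attribute
#'   \code{"excluded_cells"}.
#' @export
perCellRedox <- function(cyto, nadph, fad) {
  mN <- measureCompartments(cyto, nadph)
  mF <- measureCompartments(cyto, fad)
  mR <- measureCompartments(cyto, orrMap(nadph, fad))
  tab <- data.frame(cell_id = mN$object_id, i_nadph = mN$mean)
  tab$i_fad <- mF$mean[match(tab$cell_id, mF$object_id)]
  tab$orr <- tab$i_nadph / tab$i_fad
  tab$orr_pixel_mean <- mR$mean[match(tab$cell_id, mR$object_id)]
  ok <- is.finite(tab$i_fad) & tab$i_fad > 0
  excluded <- tab$cell_id[!ok]
  tab <- tab[ok, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "excluded_cells") <- excluded
  tab
}

#' Normalize per-cell values to the control group mean
#'
#' Divides every value by the mean of the pooled control values, so the
#' control group's normalized mean is exactly 1.
#'
#' @param values numeric vector to normalize.
#' @param controlValues numeric vector of control-group values with a
#'   positive mean.
#' @return Normalized values (unitless).
#' @export
normalizeToControl <- function(values, controlValues) {
  if (length(controlValues) == 0)
    stop("control group is empty")
  m <- mean(controlValues)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be positive")
  values / m
}

#' Fold-change table of redox variables relative to control
#'
#' For each condition and each of \code{i_nadph}, \code{i_fad} and
#' \code{orr}, the fold-change is the condition mean over pooled cells
#' divided by the control mean. Under the ratio-of-means convention and
#' uniform multiplicative shifts, fold(orr) =
#' fold(i_nadph) / fold(i_fad) exactly.
#'
#' @param groups named list of [perCellRedox()] data.frames, one per
#'   condition.
#' @param control name of the control condition in \code{groups}.
#' @param variables columns to summarize.
#' @return data.frame(\code{condition}, one column per variable) of
#'   fold-changes; the control row is all 1.
#' @export
foldChangeTable <- function(groups, control = "control",
                            variables = c("i_nadph", "i_fad", "orr")) {
  if (!control %in% names(groups))
    stop("control condition '", control, "' not present")
  ctrlMeans <- vapply(variables,
                      function(v) mean(groups[[control]][[v]]), 0)
  if (any(!is.finite(ctrlMeans) | ctrlMeans <= 0))
    stop("control means must be positive")
  rows <- lapply(names(groups), function(g) {
    folds <- vapply(variables,
                    function(v) mean(groups[[g]][[v]]), 0) / ctrlMeans
    as.data.frame(c(list(condition = g), as.list(folds)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end optical-redox pipeline for one field of view
#'
#' Runs the autofluorescence imaging chain: take the cell foreground
#' from a global Otsu threshold on the NAD(P)H image (which stops the
#' propagation from running into background), propagate cells outward
#' from the supplied nucleus seeds along the NAD(P)H image, derive the
#' cytoplasm, and measure per-cell cytoplasmic NAD(P)H, FAD and ORR.
#'
#' @param nadph,fad [IntensityImage-class] objects of one field.
#' @param nucs nucleus seed [LabelImage-class].
#' @param regularization propagation lambda.
#' @return list with elements \code{segmentation} and \code{cells}
#'   (the [perCellRedox()] data.frame).
#' @export
redoxPipeline <- function(nadph, fad, nucs, regularization = 0.05) {
  thr <- thresholdOtsu(nadph)
  fg <- pixels(nadph) >= thr
  seg <- segmentCells(nucs, nadph, fg, regularization = regularization)
  list(segmentation = seg, cells = perCellRedox(cytoplasm(seg), nadph, fad))
}
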