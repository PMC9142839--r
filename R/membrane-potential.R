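# Mitochondrial membrane potential from TMRE compartment intensities.

#' Nernst-equation mitochondrial membrane potential
#'
#' TMRE is a cationic dye whose non-quenching-mode fluorescence scales
#' with accumulation, so the mitochondrial-to-nuclear intensity ratio
#' estimates the concentration ratio across the inner membrane and the
#' Nernst relation converts it to a potential:
#' \deqn{\Delta\Psi = -RT \log_{10}(FI_m / FI_n)}
#' with RT = 61.5 mV per tenfold ratio at 37 degrees C. The nuclear
#' signal stands in for the cytosolic reference because TMRE
#' equilibrates similarly in nucleus and cytosol while the nucleus is
#' free of mitochondrial contamination. A tenfold accumulation gives
#' -61.5 mV; more accumulation gives a more negative (more polarized)
#' potential.
#'
#' @param fiM mitochondrial mean TMRE intensity (> 0); vectorized.
#' @param fiN nuclear mean TMRE intensity (> 0); vectorized.
#' @param rt Nernst slope in mV per decade (default 61.5 at 37 C).
#' @return Membrane potential(s) in mV.
#' @examples
#' nernstPotential(100, 10)            # -61.5
#' nernstPotential(10, 10)             # 0
#' @export
nernstPotential <- function(fiM, fiN, rt = 61.5) {
  if (length(rt) != 1L || !is.finite(rt) || rt <= 0)
    stop("rt must be a positive number")
  if (any(!is.finite(fiM)) || any(!is.finite(fiN)) ||
      any(fiM <= 0) || any(fiN <= 0))
    stop("potential undefined for nonpositive compartment intensities")
  -rt * log10(fiM / fiN)
}

#' Per-cell membrane-potential table
#'
#' Measures the mean TMRE intensity of each compartment per cell and
#' evaluates [nernstPotential()] on the mitochondrial and nuclear means.
#' Cells lacking mitochondrial pixels (or with a nonpositive
#' compartment mean) are excluded; their ids are reported in the
#' \code{"excluded_cells"} attribute.
#'
#' @param seg a [SegmentationResult-class] with a mitochondrial mask.
#' @param tmre TMRE [IntensityImage-class], same shape as \code{seg}.
#' @param rt Nernst slope in mV per decade.
#' @return data.frame(\code{cell_id}, \code{fi_n}, \code{fi_m},
#'   \code{fi_cyto}, \code{fi_cell}, \code{delta_psi_mV}) with attribute
#'   \code{"excluded_cells"}.
#' @export
potentialTable <- function(seg, tmre, rt = 61.5) {
  mN <- measureCompartments(nuclei(seg), tmre)
  mM <- measureCompartments(mitochondria(seg), tmre)
  mCy <- measureCompartments(cytoplasm(seg), tmre)
  mCe <- measureCompartments(cells(seg), tmre)
  allIds <- mN$object_id
  ok <- allIds %in% mM$object_id
  tab <- data.frame(cell_id = allIds[ok])
  tab$fi_n <- mN$mean[match(tab$cell_id, mN$object_id)]
  tab$fi_m <- mM$mean[match(tab$cell_id, mM$object_id)]
  tab$fi_cyto <- mCy$mean[match(tab$cell_id, mCy$object_id)]
  tab$fi_cell <- mCe$mean[match(tab$cell_id, mCe$object_id)]
  defined <- tab$fi_n > 0 & tab$fi_m > 0
  excluded <- c(allIds[!ok], tab$cell_id[!defined])
  tab <- tab[defined, , drop = FALSE]
  tab$delta_psi_mV <- nernstPotential(tab$fi_m, tab$fi_n, rt)
  rownames(tab) <- NULL
  attr(tab, "excluded_cells") <- sort(excluded)
  tab
}

#' End-to-end TMRE membrane-potential pipeline
#'
#' Runs the full TMRE imaging chain on one field of view: smooth the
#' TMRE image with a circular average filter, take the cell-body
#' foreground from a global minimum-cross-entropy threshold with
#' correction factor 2 on the smoothed image, propagate cells outward
#' from the supplied nucleus seeds along the smoothed image, derive the
#' cytoplasm, isolate the mitochondrial signal with a global Otsu
#' threshold over cytoplasmic TMRE, and evaluate the Nernst equation on
#' the per-cell compartment means (measured on the unsmoothed image).
#'
#' @param tmre TMRE [IntensityImage-class].
#' @param nucs nucleus seed [LabelImage-class] (nuclei are supplied,
#'   e.g. manually traced or from a generator's ground truth).
#' @param rt Nernst slope in mV per decade.
#' @param smoothRadius circular-filter radius in pixels.
#' @param cellSpec [ThresholdSpec-class] for the cell-body foreground.
#' @param mitoSpec [ThresholdSpec-class] for the mitochondrial mask.
#' @param regularization propagation lambda.
#' @return list with elements \code{segmentation}
#'   ([SegmentationResult-class]) and \code{cells} (the
#'   [potentialTable()] data.frame).
#' @export
potentialPipeline <- function(tmre, nucs, rt = 61.5, smoothRadius = 2,
                              cellSpec = thresholdSpec("min_cross_entropy", 2),
                              mitoSpec = thresholdSpec("otsu"),
                              regularization = 0.05) {
  sm <- smoothCircularAverage(tmre, smoothRadius)
  thr <- applyThresholdSpec(cellSpec, sm)
  fg <- pixels(sm) >= thr
  seg <- segmentCells(nucs, sm, fg, tmre = tmre, mitoSpec = mitoSpec,
                      regularization = regularization)
  list(segmentation = seg, cells = potentialTable(seg, tmre, rt))
}
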