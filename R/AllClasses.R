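#' @useDynLib redoxcell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.validChannels <- c("NADPH", "FAD", "TMRE", "DAPI", "KI67", "CC3", "ORR")

#' Single-channel fluorescence intensity image
#'
#' A 2-D grid of nonnegative fluorescence values with a channel tag.
#' Pixels may be \code{NA} only for derived maps (e.g. the per-pixel
#' redox ratio at pixels with zero FAD signal); acquired images are
#' finite everywhere.
#'
#' @slot pixels numeric matrix, values >= 0 (or NA for undefined pixels
#'   of derived maps).
#' @slot channel one of \code{"NADPH"}, \code{"FAD"}, \code{"TMRE"},
#'   \code{"DAPI"}, \code{"KI67"}, \code{"CC3"}, \code{"ORR"}.
#' @seealso [intensityImage()], [readIntensityImage()]
#' @export
setClass("IntensityImage",
  representation(pixels = "matrix", channel = "character"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
    if (any(p < 0, na.rm = TRUE)) return("pixel values must be >= 0")
    if (length(object@channel) != 1L ||
        !object@channel %in% .validChannels)
      return(paste("channel must be one of:",
                   paste(.validChannels, collapse = ", ")))
    TRUE
  })

#' Photon-count decay stack
#'
#' Time-resolved photon counts from photon-counting acquisition:
#' a T x height x width array of nonnegative integer counts. Decay
#' curves are integrated (summed over time, optionally with spatial
#' binning) to form an intensity image; no lifetime fitting is done.
#'
#' @slot counts 3-D numeric array (time bins x rows x columns) of
#'   nonnegative integers.
#' @slot channel channel tag, as for [IntensityImage-class].
#' @seealso [integrateDecay()]
#' @export
setClass("DecayStack",
  representation(counts = "array", channel = "character"),
  validity = function(object) {
    a <- object@counts
    if (length(dim(a)) != 3L) return("counts must be a 3-D array")
    if (dim(a)[1L] < 1L) return("need at least one time bin")
    if (any(a < 0) || any(a != round(a)))
      return("counts must be nonnegative integers")
    if (length(object@channel) != 1L ||
        !object@channel %in% .validChannels)
      return("invalid channel tag")
    TRUE
  })

#' Integer object-label image
#'
#' A 2-D mask of nonnegative integers: 0 is background, k >= 1 marks
#' pixels of object k. Used for nuclei, cells, cytoplasm and
#' mitochondria masks; a cell and its compartments share one label id.
#'
#' @slot labels integer matrix with values >= 0.
#' @seealso [labelImage()], [readLabelImage()]
#' @export
setClass("LabelImage",
  representation(labels = "matrix"),
  validity = function(object) {
    l <- object@labels
    if (!is.numeric(l)) return("labels must be an integer matrix")
    if (any(!is.finite(l))) return("labels must be finite")
    if (any(l < 0) || any(l != round(l)))
      return("labels must be nonnegative integers")
    TRUE
  })

#' Global threshold specification
#'
#' Names a global thresholding method and a positive correction factor
#' applied multiplicatively to the computed threshold (a factor of 2
#' doubles it). For \code{method = "manual"} the threshold is
#' \code{correctionFactor * manualValue}.
#'
#' @slot method \code{"otsu"}, \code{"min_cross_entropy"} or
#'   \code{"manual"}.
#' @slot correctionFactor positive multiplier.
#' @slot manualValue numeric; required iff \code{method = "manual"}.
#' @seealso [thresholdSpec()], [thresholdOtsu()],
#'   [thresholdMinCrossEntropy()]
#' @export
setClass("ThresholdSpec",
  representation(method = "character", correctionFactor = "numeric",
                 manualValue = "numeric"),
  validity = function(object) {
    if (!object@method %in% c("otsu", "min_cross_entropy", "manual"))
      return("method must be otsu, min_cross_entropy or manual")
    if (length(object@correctionFactor) != 1L ||
        !is.finite(object@correctionFactor) ||
        object@correctionFactor <= 0)
      return("correctionFactor must be a positive number")
    if (object@method == "manual" &&
        (length(object@manualValue) != 1L || !is.finite(object@manualValue)))
      return("manual method requires a finite manualValue")
    TRUE
  })

#' Result of nucleus-seeded cell segmentation
#'
#' Holds the four compartment masks produced by the segmentation chain,
#' with one shared label id per cell. Validity enforces the structural
#' contract: each nucleus lies inside the cell of the same id, the
#' cytoplasm is exactly the cell minus its nucleus, mitochondria lie
#' inside the cytoplasm, and every cell contains exactly one nucleus.
#'
#' @slot nuclei,cells,cytoplasm,mitochondria [LabelImage-class] objects
#'   of identical shape.
#' @seealso [segmentationResult()], [propagateCells()],
#'   [deriveCytoplasm()], [maskMitochondria()]
#' @export
setClass("SegmentationResult",
  representation(nuclei = "LabelImage", cells = "LabelImage",
                 cytoplasm = "LabelImage", mitochondria = "LabelImage"),
  validity = function(object) {
    nu <- object@nuclei@labels; ce <- object@cells@labels
    cy <- object@cytoplasm@labels; mi <- object@mitochondria@labels
    d <- dim(nu)
    if (!identical(d, dim(ce)) || !identical(d, dim(cy)) ||
        !identical(d, dim(mi)))
      return("all compartment masks must share one shape")
    if (any(nu > 0 & ce != nu))
      return("every nucleus pixel must lie in the cell of the same id")
    if (!all(cy == ifelse(nu > 0, 0, ce)))
      return("cytoplasm must equal cells minus nuclei, labels preserved")
    if (any(mi > 0 & cy != mi))
      return("mitochondria must lie inside the cytoplasm of the same id")
    cellIds <- setdiff(unique(as.vector(ce)), 0)
    nucIds <- setdiff(unique(as.vector(nu)), 0)
    if (!setequal(cellIds, nucIds))
      return("each cell label must contain exactly one nucleus label")
    TRUE
  })

#' Extracellular-flux trace for one well
#'
#' Time-ordered oxygen consumption (OCR, pmol O2/min) and extracellular
#' acidification (ECAR, mpH/min) measurement cycles with the mito-stress
#' injection schedule. The standard layout has 3 baseline cycles and 3
#' cycles after each of three injections (oligomycin, FCCP,
#' rotenone + antimycin A), injected after cycles 3, 6 and 9.
#'
#' @slot well well identifier.
#' @slot condition treatment condition label.
#' @slot cycles data.frame with columns \code{time} (min, strictly
#'   increasing), \code{ocr}, \code{ecar}.
#' @slot injections data.frame with columns \code{after_cycle} (cycle
#'   index after which the agent is injected) and \code{agent}.
#' @slot dnaAbsorbance crystal-violet A590 of the well, the DNA-content
#'   normalizer; must be > 0 to normalize.
#' @slot normalized logical; TRUE once rates have been divided by
#'   \code{dnaAbsorbance}.
#' @seealso [fluxTrace()], [basalRespiration()], [normalizeFlux()]
#' @export
setClass("FluxTrace",
  representation(well = "character", condition = "character",
                 cycles = "data.frame", injections = "data.frame",
                 dnaAbsorbance = "numeric", normalized = "logical"),
  validity = function(object) {
    cy <- object@cycles
    if (!all(c("time", "ocr", "ecar") %in% names(cy)))
      return("cycles needs columns time, ocr, ecar")
    if (nrow(cy) > 1 && any(diff(cy$time) <= 0))
      return("cycle times must be strictly increasing")
    inj <- object@injections
    if (nrow(inj) > 0 &&
        !all(c("after_cycle", "agent") %in% names(inj)))
      return("injections needs columns after_cycle, agent")
    if (length(object@dnaAbsorbance) != 1L ||
        !is.finite(object@dnaAbsorbance))
      return("dnaAbsorbance must be a single finite number")
    TRUE
  })

#' Synthetic imaging scene with ground truth
#'
#' Output of the cell-scene generator: channel images with Poisson shot
#' noise, noise-free ground-truth compartment masks satisfying the
#' [SegmentationResult-class] contract, and the per-cell true values the
#' pipeline is expected to recover.
#'
#' @slot channels named list of [IntensityImage-class] objects
#'   (\code{nadph}, \code{fad}, \code{tmre}).
#' @slot segmentation ground-truth [SegmentationResult-class].
#' @slot truth data.frame of per-cell generating values: \code{cell_id},
#'   \code{i_nadph}, \code{i_fad}, \code{orr}, \code{fi_n}, \code{fi_m},
#'   \code{delta_psi_mV}.
#' @slot config the [SimConfig-class] used.
#' @seealso [generateCellScene()]
#' @export
setClass("SimScene",
  representation(channels = "list", segmentation = "SegmentationResult",
                 truth = "data.frame", config = "ANY"))

#' Configuration of the synthetic cell-scene generator
#'
#' Defines the imaging study conditions emulated by
#' [generateCellScene()]: scene geometry, per-channel expected photon
#' counts, per-condition multiplicative fold-changes, the target
#' mitochondrial membrane potential, and the mitochondrial puncta
#' density. Intensities are expected photon counts; the rendered images
#' add per-pixel Poisson shot noise.
#'
#' @slot seed integer random seed; a fixed seed gives identical scenes.
#' @slot imageSize side length in pixels of the square scene.
#' @slot nCells number of non-overlapping cells to place.
#' @slot cellRadius length-2 range of cell semi-axes (pixels).
#' @slot nucleusRadius length-2 range of nucleus radii (pixels); must
#'   stay below the cell radius.
#' @slot background expected background count, all channels.
#' @slot baselineNadph,baselineFad expected cytoplasmic counts of the
#'   control condition.
#' @slot nucleusFraction nuclear NAD(P)H/FAD level relative to
#'   cytoplasm.
#' @slot nadphFold,fadFold multiplicative condition fold-changes applied
#'   to the baselines (1 = control).
#' @slot baselineTmre expected nuclear (= cytosolic) TMRE count n0; the
#'   mitochondrial mean is n0 * 10^(-deltaPsi/rt) by the inverse Nernst
#'   relation.
#' @slot deltaPsi target mitochondrial membrane potential, mV.
#' @slot rt Nernst slope, mV per tenfold concentration ratio.
#' @slot punctaDensity fraction of cytoplasm area covered by
#'   mitochondrial puncta.
#' @slot cellCV lognormal coefficient of variation of per-cell
#'   brightness (cell-to-cell heterogeneity).
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  representation(seed = "numeric", imageSize = "numeric",
                 nCells = "numeric", cellRadius = "numeric",
                 nucleusRadius = "numeric", background = "numeric",
                 baselineNadph = "numeric", baselineFad = "numeric",
                 nucleusFraction = "numeric", nadphFold = "numeric",
                 fadFold = "numeric", baselineTmre = "numeric",
                 deltaPsi = "numeric", rt = "numeric",
                 punctaDensity = "numeric", cellCV = "numeric"),
  validity = function(object) {
    if (object@imageSize < 16) return("imageSize must be >= 16")
    if (object@nCells < 1) return("nCells must be >= 1")
    if (length(object@cellRadius) != 2L || any(object@cellRadius <= 0))
      return("cellRadius must be a positive length-2 range")
    if (length(object@nucleusRadius) != 2L ||
        any(object@nucleusRadius <= 0))
      return("nucleusRadius must be a positive length-2 range")
    if (max(object@nucleusRadius) >= min(object@cellRadius))
      return("nucleus radius must stay below the cell radius")
    if (object@nadphFold <= 0 || object@fadFold <= 0)
      return("condition folds must be > 0")
    if (object@rt <= 0) return("rt must be > 0")
    if (object@punctaDensity <= 0 || object@punctaDensity > 1)
      return("punctaDensity must be in (0, 1]")
    TRUE
  })
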