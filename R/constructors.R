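#' Create an intensity image
#'
#' @param pixels numeric matrix of nonnegative values.
#' @param channel channel tag (see [IntensityImage-class]).
#' @return An [IntensityImage-class] object.
#' @examples
#' img <- intensityImage(matrix(1:12, 3, 4), "NADPH")
#' dim(pixels(img))
#' @export
intensityImage <- function(pixels, channel) {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  new("IntensityImage", pixels = pixels, channel = channel)
}

#' Create a decay stack
#'
#' @param counts 3-D array (time bins x rows x columns) of nonnegative
#'   integer photon counts.
#' @param channel channel tag.
#' @return A [DecayStack-class] object.
#' @export
decayStack <- function(counts, channel) {
  storage.mode(counts) <- "double"
  new("DecayStack", counts = counts, channel = channel)
}

#' Create a label image
#'
#' @param labels matrix of nonnegative integers (0 = background).
#' @return A [LabelImage-class] object.
#' @examples
#' m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
#' labelImage(m)
#' @export
labelImage <- function(labels) {
  if (!is.matrix(labels)) labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  new("LabelImage", labels = labels)
}

#' Create a threshold specification
#'
#' @param method \code{"otsu"}, \code{"min_cross_entropy"} or
#'   \code{"manual"}.
#' @param correctionFactor positive multiplier applied to the computed
#'   (or manual) threshold; default 1.
#' @param manualValue threshold value when \code{method = "manual"}.
#' @return A [ThresholdSpec-class] object.
#' @export
thresholdSpec <- function(method = c("otsu", "min_cross_entropy", "manual"),
                          correctionFactor = 1, manualValue = NA_real_) {
  method <- match.arg(method)
  new("ThresholdSpec", method = method,
      correctionFactor = as.numeric(correctionFactor),
      manualValue = as.numeric(manualValue))
}

#' Assemble a segmentation result
#'
#' Bundles the four compartment masks and checks the structural
#' contract (see [SegmentationResult-class]).
#'
#' @param nuclei,cells,cytoplasm,mitochondria [LabelImage-class] masks
#'   of identical shape sharing label ids per cell. If
#'   \code{mitochondria} is missing an empty mask is used.
#' @return A validated [SegmentationResult-class] object.
#' @export
segmentationResult <- function(nuclei, cells, cytoplasm,
                               mitochondria = NULL) {
  if (is.null(mitochondria))
    mitochondria <- labelImage(matrix(0L, nrow(nuclei@labels),
                                      ncol(nuclei@labels)))
  new("SegmentationResult", nuclei = nuclei, cells = cells,
      cytoplasm = cytoplasm, mitochondria = mitochondria)
}

#' Create an extracellular-flux trace
#'
#' @param well well identifier.
#' @param condition condition label.
#' @param ocr,ecar per-cycle rates (pmol O2/min, mpH/min).
#' @param time cycle times in minutes; defaults to 6-minute cycles.
#' @param injections data.frame(\code{after_cycle}, \code{agent});
#'   defaults to the standard mito-stress schedule (oligomycin, FCCP,
#'   rotenone + antimycin A after cycles 3, 6, 9) when the trace has 12
#'   cycles.
#' @param dnaAbsorbance crystal-violet A590 normalizer (> 0).
#' @return A [FluxTrace-class] object.
#' @examples
#' tr <- fluxTrace("A1", "control", ocr = rep(c(100, 40, 120, 20), each = 3),
#'                 ecar = rep(10, 12))
#' basalRespiration(tr)
#' @export
fluxTrace <- function(well, condition, ocr, ecar, time = NULL,
                      injections = NULL, dnaAbsorbance = 1) {
  n <- length(ocr)
  stopifnot(length(ecar) == n)
  if (is.null(time)) time <- seq_len(n) * 6
  if (is.null(injections)) {
    injections <- if (n == 12L) mitoStressInjections() else
      data.frame(after_cycle = integer(0), agent = character(0))
  }
  new("FluxTrace", well = as.character(well),
      condition = as.character(condition),
      cycles = data.frame(time = as.numeric(time), ocr = as.numeric(ocr),
                          ecar = as.numeric(ecar)),
      injections = injections,
      dnaAbsorbance = as.numeric(dnaAbsorbance), normalized = FALSE)
}

#' Standard mito-stress injection schedule
#'
#' Three injections after cycles 3, 6 and 9: oligomycin (ATP-synthase
#' inhibitor), FCCP (uncoupler), rotenone + antimycin A (complex I/III
#' inhibitors).
#'
#' @return data.frame with columns \code{after_cycle}, \code{agent}.
#' @export
mitoStressInjections <- function() {
  data.frame(after_cycle = c(3L, 6L, 9L),
             agent = c("oligomycin", "FCCP", "rotenone_antimycinA"))
}
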