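#' @name accessors
#' @title Accessors for image and segmentation objects
#' @description Slot accessors: \code{pixels()} returns the pixel grid
#'   of an [IntensityImage-class], \code{channel()} its channel tag,
#'   \code{labels()} the integer grid of a [LabelImage-class],
#'   \code{counts()} the 3-D array of a [DecayStack-class], and
#'   \code{nuclei()}, \code{cells()}, \code{cytoplasm()},
#'   \code{mitochondria()} the compartment masks of a
#'   [SegmentationResult-class]. \code{cycles()} and \code{injections()}
#'   return the measurement table and injection schedule of a
#'   [FluxTrace-class].
#' @param x the object.
#' @return The slot contents.
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "IntensityImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname accessors
#' @export
setMethod("channel", "IntensityImage", function(x) x@channel)
#' @rdname accessors
#' @export
setMethod("channel", "DecayStack", function(x) x@channel)

#' @rdname accessors
#' @export
setGeneric("labels2d", function(x) standardGeneric("labels2d"))
#' @rdname accessors
#' @export
setMethod("labels2d", "LabelImage", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "DecayStack", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("nuclei", function(x) standardGeneric("nuclei"))
#' @rdname accessors
#' @export
setMethod("nuclei", "SegmentationResult", function(x) x@nuclei)

#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname accessors
#' @export
setMethod("cells", "SegmentationResult", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("cytoplasm", function(x) standardGeneric("cytoplasm"))
#' @rdname accessors
#' @export
setMethod("cytoplasm", "SegmentationResult", function(x) x@cytoplasm)

#' @rdname accessors
#' @export
setGeneric("mitochondria", function(x) standardGeneric("mitochondria"))
#' @rdname accessors
#' @export
setMethod("mitochondria", "SegmentationResult", function(x) x@mitochondria)

#' @rdname accessors
#' @export
setGeneric("cycles", function(x) standardGeneric("cycles"))
#' @rdname accessors
#' @export
setMethod("cycles", "FluxTrace", function(x) x@cycles)

#' @rdname accessors
#' @export
setGeneric("injections", function(x) standardGeneric("injections"))
#' @rdname accessors
#' @export
setMethod("injections", "FluxTrace", function(x) x@injections)

#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setMethod("truth", "SimScene", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname accessors
#' @export
setMethod("channels", "SimScene", function(x) x@channels)

#' @rdname accessors
#' @export
setGeneric("segmentation", function(x) standardGeneric("segmentation"))
#' @rdname accessors
#' @export
setMethod("segmentation", "SimScene", function(x) x@segmentation)

setMethod("show", "IntensityImage", function(object) {
  p <- object@pixels
  cat(sprintf("IntensityImage [%s] %d x %d, range [%.4g, %.4g]%s\n",
              object@channel, nrow(p), ncol(p),
              min(p, na.rm = TRUE), max(p, na.rm = TRUE),
              if (anyNA(p)) sprintf(", %d undefined px", sum(is.na(p)))
              else ""))
})

setMethod("show", "DecayStack", function(object) {
  d <- dim(object@counts)
  cat(sprintf("DecayStack [%s] %d time bins, %d x %d px, %g photons\n",
              object@channel, d[1], d[2], d[3], sum(object@counts)))
})

setMethod("show", "LabelImage", function(object) {
  ids <- setdiff(unique(as.vector(object@labels)), 0)
  cat(sprintf("LabelImage %d x %d, %d object(s)\n",
              nrow(object@labels), ncol(object@labels), length(ids)))
})

setMethod("show", "SegmentationResult", function(object) {
  ids <- setdiff(unique(as.vector(object@cells@labels)), 0)
  cat(sprintf(
    "SegmentationResult: %d cell(s), %d x %d px (nuclei/cells/cytoplasm/mitochondria)\n",
    length(ids), nrow(object@cells@labels), ncol(object@cells@labels)))
})

setMethod("show", "FluxTrace", function(object) {
  cat(sprintf(
    "FluxTrace well %s (%s): %d cycles, %d injection(s)%s\n",
    object@well, object@condition, nrow(object@cycles),
    nrow(object@injections),
    if (object@normalized) ", DNA-normalized" else ""))
})

setMethod("show", "SimScene", function(object) {
  cat(sprintf("SimScene: %d cell(s), channels: %s\n",
              nrow(object@truth),
              paste(names(object@channels), collapse = ", ")))
})
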