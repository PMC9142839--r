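# Extracellular-flux mito-stress metrics.

#' Normalize a flux trace to DNA content
#'
#' Divides every OCR and ECAR cycle value by the well's crystal-violet
#' A590 absorbance (a DNA-content proxy), marking the trace normalized.
#' Normalization commutes with [basalRespiration()] up to the same
#' scalar division.
#'
#' @param trace a [FluxTrace-class] with \code{dnaAbsorbance > 0}.
#' @return The normalized [FluxTrace-class].
#' @export
normalizeFlux <- function(trace) {
  a <- trace@dnaAbsorbance
  if (!is.finite(a) || a <= 0)
    stop("dnaAbsorbance must be > 0 to normalize")
  trace@cycles$ocr <- trace@cycles$ocr / a
  trace@cycles$ecar <- trace@cycles$ecar / a
  trace@normalized <- TRUE
  trace
}

.phaseMeans <- function(trace, what = "ocr") {
  ph <- findInterval(seq_len(nrow(cycles(trace))),
                     injections(trace)$after_cycle + 0.5)
  tapply(cycles(trace)[[what]], ph, mean)
}

#' Basal respiration of a mito-stress trace
#'
#' Pre-treatment (baseline) mean OCR minus the mean OCR of the cycles
#' after the rotenone + antimycin A injection (the non-mitochondrial
#' floor). Invariant to cycle order within a phase and linear in OCR
#' scale.
#'
#' @param trace a [FluxTrace-class] with baseline cycles and cycles
#'   after the final (rotenone + antimycin A) injection.
#' @return Basal respiration in the trace's OCR units.
#' @export
basalRespiration <- function(trace) {
  inj <- injections(trace)
  if (nrow(inj) == 0) stop("trace has no injections")
  pm <- .phaseMeans(trace, "ocr")
  last <- as.character(nrow(inj))
  if (!"0" %in% names(pm)) stop("trace has no baseline cycles")
  if (!last %in% names(pm))
    stop("trace has no cycles after the final injection")
  unname(pm[["0"]] - pm[[last]])
}

#' Baseline OCR:ECAR ratio
#'
#' Mean baseline OCR divided by mean baseline ECAR; the ratio of
#' oxidative to glycolytic energy production at rest.
#'
#' @param trace a [FluxTrace-class].
#' @return The unitless ratio.
#' @export
ocrEcarRatio <- function(trace) {
  ph <- findInterval(seq_len(nrow(cycles(trace))),
                     injections(trace)$after_cycle + 0.5)
  base <- ph == 0
  if (!any(base)) stop("trace has no baseline cycles")
  e <- mean(cycles(trace)$ecar[base])
  if (!is.finite(e) || e == 0) stop("baseline ECAR mean is zero")
  mean(cycles(trace)$ocr[base]) / e
}

#' Energetic-quadrant phenotype of an OCR/ECAR pair
#'
#' Classifies a condition's baseline (OCR, ECAR) point relative to the
#' control condition's baseline means, which define the quadrant
#' origin: \code{energetic} (both above control), \code{aerobic} (OCR
#' above, ECAR at or below), \code{glycolytic} (ECAR above, OCR at or
#' below), \code{quiescent} otherwise (points exactly at the control
#' origin are quiescent).
#'
#' @param ocr,ecar baseline means of the condition.
#' @param controlOcr,controlEcar baseline means of the control (> 0).
#' @return One of \code{"energetic"}, \code{"aerobic"},
#'   \code{"glycolytic"}, \code{"quiescent"}.
#' @export
energeticQuadrant <- function(ocr, ecar, controlOcr, controlEcar) {
  if (controlOcr <= 0 || controlEcar <= 0)
    stop("control reference values must be positive")
  up_o <- ocr > controlOcr
  up_e <- ecar > controlEcar
  if (up_o && up_e) "energetic"
  else if (up_o) "aerobic"
  else if (up_e) "glycolytic"
  else "quiescent"
}

#' Full metric set for one mito-stress trace
#'
#' Basal respiration plus the derived mito-stress decomposition:
#' ATP-linked respiration (baseline minus post-oligomycin), maximal
#' respiration (post-FCCP minus non-mitochondrial floor) and spare
#' capacity (maximal minus basal), and the baseline OCR:ECAR ratio.
#'
#' @param trace a 12-cycle mito-stress [FluxTrace-class].
#' @return data.frame of the metrics (one row).
#' @export
fluxMetrics <- function(trace) {
  pm <- .phaseMeans(trace, "ocr")
  floor <- pm[["3"]]
  basal <- pm[["0"]] - floor
  data.frame(well = trace@well, condition = trace@condition,
             basal_respiration = basal,
             atp_linked = pm[["0"]] - pm[["1"]],
             maximal_respiration = pm[["2"]] - floor,
             spare_capacity = (pm[["2"]] - floor) - basal,
             ocr_ecar_ratio = ocrEcarRatio(trace),
             baseline_ocr = unname(pm[["0"]]),
             baseline_ecar = mean(cycles(trace)$ecar[
               findInterval(seq_len(nrow(cycles(trace))),
                            injections(trace)$after_cycle + 0.5) == 0]),
             row.names = NULL)
}

#' Read / write flux traces as CSV
#'
#' The cycles table has columns \code{well}, \code{condition},
#' \code{cycle}, \code{time_min}, \code{ocr}, \code{ecar}; the optional
#' injections table has \code{after_cycle}, \code{agent}. A separate
#' absorbance table (\code{well}, \code{dna_absorbance}) supplies the
#' normalizers.
#'
#' @param cyclesCsv path of the cycles CSV.
#' @param injectionsCsv optional path of the injections CSV; defaults
#'   to the standard mito-stress schedule for 12-cycle traces.
#' @param absorbanceCsv optional path of the DNA-absorbance CSV.
#' @return A list of [FluxTrace-class] objects, one per well.
#' @export
readFluxTraces <- function(cyclesCsv, injectionsCsv = NULL,
                           absorbanceCsv = NULL) {
  tab <- utils::read.csv(cyclesCsv, comment.char = "#")
  inj <- if (is.null(injectionsCsv)) NULL else
    utils::read.csv(injectionsCsv, comment.char = "#")
  absb <- if (is.null(absorbanceCsv)) NULL else
    utils::read.csv(absorbanceCsv, comment.char = "#")
  lapply(split(tab, tab$well), function(d) {
    d <- d[order(d$cycle), ]
    a <- if (is.null(absb)) 1 else
      absb$dna_absorbance[match(d$well[1L], absb$well)]
    fluxTrace(d$well[1L], d$condition[1L], ocr = d$ocr, ecar = d$ecar,
              time = d$time_min, injections = inj, dnaAbsorbance = a)
  })
}

#' @rdname readFluxTraces
#' @param traces list of [FluxTrace-class] objects.
#' @param path output CSV path for the cycles table.
#' @export
writeFluxTraces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    cy <- cycles(tr)
    data.frame(well = tr@well, condition = tr@condition,
               cycle = seq_len(nrow(cy)), time_min = cy$time,
               ocr = cy$ocr, ecar = cy$ecar)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
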