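# Object-overlap percent-positive counting and plate-assay reductions.

#' Percent of DAPI objects positive for a marker
#'
#' A DAPI (nucleus) object is positive when it shares at least one
#' pixel with any marker object; optionally a minimum overlap fraction
#' of the DAPI object's area can be required. Percent positive is
#' 100 * positives / total DAPI objects.
#'
#' @param dapi DAPI object [LabelImage-class]; must contain objects.
#' @param marker marker (e.g. Ki67 or CC3) object [LabelImage-class].
#' @param minOverlapFraction minimum overlapping fraction of the DAPI
#'   object area required to call it positive; the default 0 means any
#'   shared pixel counts.
#' @return data.frame(\code{n_total}, \code{n_positive}, \code{pct}).
#' @export
percentPositive <- function(dapi, marker, minOverlapFraction = 0) {
  d <- labels2d(dapi); m <- labels2d(marker)
  if (!identical(dim(d), dim(m))) stop("shape mismatch")
  ids <- setdiff(unique(as.vector(d)), 0L)
  if (length(ids) == 0L) stop("no DAPI objects to count")
  area <- table(factor(d[d > 0], levels = ids))
  ovl <- table(factor(d[d > 0 & m > 0], levels = ids))
  pos <- as.vector(ovl) > pmax(minOverlapFraction * as.vector(area), 0)
  nPos <- sum(pos)
  data.frame(n_total = length(ids), n_positive = nPos,
             pct = 100 * nPos / length(ids))
}

#' Colocalization summary for proliferation and apoptosis markers
#'
#' Counts DAPI objects overlapping Ki67 (proliferation) and CC3
#' (apoptosis) objects and reports percent positive for each marker.
#'
#' @param dapi,ki67,cc3 object [LabelImage-class] masks of one field.
#' @param minOverlapFraction see [percentPositive()].
#' @return data.frame(\code{n_dapi}, \code{n_positive_ki67},
#'   \code{n_positive_cc3}, \code{pct_ki67}, \code{pct_cc3}).
#' @export
colocSummary <- function(dapi, ki67, cc3, minOverlapFraction = 0) {
  a <- percentPositive(dapi, ki67, minOverlapFraction)
  b <- percentPositive(dapi, cc3, minOverlapFraction)
  data.frame(n_dapi = a$n_total,
             n_positive_ki67 = a$n_positive,
             n_positive_cc3 = b$n_positive,
             pct_ki67 = a$pct, pct_cc3 = b$pct)
}

#' Cell growth as percent of control
#'
#' The mean baseline (pre-treatment) count is subtracted from every
#' post-treatment well count; each condition's mean adjusted count is
#' divided by the control condition's mean adjusted count and
#' multiplied by 100. Values above 100 (faster growth than control) and
#' below 0 (net cell loss) are both possible.
#'
#' @param postCounts data.frame(\code{condition}, \code{count}) of
#'   post-treatment well counts.
#' @param baselineCounts numeric vector of pre-treatment well counts.
#' @param control control condition label.
#' @return data.frame(\code{condition}, \code{percent_of_control}).
#' @export
cellCountPercentOfControl <- function(postCounts, baselineCounts,
                                      control = "control") {
  if (length(baselineCounts) == 0) stop("baseline counts are empty")
  if (!control %in% postCounts$condition)
    stop("control condition not present")
  adj <- postCounts$count - mean(baselineCounts)
  condMean <- tapply(adj, postCounts$condition, mean)
  ctrl <- condMean[[control]]
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control adjusted mean must be positive")
  data.frame(condition = names(condMean),
             percent_of_control = 100 * as.vector(condMean) / ctrl,
             row.names = NULL)
}

#' WST-1 viability as percent of control
#'
#' Per well, the background phenol-red absorbance (650 nm) is
#' subtracted from the WST-1 formazan signal (450 nm); the mean signal
#' of the blank wells (no cells) is then subtracted from every sample
#' well; wells are averaged within condition and expressed as percent
#' of the control condition.
#'
#' @param wells data.frame(\code{condition}, \code{replicate},
#'   \code{role}, \code{a450}, \code{a650}); blank wells have
#'   \code{role == "blank"}.
#' @param control control condition label.
#' @return data.frame(\code{condition}, \code{corrected_signal},
#'   \code{percent_of_control}).
#' @export
wst1PercentViability <- function(wells, control = "control") {
  sig <- wells$a450 - wells$a650
  blank <- wells$role == "blank"
  if (!any(blank)) stop("no blank wells present")
  if (all(blank)) stop("no sample wells present")
  corr <- sig - mean(sig[blank])
  smp <- !blank
  condMean <- tapply(corr[smp], wells$condition[smp], mean)
  if (!control %in% names(condMean)) stop("control condition not present")
  ctrl <- condMean[[control]]
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control corrected mean must be positive")
  data.frame(condition = names(condMean),
             corrected_signal = as.vector(condMean),
             percent_of_control = 100 * as.vector(condMean) / ctrl,
             row.names = NULL)
}

#' Hoechst-normalized CytoID autophagy signal
#'
#' Divides each well's CytoID (autophagosome dye) read by its Hoechst
#' (DNA dye) read to correct for cell number, then averages replicate
#' wells within condition.
#'
#' @param wells data.frame(\code{condition}, \code{replicate},
#'   \code{cytoid}, \code{hoechst}) with \code{hoechst > 0}.
#' @return list with \code{wells} (per-well normalized values) and
#'   \code{conditions} (data.frame of condition means).
#' @export
cytoidNormalized <- function(wells) {
  if (any(wells$hoechst <= 0)) stop("hoechst reads must be > 0")
  w <- wells
  w$value <- w$cytoid / w$hoechst
  condMean <- tapply(w$value, w$condition, mean)
  list(wells = w,
       conditions = data.frame(condition = names(condMean),
                               mean_value = as.vector(condMean),
                               row.names = NULL))
}

#' Percent of senescence-positive cells
#'
#' @param positive number of X-gal positive cells (0 <= positive <=
#'   total).
#' @param total total cells counted (> 0).
#' @return 100 * positive / total.
#' @examples
#' senescencePercent(28, 100)  # 28
#' @export
senescencePercent <- function(positive, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(positive < 0 | positive > total))
    stop("positive must lie in [0, total]")
  100 * positive / total
}
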