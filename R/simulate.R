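# Ground-truth generators for every input the analysis consumes:
# multi-channel cell scenes, mito-stress flux traces, plate tables,
# colocalization label masks and normal group samples. All generators
# take an explicit seed, use it locally, and restore the global RNG
# state, so a fixed seed reproduces outputs byte for byte.

#' Build a cell-scene generator configuration
#'
#' Defaults describe a field of 25 non-overlapping elliptical cells on
#' a 256 x 256 grid with photon-count intensities typical of
#' autofluorescence imaging: background 2 counts, control cytoplasmic
#' NAD(P)H 60 and FAD 50 counts, nuclear autofluorescence at 0.6 of the
#' cytoplasm, nuclear/cytosolic TMRE 30 counts, mitochondrial puncta
#' covering half the cytoplasm, 10 percent lognormal cell-to-cell
#' brightness variation, and a resting potential of -61.5 mV (a
#' tenfold TMRE accumulation). Condition effects enter as
#' multiplicative fold-changes on the channel baselines and as the
#' target membrane potential.
#'
#' @param seed integer seed.
#' @param imageSize,nCells,cellRadius,nucleusRadius scene geometry
#'   (see [SimConfig-class]).
#' @param background,baselineNadph,baselineFad,baselineTmre expected
#'   photon counts.
#' @param nucleusFraction nuclear NAD(P)H/FAD level relative to the
#'   cytoplasm.
#' @param nadphFold,fadFold condition fold-changes (1 = control).
#' @param deltaPsi target mitochondrial membrane potential, mV.
#' @param rt Nernst slope, mV per decade.
#' @param punctaDensity fraction of cytoplasm covered by mitochondrial
#'   puncta.
#' @param cellCV lognormal CV of per-cell brightness.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, imageSize = 256L, nCells = 25L,
                      cellRadius = c(7, 10), nucleusRadius = c(3, 4.5),
                      background = 2, baselineNadph = 60,
                      baselineFad = 50, nucleusFraction = 0.6,
                      nadphFold = 1, fadFold = 1, baselineTmre = 30,
                      deltaPsi = -61.5, rt = 61.5,
                      punctaDensity = 0.5, cellCV = 0.1) {
  new("SimConfig", seed = as.numeric(seed),
      imageSize = as.numeric(imageSize), nCells = as.numeric(nCells),
      cellRadius = as.numeric(cellRadius),
      nucleusRadius = as.numeric(nucleusRadius),
      background = background, baselineNadph = baselineNadph,
      baselineFad = baselineFad, nucleusFraction = nucleusFraction,
      nadphFold = nadphFold, fadFold = fadFold,
      baselineTmre = baselineTmre, deltaPsi = deltaPsi, rt = rt,
      punctaDensity = punctaDensity, cellCV = cellCV)
}

.withSeed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)  # force before snapshot
  restore <- .restoreSeed()
  on.exit(restore())
  set.seed(seed)
  expr
}

# 5-pixel plus-shaped punctum offsets
.punctumOffsets <- cbind(dr = c(0, -1, 1, 0, 0), dc = c(0, 0, 0, -1, 1))

#' Generate a synthetic multi-channel cell scene with ground truth
#'
#' Renders non-overlapping elliptical cells with concentric circular
#' nuclei and plus-shaped mitochondrial puncta scattered through the
#' cytoplasm, then draws per-pixel Poisson photon counts around the
#' expected intensities. Cytoplasmic NAD(P)H and FAD means follow the
#' configured baselines times the condition folds; nuclear and
#' cytosolic TMRE share the mean n0 (TMRE equilibrates similarly in
#' both) and the mitochondrial mean is n0 * 10^(-deltaPsi/rt), the
#' inverse of the Nernst relation, so the configured potential is the
#' scene's ground truth. Per-cell lognormal brightness factors model
#' cell-to-cell heterogeneity; they scale nuclear and mitochondrial
#' TMRE together and therefore cancel in the Nernst ratio. Ground
#' truth (masks and expected means) is recorded before noise.
#'
#' @param cfg a [SimConfig-class].
#' @return A [SimScene-class] whose masks satisfy the
#'   [SegmentationResult-class] contract.
#' @export
generateCellScene <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  .withSeed(cfg@seed, {
    S <- as.integer(cfg@imageSize)
    nuc <- matrix(0L, S, S); cel <- matrix(0L, S, S)
    mit <- matrix(0L, S, S)
    eNad <- matrix(cfg@background, S, S)
    eFad <- matrix(cfg@background, S, S)
    eTmre <- matrix(cfg@background, S, S)
    rc <- row(nuc); cc <- col(nuc)

    placed <- matrix(numeric(0), 0, 3)   # x, y, bounding radius
    truthRows <- vector("list", cfg@nCells)
    ratio <- 10^(-cfg@deltaPsi / cfg@rt)
    sdl <- sqrt(log(1 + cfg@cellCV^2))

    for (k in seq_len(cfg@nCells)) {
      a <- stats::runif(1, cfg@cellRadius[1], cfg@cellRadius[2])
      b <- stats::runif(1, cfg@cellRadius[1], cfg@cellRadius[2])
      phi <- stats::runif(1, 0, pi)
      rn <- stats::runif(1, cfg@nucleusRadius[1],
                         min(cfg@nucleusRadius[2], min(a, b) - 1.5))
      rb <- max(a, b) + 1
      ok <- FALSE
      for (try in seq_len(4000L)) {
        cx <- stats::runif(1, rb + 1, S - rb)
        cy <- stats::runif(1, rb + 1, S - rb)
        if (nrow(placed) == 0 ||
            all((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 >
                (placed[, 3] + rb + 1)^2)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place ", cfg@nCells, " cells; ",
                    "reduce nCells or cell size")
      placed <- rbind(placed, c(cx, cy, rb))
      dx <- rc - cx; dy <- cc - cy
      u <- dx * cos(phi) + dy * sin(phi)
      v <- -dx * sin(phi) + dy * cos(phi)
      inCell <- (u / a)^2 + (v / b)^2 <= 1
      inNuc <- dx^2 + dy^2 <= rn^2
      cel[inCell] <- k
      nuc[inNuc] <- k
      cytoIdx <- which(inCell & !inNuc)

      # mitochondrial puncta: plus-shaped, centers sampled in cytoplasm
      nP <- max(1L, ceiling(cfg@punctaDensity * length(cytoIdx) /
                              nrow(.punctumOffsets)))
      ctr <- sample(cytoIdx, min(nP, length(cytoIdx)),
                    replace = length(cytoIdx) < nP)
      pr <- ((ctr - 1L) %% S) + 1L; pc <- ((ctr - 1L) %/% S) + 1L
      mr <- outer(pr, .punctumOffsets[, "dr"], `+`)
      mc <- outer(pc, .punctumOffsets[, "dc"], `+`)
      keep <- mr >= 1 & mr <= S & mc >= 1 & mc <= S
      mIdx <- unique((mc[keep] - 1L) * S + mr[keep])
      mIdx <- mIdx[inCell[mIdx] & !inNuc[mIdx]]
      mit[mIdx] <- k

      hN <- stats::rlnorm(1, -sdl^2 / 2, sdl)
      hF <- stats::rlnorm(1, -sdl^2 / 2, sdl)
      hT <- stats::rlnorm(1, -sdl^2 / 2, sdl)
      cytN <- cfg@baselineNadph * cfg@nadphFold * hN
      cytF <- cfg@baselineFad * cfg@fadFold * hF
      n0 <- cfg@baselineTmre * hT
      eNad[cytoIdx] <- cytN
      eNad[inNuc] <- cfg@nucleusFraction * cytN
      eFad[cytoIdx] <- cytF
      eFad[inNuc] <- cfg@nucleusFraction * cytF
      eTmre[inCell] <- n0                 # cytosol and (below) nucleus
      eTmre[mIdx] <- n0 * ratio
      truthRows[[k]] <- data.frame(
        cell_id = k, i_nadph = cytN, i_fad = cytF, orr = cytN / cytF,
        fi_n = n0, fi_m = n0 * ratio, delta_psi_mV = cfg@deltaPsi)
    }

    cyt <- cel; cyt[nuc > 0] <- 0L
    seg <- segmentationResult(labelImage(nuc), labelImage(cel),
                              labelImage(cyt), labelImage(mit))
    chans <- list(
      nadph = intensityImage(matrix(stats::rpois(S * S, eNad), S, S),
                             "NADPH"),
      fad = intensityImage(matrix(stats::rpois(S * S, eFad), S, S),
                           "FAD"),
      tmre = intensityImage(matrix(stats::rpois(S * S, eTmre), S, S),
                            "TMRE"))
    new("SimScene", channels = chans, segmentation = seg,
        truth = do.call(rbind, truthRows), config = cfg)
  })
}

#' Generate synthetic mito-stress flux traces
#'
#' Builds 12-cycle traces (3 baseline cycles plus 3 cycles after each
#' of the oligomycin, FCCP and rotenone + antimycin A injections at
#' cycles 3, 6 and 9) with configured phase means and independent
#' Gaussian cycle noise. With zero noise, [basalRespiration()] returns
#' exactly \code{basal - floorOcr}.
#'
#' @param condition condition label.
#' @param nWells number of replicate wells.
#' @param basal,postOligomycin,postFccp,floorOcr OCR phase means.
#' @param ecarBaseline baseline ECAR mean; post-injection ECAR phases
#'   follow at 1.5, 1.5 and 1.2 times baseline (glycolytic
#'   compensation after ATP-synthase inhibition).
#' @param ocrNoiseSd,ecarNoiseSd Gaussian cycle noise; defaults are 2
#'   percent of the respective baselines.
#' @param dnaAbsorbance crystal-violet A590 per well.
#' @param seed integer seed.
#' @return List of [FluxTrace-class] objects.
#' @export
generateFluxTraces <- function(condition = "control", nWells = 6L,
                               basal = 100, postOligomycin = 40,
                               postFccp = 150, floorOcr = 20,
                               ecarBaseline = 10,
                               ocrNoiseSd = 0.02 * basal,
                               ecarNoiseSd = 0.02 * ecarBaseline,
                               dnaAbsorbance = 1, seed = 1L) {
  ocrLevels <- rep(c(basal, postOligomycin, postFccp, floorOcr),
                   each = 3)
  ecarLevels <- rep(ecarBaseline * c(1, 1.5, 1.5, 1.2), each = 3)
  .withSeed(seed, {
    lapply(seq_len(nWells), function(w) {
      fluxTrace(sprintf("%s_W%02d", condition, w), condition,
                ocr = ocrLevels + stats::rnorm(12, 0, ocrNoiseSd),
                ecar = ecarLevels + stats::rnorm(12, 0, ecarNoiseSd),
                dnaAbsorbance = dnaAbsorbance)
    })
  })
}

#' Generate synthetic plate-reader tables
#'
#' Emulates the replicate well layouts of the plate assays:
#' \describe{
#'   \item{wst1}{sample wells with A450 = signal + blank + A650 plus
#'     noise, and no-cell blank wells; \code{conditionMeans} are the
#'     true blank-corrected signals.}
#'   \item{cytoid}{wells with Hoechst reads around
#'     \code{hoechstMean} and CytoID = ratio * Hoechst plus noise;
#'     \code{conditionMeans} are the true CytoID:Hoechst ratios.}
#'   \item{count}{post-treatment well counts around the condition
#'     means plus separate pre-treatment baseline wells.}
#' }
#'
#' @param assay \code{"wst1"}, \code{"cytoid"} or \code{"count"}.
#' @param conditionMeans named numeric of true condition-level values.
#' @param nReplicates wells per condition.
#' @param noiseSd Gaussian well noise.
#' @param blankMean true blank (media-only) WST-1 signal.
#' @param a650 phenol-red background absorbance.
#' @param hoechstMean mean Hoechst read (cytoid assay).
#' @param baselineMean pre-treatment mean count (count assay).
#' @param nBaselineWells pre-treatment wells (count assay).
#' @param seed integer seed.
#' @return data.frame of wells; columns depend on the assay (see
#'   [wst1PercentViability()], [cytoidNormalized()],
#'   [cellCountPercentOfControl()]).
#' @export
generatePlateTable <- function(assay = c("wst1", "cytoid", "count"),
                               conditionMeans, nReplicates = 6L,
                               noiseSd = 0, blankMean = 0.1,
                               a650 = 0.05, hoechstMean = 1000,
                               baselineMean = 100,
                               nBaselineWells = 4L, seed = 1L) {
  assay <- match.arg(assay)
  stopifnot(!is.null(names(conditionMeans)), nReplicates >= 1)
  conds <- names(conditionMeans)
  .withSeed(seed, switch(assay,
    wst1 = {
      smp <- data.frame(
        condition = rep(conds, each = nReplicates),
        replicate = rep(seq_len(nReplicates), length(conds)),
        role = "sample")
      smp$a650 <- a650
      smp$a450 <- a650 + blankMean +
        rep(conditionMeans, each = nReplicates) +
        stats::rnorm(nrow(smp), 0, noiseSd)
      blk <- data.frame(condition = "blank",
                        replicate = seq_len(nReplicates),
                        role = "blank", a650 = a650,
                        a450 = a650 + blankMean +
                          stats::rnorm(nReplicates, 0, noiseSd))
      rbind(smp, blk)
    },
    cytoid = {
      d <- data.frame(
        condition = rep(conds, each = nReplicates),
        replicate = rep(seq_len(nReplicates), length(conds)))
      d$hoechst <- hoechstMean *
        exp(stats::rnorm(nrow(d), 0, noiseSd / hoechstMean))
      d$cytoid <- rep(conditionMeans, each = nReplicates) * d$hoechst +
        stats::rnorm(nrow(d), 0, noiseSd)
      d
    },
    count = {
      smp <- data.frame(
        condition = rep(conds, each = nReplicates),
        replicate = rep(seq_len(nReplicates), length(conds)),
        role = "sample")
      smp$count <- rep(conditionMeans, each = nReplicates) +
        stats::rnorm(nrow(smp), 0, noiseSd)
      bas <- data.frame(condition = "baseline",
                        replicate = seq_len(nBaselineWells),
                        role = "baseline",
                        count = baselineMean +
                          stats::rnorm(nBaselineWells, 0, noiseSd))
      rbind(smp, bas)
    }))
}

#' Generate a synthetic colocalization scene
#'
#' Places DAPI nucleus objects (disks on a regular grid) and marker
#' masks that overlap a chosen number of them, giving an exact
#' ground-truth percent positive.
#'
#' @param nDapi number of DAPI objects.
#' @param nPositiveKi67,nPositiveCc3 how many DAPI objects each marker
#'   overlaps.
#' @param seed integer seed (picks which objects are positive).
#' @return list of [LabelImage-class] masks \code{dapi}, \code{ki67},
#'   \code{cc3}.
#' @export
generateColocScene <- function(nDapi = 20L, nPositiveKi67 = 7L,
                               nPositiveCc3 = 2L, seed = 1L) {
  stopifnot(nPositiveKi67 <= nDapi, nPositiveCc3 <= nDapi)
  perRow <- ceiling(sqrt(nDapi))
  pitch <- 14L
  S <- perRow * pitch + pitch
  dapi <- matrix(0L, S, S); ki67 <- matrix(0L, S, S)
  cc3 <- matrix(0L, S, S)
  rc <- row(dapi); cc <- col(dapi)
  .withSeed(seed, {
    posK <- sample(nDapi, nPositiveKi67)
    posC <- sample(nDapi, nPositiveCc3)
    for (k in seq_len(nDapi)) {
      cx <- pitch * (((k - 1L) %% perRow) + 1L)
      cy <- pitch * (((k - 1L) %/% perRow) + 1L)
      disk <- (rc - cx)^2 + (cc - cy)^2 <= 9
      dapi[disk] <- k
      # marker object offset by 2 px so it overlaps partially
      mdisk <- (rc - cx - 2)^2 + (cc - cy)^2 <= 9
      if (k %in% posK) ki67[mdisk] <- k
      if (k %in% posC) cc3[mdisk] <- k
    }
  })
  list(dapi = labelImage(dapi), ki67 = labelImage(ki67),
       cc3 = labelImage(cc3))
}

#' Generate normal group samples for statistics fixtures
#'
#' @param means named numeric of group means (names become group
#'   labels).
#' @param n observations per group (recycled).
#' @param sd common standard deviation.
#' @param seed integer seed.
#' @return Named list of numeric vectors.
#' @export
generateGroupSamples <- function(means, n = 30L, sd = 1, seed = 1L) {
  stopifnot(!is.null(names(means)), all(n >= 2))
  n <- rep(n, length.out = length(means))
  .withSeed(seed, {
    out <- lapply(seq_along(means), function(i)
      stats::rnorm(n[i], means[i], sd))
    names(out) <- names(means)
    out
  })
}
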