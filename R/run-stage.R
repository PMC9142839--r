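# Config-driven orchestration: one subcommand per pipeline stage,
# reproducible outputs, logged parameters.

#' Default run configuration
#'
#' A complete configuration for the staged pipeline, sized for quick
#' desk-scale runs: two imaging conditions (control, and a treatment
#' with NAD(P)H fold 1.70, FAD fold 1.99 and a hyperpolarized
#' membrane potential), flux traces, plate tables, colocalization
#' scenes and senescence counts. Any element can be overridden in a
#' user YAML config with the same structure.
#'
#' @param seed integer seed propagated to every generator.
#' @return Nested list mirroring the YAML config layout.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    rt_mV = 61.5,
    alpha = 0.01,
    regularization = 0.05,
    scene = list(image_size = 192L, n_cells = 12L, n_scenes = 2L),
    conditions = list(
      control = list(nadph_fold = 1.0, fad_fold = 1.0,
                     delta_psi = -61.5),
      treated = list(nadph_fold = 1.70, fad_fold = 1.99,
                     delta_psi = -75)),
    flux = list(
      n_wells = 6L, noise_fraction = 0.02,
      control = list(basal = 100, post_oligomycin = 40,
                     post_fccp = 150, floor = 20, ecar = 10),
      treated = list(basal = 130, post_oligomycin = 50,
                     post_fccp = 170, floor = 20, ecar = 13)),
    plate = list(
      wst1 = list(means = list(control = 0.8, treated = 0.53),
                  n_replicates = 16L, noise_sd = 0.02),
      cytoid = list(means = list(control = 0.10, treated = 0.13),
                    n_replicates = 5L, noise_sd = 2),
      count = list(means = list(control = 300, treated = 232),
                   baseline = 100, n_replicates = 6L, noise_sd = 5)),
    coloc = list(n_dapi = 20L,
                 positive = list(control = list(ki67 = 12L, cc3 = 1L),
                                 treated = list(ki67 = 10L, cc3 = 3L))),
    senescence = list(total = 100L,
                      positive = list(control = 28L, treated = 40L)))
}

.loadRunConfig <- function(config, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  base <- defaultRunConfig()
  merge2 <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge2(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  cfg <- merge2(base, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

.configDigest <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

.writeStageCsv <- function(df, path, stage, digest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# redoxcell stage=%s digest=%s", stage, digest),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.stageLog <- function(outDir, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  cat(line, "\n", file = file.path(outDir, "run.log"), append = TRUE)
}

.sceneSeed <- function(seed, ci, s) (seed * 1000L + ci * 100L + s) %%
  .Machine$integer.max

.scenePaths <- function(outDir, cond, s) {
  stem <- file.path(outDir, "simulate", sprintf("%s_scene%02d", cond, s))
  list(nadph = paste0(stem, "_nadph.tif"),
       fad = paste0(stem, "_fad.tif"),
       tmre = paste0(stem, "_tmre.tif"),
       nuclei = paste0(stem, "_nuclei.tif"))
}

.sceneConfigFor <- function(cfg, cond, sceneSeed) {
  cc <- cfg$conditions[[cond]]
  simConfig(seed = sceneSeed,
            imageSize = cfg$scene$image_size,
            nCells = cfg$scene$n_cells,
            nadphFold = cc$nadph_fold, fadFold = cc$fad_fold,
            deltaPsi = cc$delta_psi, rt = cfg$rt_mV)
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (write synthetic inputs: scene TIFFs, flux
#' and plate CSVs, colocalization masks), \code{segment} (label images
#' and compartment measurements), \code{orr} (per-cell redox tables,
#' control-normalized ORR and fold-changes), \code{tmre} (per-cell
#' membrane potentials), \code{coloc} (percent positive),
#' \code{flux} (mito-stress metrics and quadrants), \code{assays}
#' (plate reductions), \code{stats} (ANOVA and Dunnett on per-cell
#' ORR), \code{report} (z-score matrix over all variables). Later
#' stages read the files earlier stages wrote under \code{outDir};
#' every CSV starts with a comment naming the producing stage and the
#' config digest, so outputs are traceable and reruns with an
#' identical config are byte-identical.
#'
#' @param stage stage name.
#' @param config path to a YAML config or a config list; defaults are
#'   filled from [defaultRunConfig()].
#' @param outDir output directory (created if needed).
#' @param seed optional seed overriding the config seed.
#' @return Invisibly, the paths written.
#' @export
runStage <- function(stage, config = list(), outDir = "redoxcell_out",
                     seed = NULL) {
  stages <- c("simulate", "segment", "orr", "tmre", "coloc", "flux",
              "assays", "stats", "report")
  if (!is.character(stage) || length(stage) != 1L ||
      !stage %in% stages)
    stop("unknown stage '", paste(stage, collapse = ","),
         "'; expected one of: ", paste(stages, collapse = ", "))
  cfg <- .loadRunConfig(config, seed)
  digest <- .configDigest(cfg)
  dir.create(file.path(outDir, stage), recursive = TRUE,
             showWarnings = FALSE)
  .stageLog(outDir, stage, sprintf("seed=%d digest=%s", cfg$seed,
                                   digest))
  fn <- switch(stage, simulate = .stageSimulate,
               segment = .stageSegment, orr = .stageOrr,
               tmre = .stageTmre, coloc = .stageColoc,
               flux = .stageFlux, assays = .stageAssays,
               stats = .stageStats, report = .stageReport)
  invisible(fn(cfg, outDir, digest))
}

.stageSimulate <- function(cfg, outDir, digest) {
  conds <- names(cfg$conditions)
  rows <- list(); truthRows <- list()
  for (ci in seq_along(conds)) {
    for (s in seq_len(cfg$scene$n_scenes)) {
      sc <- generateCellScene(
        .sceneConfigFor(cfg, conds[ci], .sceneSeed(cfg$seed, ci, s)))
      p <- .scenePaths(outDir, conds[ci], s)
      writeIntensityImage(channels(sc)$nadph, p$nadph)
      writeIntensityImage(channels(sc)$fad, p$fad)
      writeIntensityImage(channels(sc)$tmre, p$tmre)
      writeLabelImage(nuclei(segmentation(sc)), p$nuclei)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = conds[ci], scene = s,
                   nadph = p$nadph, fad = p$fad, tmre = p$tmre,
                   nuclei = p$nuclei)
      tr <- truth(sc); tr$condition <- conds[ci]; tr$scene <- s
      truthRows[[length(truthRows) + 1L]] <- tr
    }
  }
  sim <- file.path(outDir, "simulate")
  .writeStageCsv(do.call(rbind, rows), file.path(sim, "manifest.csv"),
                 "simulate", digest)
  .writeStageCsv(do.call(rbind, truthRows),
                 file.path(sim, "truth.csv"), "simulate", digest)
  # flux traces
  traces <- list()
  for (ci in seq_along(conds)) {
    fl <- cfg$flux[[conds[ci]]]
    traces <- c(traces, generateFluxTraces(
      conds[ci], nWells = cfg$flux$n_wells, basal = fl$basal,
      postOligomycin = fl$post_oligomycin, postFccp = fl$post_fccp,
      floorOcr = fl$floor, ecarBaseline = fl$ecar,
      ocrNoiseSd = cfg$flux$noise_fraction * fl$basal,
      ecarNoiseSd = cfg$flux$noise_fraction * fl$ecar,
      seed = .sceneSeed(cfg$seed, ci, 77L)))
  }
  writeFluxTraces(traces, file.path(sim, "flux_cycles.csv"))
  # plate tables
  pl <- cfg$plate
  .writeStageCsv(generatePlateTable("wst1",
      unlist(pl$wst1$means), pl$wst1$n_replicates, pl$wst1$noise_sd,
      seed = cfg$seed + 11L),
    file.path(sim, "plate_wst1.csv"), "simulate", digest)
  .writeStageCsv(generatePlateTable("cytoid",
      unlist(pl$cytoid$means), pl$cytoid$n_replicates,
      pl$cytoid$noise_sd, seed = cfg$seed + 12L),
    file.path(sim, "plate_cytoid.csv"), "simulate", digest)
  .writeStageCsv(generatePlateTable("count",
      unlist(pl$count$means), pl$count$n_replicates,
      pl$count$noise_sd, baselineMean = pl$count$baseline,
      seed = cfg$seed + 13L),
    file.path(sim, "plate_count.csv"), "simulate", digest)
  # colocalization masks
  for (ci in seq_along(conds)) {
    pos <- cfg$coloc$positive[[conds[ci]]]
    cs <- generateColocScene(cfg$coloc$n_dapi, pos$ki67, pos$cc3,
                             seed = cfg$seed + 20L + ci)
    stem <- file.path(sim, sprintf("%s_coloc", conds[ci]))
    writeLabelImage(cs$dapi, paste0(stem, "_dapi.tif"))
    writeLabelImage(cs$ki67, paste0(stem, "_ki67.tif"))
    writeLabelImage(cs$cc3, paste0(stem, "_cc3.tif"))
  }
  sen <- cfg$senescence
  .writeStageCsv(
    data.frame(condition = conds,
               positive = unlist(sen$positive[conds]),
               total = sen$total),
    file.path(sim, "senescence_counts.csv"), "simulate", digest)
  invisible(sim)
}

.readManifest <- function(outDir) {
  f <- file.path(outDir, "simulate", "manifest.csv")
  if (!file.exists(f)) stop("run the simulate stage first (missing ",
                            f, ")")
  utils::read.csv(f, comment.char = "#")
}

.stageSegment <- function(cfg, outDir, digest) {
  man <- .readManifest(outDir)
  dir <- file.path(outDir, "segment")
  meas <- list()
  for (i in seq_len(nrow(man))) {
    nadph <- readIntensityImage(man$nadph[i], "NADPH")
    nucs <- readLabelImage(man$nuclei[i])
    res <- redoxPipeline(nadph, readIntensityImage(man$fad[i], "FAD"),
                         nucs, cfg$regularization)
    stem <- file.path(dir, sprintf("%s_scene%02d", man$condition[i],
                                   man$scene[i]))
    writeLabelImage(cells(res$segmentation), paste0(stem, "_cells.tif"))
    writeLabelImage(cytoplasm(res$segmentation),
                    paste0(stem, "_cytoplasm.tif"))
    m <- measureCompartments(cytoplasm(res$segmentation), nadph)
    if (nrow(m)) {
      m$compartment <- "cytoplasm"
      m$condition <- man$condition[i]; m$scene <- man$scene[i]
      meas[[length(meas) + 1L]] <- m
    }
  }
  .writeStageCsv(do.call(rbind, meas),
                 file.path(dir, "compartments.csv"), "segment", digest)
  invisible(dir)
}

.stageOrr <- function(cfg, outDir, digest) {
  man <- .readManifest(outDir)
  dir <- file.path(outDir, "orr")
  perCell <- list()
  for (i in seq_len(nrow(man))) {
    res <- redoxPipeline(readIntensityImage(man$nadph[i], "NADPH"),
                         readIntensityImage(man$fad[i], "FAD"),
                         readLabelImage(man$nuclei[i]),
                         cfg$regularization)
    d <- res$cells
    d$condition <- man$condition[i]; d$scene <- man$scene[i]
    perCell[[length(perCell) + 1L]] <- d
  }
  tab <- do.call(rbind, perCell)
  ctrl <- names(cfg$conditions)[1L]
  tab$orr_normalized <- normalizeToControl(
    tab$orr, tab$orr[tab$condition == ctrl])
  groups <- split(tab, tab$condition)
  folds <- foldChangeTable(groups, control = ctrl)
  .writeStageCsv(tab, file.path(dir, "per_cell_redox.csv"), "orr",
                 digest)
  .writeStageCsv(folds, file.path(dir, "fold_changes.csv"), "orr",
                 digest)
  invisible(dir)
}

.stageTmre <- function(cfg, outDir, digest) {
  man <- .readManifest(outDir)
  dir <- file.path(outDir, "tmre")
  perCell <- list()
  for (i in seq_len(nrow(man))) {
    res <- potentialPipeline(readIntensityImage(man$tmre[i], "TMRE"),
                             readLabelImage(man$nuclei[i]),
                             rt = cfg$rt_mV,
                             regularization = cfg$regularization)
    d <- res$cells
    d$condition <- man$condition[i]; d$scene <- man$scene[i]
    perCell[[length(perCell) + 1L]] <- d
  }
  .writeStageCsv(do.call(rbind, perCell),
                 file.path(dir, "per_cell_potential.csv"), "tmre",
                 digest)
  invisible(dir)
}

.stageColoc <- function(cfg, outDir, digest) {
  conds <- names(cfg$conditions)
  dir <- file.path(outDir, "coloc")
  rows <- lapply(conds, function(cond) {
    stem <- file.path(outDir, "simulate", sprintf("%s_coloc", cond))
    s <- colocSummary(readLabelImage(paste0(stem, "_dapi.tif")),
                      readLabelImage(paste0(stem, "_ki67.tif")),
                      readLabelImage(paste0(stem, "_cc3.tif")))
    cbind(condition = cond, s)
  })
  .writeStageCsv(do.call(rbind, rows),
                 file.path(dir, "percent_positive.csv"), "coloc",
                 digest)
  invisible(dir)
}

.stageFlux <- function(cfg, outDir, digest) {
  dir <- file.path(outDir, "flux")
  traces <- readFluxTraces(file.path(outDir, "simulate",
                                     "flux_cycles.csv"))
  mets <- do.call(rbind, lapply(traces,
                                function(tr) fluxMetrics(normalizeFlux(tr))))
  rownames(mets) <- NULL
  ctrl <- names(cfg$conditions)[1L]
  condMean <- function(v) tapply(mets[[v]], mets$condition, mean)
  bo <- condMean("baseline_ocr"); be <- condMean("baseline_ecar")
  summ <- data.frame(
    condition = names(bo),
    basal_respiration = as.vector(condMean("basal_respiration")),
    ocr_ecar_ratio = as.vector(condMean("ocr_ecar_ratio")),
    baseline_ocr = as.vector(bo), baseline_ecar = as.vector(be))
  summ$quadrant <- vapply(seq_len(nrow(summ)), function(i)
    energeticQuadrant(summ$baseline_ocr[i], summ$baseline_ecar[i],
                      bo[[ctrl]], be[[ctrl]]), "")
  .writeStageCsv(mets, file.path(dir, "well_metrics.csv"), "flux",
                 digest)
  .writeStageCsv(summ, file.path(dir, "condition_summary.csv"),
                 "flux", digest)
  invisible(dir)
}

.stageAssays <- function(cfg, outDir, digest) {
  sim <- file.path(outDir, "simulate")
  dir <- file.path(outDir, "assays")
  ctrl <- names(cfg$conditions)[1L]
  wst <- utils::read.csv(file.path(sim, "plate_wst1.csv"),
                         comment.char = "#")
  .writeStageCsv(wst1PercentViability(wst, control = ctrl),
                 file.path(dir, "wst1.csv"), "assays", digest)
  cyt <- utils::read.csv(file.path(sim, "plate_cytoid.csv"),
                         comment.char = "#")
  .writeStageCsv(cytoidNormalized(cyt)$conditions,
                 file.path(dir, "cytoid.csv"), "assays", digest)
  cnt <- utils::read.csv(file.path(sim, "plate_count.csv"),
                         comment.char = "#")
  .writeStageCsv(
    cellCountPercentOfControl(cnt[cnt$role == "sample", ],
                              cnt$count[cnt$role == "baseline"],
                              control = ctrl),
    file.path(dir, "cell_counts.csv"), "assays", digest)
  sen <- utils::read.csv(file.path(sim, "senescence_counts.csv"),
                         comment.char = "#")
  sen$pct_positive <- senescencePercent(sen$positive, sen$total)
  .writeStageCsv(sen, file.path(dir, "senescence.csv"), "assays",
                 digest)
  invisible(dir)
}

.stageStats <- function(cfg, outDir, digest) {
  dir <- file.path(outDir, "stats")
  f <- file.path(outDir, "orr", "per_cell_redox.csv")
  if (!file.exists(f)) stop("run the orr stage first (missing ", f, ")")
  tab <- utils::read.csv(f, comment.char = "#")
  ctrl <- names(cfg$conditions)[1L]
  g <- split(tab$orr, tab$condition)
  an <- anovaOneway(g)
  .writeStageCsv(data.frame(variable = "orr", F = an$F, p = an$p,
                            df_between = an$df_between,
                            df_within = an$df_within),
                 file.path(dir, "anova.csv"), "stats", digest)
  dt <- dunnettTest(g, control = ctrl, alpha = cfg$alpha,
                    seed = cfg$seed)
  .writeStageCsv(cbind(variable = "orr", dt),
                 file.path(dir, "dunnett.csv"), "stats", digest)
  invisible(dir)
}

.stageReport <- function(cfg, outDir, digest) {
  dir <- file.path(outDir, "report")
  ctrl <- names(cfg$conditions)[1L]
  pieces <- list()
  f <- file.path(outDir, "orr", "per_cell_redox.csv")
  if (file.exists(f)) {
    d <- utils::read.csv(f, comment.char = "#")
    for (v in c("i_nadph", "i_fad", "orr"))
      pieces[[length(pieces) + 1L]] <-
        data.frame(variable = v, condition = d$condition,
                   value = d[[v]])
  }
  f <- file.path(outDir, "tmre", "per_cell_potential.csv")
  if (file.exists(f)) {
    d <- utils::read.csv(f, comment.char = "#")
    pieces[[length(pieces) + 1L]] <-
      data.frame(variable = "delta_psi_mV", condition = d$condition,
                 value = d$delta_psi_mV)
  }
  f <- file.path(outDir, "flux", "well_metrics.csv")
  if (file.exists(f)) {
    d <- utils::read.csv(f, comment.char = "#")
    for (v in c("basal_respiration", "ocr_ecar_ratio"))
      pieces[[length(pieces) + 1L]] <-
        data.frame(variable = v, condition = d$condition,
                   value = d[[v]])
  }
  if (!length(pieces))
    stop("no upstream outputs found; run orr/tmre/flux first")
  z <- zScoreMatrix(do.call(rbind, pieces), control = ctrl)
  .writeStageCsv(data.frame(variable = rownames(z), z,
                            check.names = FALSE),
                 file.path(dir, "zscore_matrix.csv"), "report", digest)
  invisible(dir)
}
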