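#' Named preset configurations
#'
#' \code{deskSmallConfig} is the desk-scale default used throughout the
#' test suite: the full scanner geometry with coarser detector sampling
#' (2.4 mm pixels), 60 views, a 48^3 voxel grid at 4 mm -- small enough for
#' interactive work while exercising every stage.  \code{n1BaselineConfig}
#' is the same scan in the degenerate single-source wide-cone
#' configuration.  \code{fullScaleConfig} documents the full-size protocol
#' (360 views, 0.198 mm pixels); it is provided for completeness and takes
#' hours at full grid sizes.
#'
#' @param seed integer seed.
#' @return a config list for \code{\link{runPipeline}}.
#' @name presets
NULL

#' @rdname presets
#' @export
deskSmallConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n1 = FALSE,
    geometry = list(nSources = 8L, sourcePitch = 12, sdd = 615,
                    sid = "derive", detWidth = 147.3, detHeight = 113.7,
                    pixelPitch = 2.4, lateralOffset = 70, beamFwhm = 32.5,
                    penumbraSigma = 1, targetFovDiameter = 187),
    protocol = list(nViews = 60L, tReadout = 11.6e-3, tExposure = 6.5e-3,
                    tubeCurrent = 15, doseRate = 1299e-6,
                    photonBudget = 2e4),
    phantom = list(type = "contrast", voxelSize = 4, gridDim = c(48L, 48L, 48L),
                   cylDiameter = 160, height = 80),
    scatter = list(enabled = TRUE, kernelSigma = 300, amplitude = 1,
                   axialWidthReference = 113.7),
    asrs = list(enabled = TRUE, bandOffset = 50, bandRows = 5L,
                spar = NA_real_, ratioClip = 0.95),
    recon = list(nIter = 100L, relaxation = 1.9, tvWeight = 0, tvEvery = 0L,
                 tvIter = 20L, gridDim = c(48L, 48L, 48L), voxelSize = 4,
                 calibration = "two-point", floorFrac = 1e-6),
    metrics = list(roiSideMm = 10)
  )
}

#' @rdname presets
#' @export
n1BaselineConfig <- function(seed = 1L) {
  cfg <- deskSmallConfig(seed)
  cfg$n1 <- TRUE
  cfg
}

#' @rdname presets
#' @export
fullScaleConfig <- function(seed = 1L) {
  cfg <- deskSmallConfig(seed)
  cfg$geometry$pixelPitch <- 0.198
  cfg$protocol$nViews <- 360L
  cfg$protocol$photonBudget <- 1e5
  cfg$phantom$voxelSize <- 0.5
  cfg$phantom$gridDim <- c(384L, 384L, 256L)
  cfg$recon$gridDim <- c(384L, 384L, 256L)
  cfg$recon$voxelSize <- 0.5
  cfg$recon$nIter <- 200L
  cfg$asrs$bandRows <- 50L
  cfg
}

#' Validate and resolve a run configuration
#'
#' Accepts a config list or a YAML file path; fills defaults from the
#' desk-scale preset, rejects unknown keys, requires a seed, and runs
#' cross-field checks (e.g. that the scatter sampling band fits on the
#' detector).
#'
#' @param config list or path to a YAML file.
#' @return the resolved config list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- deskSmallConfig(seed = 0L)
  known <- names(base)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (blk in intersect(names(config), names(base))) {
    if (is.list(base[[blk]]) && is.list(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(base[[blk]]))
      extraOk <- if (blk == "phantom")
        c("nDiscs", "discDiameter", "discThickness", "gap", "discHu",
          "inserts", "a", "b", "macorHu") else character()
      bad <- setdiff(bad, extraOk)
      if (length(bad))
        stop(sprintf("unknown keys in config$%s: %s", blk,
                     paste(bad, collapse = ", ")))
    }
  }
  cfg <- modifyList(base, config)
  if (is.null(config$seed))
    stop("config$seed is mandatory (stochastic stages require a seed)")
  g <- cfg$geometry
  if (isTRUE(cfg$asrs$enabled) && !isTRUE(cfg$n1)) {
    # feasibility for the most central source: at least one side of its
    # band must accommodate the sampling band on the panel
    n <- g$nSources
    zc <- min(abs((seq_len(n) - (n + 1) / 2) * g$sourcePitch))
    half <- cfg$asrs$bandRows * g$pixelPitch / 2
    fits <- abs(c(zc - cfg$asrs$bandOffset, zc + cfg$asrs$bandOffset)) +
      half <= g$detHeight / 2
    if (!any(fits))
      stop("config$asrs.bandOffset: sampling band does not fit on the ",
           "detector for any source (offset ", cfg$asrs$bandOffset,
           " mm, panel half-height ", g$detHeight / 2, " mm)")
  }
  cfg
}

buildConfigGeometry <- function(cfg) {
  g <- cfg$geometry
  geom <- buildGeometry(nSources = g$nSources, sourcePitch = g$sourcePitch,
                        sdd = g$sdd, sid = g$sid, detWidth = g$detWidth,
                        detHeight = g$detHeight, pixelPitch = g$pixelPitch,
                        lateralOffset = g$lateralOffset, beamFwhm = g$beamFwhm,
                        penumbraSigma = g$penumbraSigma,
                        targetFovDiameter = g$targetFovDiameter)
  p <- cfg$protocol
  prot <- acquisitionProtocol(nViews = p$nViews, nSources = g$nSources,
                              tReadout = p$tReadout, tExposure = p$tExposure,
                              tubeCurrent = p$tubeCurrent,
                              doseRate = p$doseRate,
                              photonBudget = p$photonBudget,
                              seed = cfg$seed)
  if (isTRUE(cfg$n1)) {
    d <- n1Degenerate(geom, prot)
    geom <- d$geometry; prot <- d$protocol
  }
  list(geometry = geom, protocol = prot)
}

buildConfigPhantom <- function(cfg) {
  ph <- cfg$phantom
  switch(ph$type,
    contrast = makeContrast(cylDiameter = ph$cylDiameter, height = ph$height,
                            voxelSize = ph$voxelSize, gridDim = ph$gridDim),
    cylinder = makeContrast(cylDiameter = ph$cylDiameter, height = ph$height,
                            inserts = NULL, voxelSize = ph$voxelSize,
                            gridDim = ph$gridDim),
    defrise = makeDefrise(nDiscs = if (is.null(ph$nDiscs)) 12L else ph$nDiscs,
                          voxelSize = ph$voxelSize, gridDim = ph$gridDim),
    head = makeHead(voxelSize = ph$voxelSize, gridDim = ph$gridDim),
    stop("unknown phantom type: ", ph$type))
}

contrastRoiSpecs <- function(cfg, voxelSize, gridDim) {
  sidePx <- max(3L, round(cfg$metrics$roiSideMm / voxelSize))
  c0 <- (gridDim[1:2] + 1) / 2
  mm2px <- function(xy) c0 + xy / voxelSize
  ins <- contrastInserts()
  specs <- list()
  for (i in seq_len(nrow(ins))) {
    a <- ins$angleDeg[i] * pi / 180
    ctr <- ins$radius[i] * c(cos(a), sin(a))
    bg1 <- ins$radius[i] * c(cos(a + pi / 6), sin(a + pi / 6))
    bg2 <- ins$radius[i] * c(cos(a - pi / 6), sin(a - pi / 6))
    specs[[ins$material[i]]] <- list(
      insert = list(center = mm2px(ctr), side = sidePx),
      background = list(list(center = mm2px(bg1), side = sidePx),
                        list(center = mm2px(bg2), side = sidePx)))
  }
  specs
}

#' Run the full simulation-correction-reconstruction-metrics pipeline
#'
#' Stages, in order: phantom generation, scan simulation (with surrogate
#' scatter when enabled), adjacent scatter ratio subtraction (frames whose
#' sampling band does not fit are passed through), log-normalization, SIRT
#' reconstruction (with optional TV), HU calibration, and phantom-specific
#' quality metrics.  With an output directory, every stage product is
#' written (NIfTI volumes, TIFF projection stacks, JSON/CSV reports) and a
#' manifest of file hashes is produced; identical configs reproduce
#' identical hashes.
#'
#' @param config config list or YAML path (see \code{\link{validateConfig}}).
#' @param outDir optional output directory.
#' @return list with \code{recon}, \code{metrics}, \code{asrsDiagnostics},
#'   \code{projections}, \code{config} and \code{manifest}.
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- validateConfig(config)
  t0 <- proc.time()[["elapsed"]]
  gp <- buildConfigGeometry(cfg)
  phantom <- buildConfigPhantom(cfg)

  sm <- if (isTRUE(cfg$scatter$enabled))
    scatterModel(cfg$scatter$kernelSigma, cfg$scatter$amplitude,
                 cfg$scatter$axialWidthReference) else NULL
  scan <- simulateScan(phantom, gp$geometry, gp$protocol, scatter = sm)

  asrsDiag <- NULL
  corrected <- scan
  if (isTRUE(cfg$asrs$enabled)) {
    res <- asrsCorrectSet(scan, asrsParams(cfg$asrs$bandOffset,
                                           cfg$asrs$bandRows, cfg$asrs$spar,
                                           cfg$asrs$ratioClip))
    corrected <- res$projections
    asrsDiag <- res$diagnostics
  }

  li <- logNormalize(corrected, cfg$recon$floorFrac)
  system <- buildSystem(gp$geometry, gp$protocol, cfg$recon$gridDim,
                        cfg$recon$voxelSize)
  recon <- sirt(li, system, nIter = cfg$recon$nIter,
                relaxation = cfg$recon$relaxation,
                tvWeight = cfg$recon$tvWeight, tvEvery = cfg$recon$tvEvery,
                tvIter = cfg$recon$tvIter)

  recon <- calibratePipeline(recon, cfg, phantom)
  metrics <- pipelineMetrics(recon, cfg, phantom)

  manifest <- list(version = as.character(utils::packageVersion("mscbct")),
                   files = character())
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    cfgPath <- file.path(outDir, "config.yaml")
    yaml::write_yaml(cfg, cfgPath)
    writeVolume(phantom, file.path(outDir, "phantom"))
    writeProjectionSet(corrected, file.path(outDir, "projections"))
    writeVolume(recon, file.path(outDir, "recon"))
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(asrsDiag))
      write.csv(asrsDiag, file.path(outDir, "asrs_diagnostics.csv"),
                row.names = FALSE)
    files <- list.files(outDir, full.names = TRUE)
    manifest$files <- tools::md5sum(files)
    names(manifest$files) <- basename(files)
    jsonlite::write_json(lapply(manifest, as.list),
                         file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  manifest$elapsedS <- proc.time()[["elapsed"]] - t0

  list(recon = recon, metrics = metrics, asrsDiagnostics = asrsDiag,
       projections = corrected, config = cfg, manifest = manifest)
}

calibratePipeline <- function(recon, cfg, phantom) {
  if (identical(cfg$recon$calibration, "linear") ||
      !identical(cfg$phantom$type, "contrast"))
    return(calibrateHuLinear(recon, muWater = 0.02))
  # two-point: water at the cylinder centre, air in the air insert
  ins <- contrastInserts()
  ai <- which(ins$material == "air")
  a <- ins$angleDeg[ai] * pi / 180
  airCtr <- c(ins$radius[ai] * cos(a), ins$radius[ai] * sin(a), 0)
  calibrateHu(recon,
              waterRoi = list(center = c(0, 0, 0), halfSize = 6),
              airRoi = list(center = airCtr, halfSize = 5))
}

pipelineMetrics <- function(recon, cfg, phantom) {
  hu <- huVolume(recon)
  d <- dim(hu)
  kc <- ceiling(d[3] / 2)
  slice <- hu[, , kc]
  vs <- recon@voxelSize
  out <- list(phantomType = cfg$phantom$type)
  sidePx <- max(3L, round(cfg$metrics$roiSideMm / vs))

  if (cfg$phantom$type %in% c("contrast", "cylinder")) {
    Rpx <- (cfg$phantom$cylDiameter / 2) / vs
    if (cfg$phantom$type == "cylinder") {
      rois <- uniformityRois(d[1:2], Rpx, side = sidePx)
      out$nonuniformitySigmaHu <- nonuniformity(slice, rois)
      cup <- cuppingMeasure(slice, Rpx, side = sidePx)
      out$cuppingHu <- cup$cupping
      out$effectiveAxialFovMm <- effectiveAxialFov(hu, vs, 0.8 * Rpx)
    } else {
      # uniformity ring moved to 0.7 R / 22.5 deg so no ROI touches an insert
      rois <- uniformityRois(d[1:2], (0.7 / 0.6) * Rpx, side = sidePx,
                             angleOffsetDeg = 22.5)
      out$nonuniformitySigmaHu <- nonuniformity(slice, rois)
      specs <- contrastRoiSpecs(cfg, vs, d)
      tab <- lapply(names(specs), function(m) {
        cc <- contrastCnr(slice, specs[[m]]$insert, specs[[m]]$background)
        data.frame(material = m, mean = cc$insertMean, contrast = cc$contrast,
                   cnr = cc$cnr)
      })
      tab <- do.call(rbind, tab)
      out$inserts <- tab
      out$waterMeanHu <- mean(roiPixels(slice, (d[1:2] + 1) / 2, sidePx))
      nominal <- contrastInserts()$hu[match(tab$material,
                                            contrastInserts()$material)]
      out$huRmse <- huRmse(c(tab$mean, out$waterMeanHu), c(nominal, 0))
    }
  } else if (cfg$phantom$type == "defrise") {
    rPx <- round(55 / vs)
    prof <- axialProfile(hu, round(d[1] / 2) + rPx, round(d[2] / 2))
    out$axialProfile <- prof
    out$modulation <- modulation(prof)
  } else if (cfg$phantom$type == "head") {
    mats <- phantom@materials
    cort <- which(mats$name == "cortical")
    canc <- which(mats$name == "cancellous")
    thr <- (mats$hu[cort] + mats$hu[canc]) / 2
    seg <- thresholdSegment(hu, thr, minComponent = 8L)
    out$corticalDice <- diceCoefficient(seg, phantom@labels == cort)
  }
  out
}

#' Run the multisource and single-source configurations side by side
#'
#' Executes \code{\link{runPipeline}} twice on the same phantom and seed:
#' once in the multisource configuration (with scatter correction) and once
#' in the degenerate single-source wide-cone configuration (whose frames
#' cannot be scatter-corrected -- the sampling band has nowhere to go), and
#' reports both metric sets.
#'
#' @param config config list or YAML path.
#' @param outDir optional output directory (subdirectories \code{ms} and
#'   \code{n1}).
#' @return list with elements \code{ms}, \code{n1} and \code{comparison}.
#' @export
runComparison <- function(config, outDir = NULL) {
  cfg <- validateConfig(config)
  cfgMs <- cfg; cfgMs$n1 <- FALSE
  cfgN1 <- cfg; cfgN1$n1 <- TRUE
  ms <- runPipeline(cfgMs, if (is.null(outDir)) NULL else file.path(outDir, "ms"))
  n1 <- runPipeline(cfgN1, if (is.null(outDir)) NULL else file.path(outDir, "n1"))
  cmp <- list()
  for (k in c("nonuniformitySigmaHu", "cuppingHu", "effectiveAxialFovMm",
              "huRmse", "modulation")) {
    if (!is.null(ms$metrics[[k]]) && !is.null(n1$metrics[[k]]))
      cmp[[k]] <- c(ms = ms$metrics[[k]], n1 = n1$metrics[[k]])
  }
  if (!is.null(outDir))
    jsonlite::write_json(cmp, file.path(outDir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(ms = ms, n1 = n1, comparison = cmp)
}
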