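# Shared fixtures.  Heavy simulation products are memoised so module tests
# and the acceptance suite reuse one computation within a test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# desk-scale scanner: full geometry, coarse detector sampling
deskGeometry <- function() buildGeometry(pixelPitch = 2.4)

deskProtocol <- function(nViews = 60L, photonBudget = Inf, seed = 1L) {
  acquisitionProtocol(nViews = nViews, photonBudget = photonBudget, seed = seed)
}

# a phantom with arbitrary smooth attenuation, for projector oracles
randomPhantom <- function(n = 32L, voxelSize = 2, seed = 7L) {
  set.seed(seed)
  raw <- array(runif(n^3, 0, 0.04), dim = c(n, n, n))
  # mild smoothing so nearest-voxel point sampling is a fair oracle
  sm <- raw
  sm[2:(n - 1), , ] <- (raw[1:(n - 2), , ] + raw[2:(n - 1), , ] + raw[3:n, , ]) / 3
  mats <- materialTable(c("air", "stuff"), c(-1000, 0))
  new("VoxelPhantom", voxelSize = voxelSize,
      labels = array(1L, dim = dim(sm)), mu = sm,
      truthHu = array(-1000, dim = dim(sm)), materials = mats)
}

# dense point-sampling oracle for one ray (nearest-voxel Riemann sum)
bruteForcePath <- function(phantom, src, pix, nSamples = 1e4) {
  d <- pix - src
  len <- sqrt(sum(d^2))
  ts <- (seq_len(nSamples) - 0.5) / nSamples
  pts <- cbind(src[1] + ts * d[1], src[2] + ts * d[2], src[3] + ts * d[3])
  dims <- dim(phantom@mu)
  h <- phantom@voxelSize
  idx <- sweep(pts, 2, -dims * h / 2)  # offset to grid corner
  ii <- floor(idx / h) + 1
  ok <- ii[, 1] >= 1 & ii[, 1] <= dims[1] & ii[, 2] >= 1 & ii[, 2] <= dims[2] &
    ii[, 3] >= 1 & ii[, 3] <= dims[3]
  if (!any(ok)) return(0)
  lin <- ii[ok, 1] + dims[1] * (ii[ok, 2] - 1 + dims[2] * (ii[ok, 3] - 1))
  sum(phantom@mu[lin]) * len / nSamples
}

# ---- memoised heavy runs ----------------------------------------------------

# noiseless, scatter-free contrast scan reconstructed to convergence
fixtureRecovery <- function() fixture("recovery", {
  g <- deskGeometry()
  p <- deskProtocol()
  ph <- makeContrast(voxelSize = 4, gridDim = c(48L, 48L, 48L))
  scan <- simulateScan(ph, g, p)
  sys <- buildSystem(g, p, c(48L, 48L, 48L), 4)
  rec <- sirt(logNormalize(scan), sys, nIter = 320L, tvWeight = 1e-4, tvIter = 30L)
  ins <- contrastInserts()
  ai <- which(ins$material == "air")
  a <- ins$angleDeg[ai] * pi / 180
  rec <- calibrateHu(rec,
                     waterRoi = list(center = c(0, 0, 0), halfSize = 6),
                     airRoi = list(center = c(ins$radius[ai] * cos(a),
                                              ins$radius[ai] * sin(a), 0),
                                   halfSize = 5))
  list(phantom = ph, recon = rec)
})

# tall water cylinder (fills the illuminated axial range) with surrogate
# scatter: multisource scan, its ASRS correction, and the wide-cone baseline
fixtureScatterScans <- function() fixture("scatterScans", {
  g <- deskGeometry()
  p <- deskProtocol()
  n1 <- n1Degenerate(g, p)
  ph <- makeContrast(cylDiameter = 160, height = 150, inserts = NULL,
                     voxelSize = 4, gridDim = c(48L, 48L, 48L))
  sm <- scatterModel()
  ms <- simulateScan(ph, g, p, scatter = sm)
  corr <- asrsCorrectSet(ms, asrsParams(bandRows = 5L))
  wide <- simulateScan(ph, n1$geometry, n1$protocol, scatter = sm)
  list(geometry = g, protocol = p, n1 = n1, phantom = ph,
       ms = ms, corrected = corr, wide = wide)
})

# reconstructions of the scattered scans (wide-cone uncorrected vs
# multisource + ASRS), HU-calibrated by the nominal water attenuation
fixtureCupping <- function() fixture("cupping", {
  s <- fixtureScatterScans()
  rec <- function(geom, prot, scan) {
    sys <- buildSystem(geom, prot, c(48L, 48L, 48L), 4)
    calibrateHuLinear(sirt(logNormalize(scan), sys, nIter = 120L))
  }
  wideRec <- rec(s$n1$geometry, s$n1$protocol, s$wide)
  msRec <- rec(s$geometry, s$protocol, s$corrected$projections)
  list(wide = cuppingMeasure(huVolume(wideRec)[, , 24], 20, side = 3L),
       ms = cuppingMeasure(huVolume(msRec)[, , 24], 20, side = 3L),
       wideRec = wideRec, msRec = msRec)
})

# Defrise disc stack reconstructed in both configurations (noiseless)
fixtureDefrise <- function() fixture("defrise", {
  g <- deskGeometry()
  p <- deskProtocol(nViews = 48L)
  n1 <- n1Degenerate(g, p)
  ph <- makeDefrise(voxelSize = 2, gridDim = c(96L, 96L, 64L))
  rec <- function(geom, prot) {
    scan <- simulateScan(ph, geom, prot)
    sys <- buildSystem(geom, prot, c(96L, 96L, 64L), 2)
    calibrateHuLinear(sirt(logNormalize(scan), sys, nIter = 120L))
  }
  list(phantom = ph, ms = rec(g, p), wide = rec(n1$geometry, n1$protocol))
})

# uniform cylinder taller than the axial FOV, both configurations (noiseless)
fixtureAxialFov <- function() fixture("axialFov", {
  g <- deskGeometry()
  p <- deskProtocol()
  n1 <- n1Degenerate(g, p)
  ph <- makeContrast(cylDiameter = 120, height = 150, inserts = NULL,
                     voxelSize = 4, gridDim = c(48L, 48L, 48L))
  rec <- function(geom, prot) {
    scan <- simulateScan(ph, geom, prot)
    sys <- buildSystem(geom, prot, c(48L, 48L, 48L), 4)
    calibrateHuLinear(sirt(logNormalize(scan), sys, nIter = 120L))
  }
  msFov <- effectiveAxialFov(huVolume(rec(g, p)), 4, 0.8 * 15)
  wideFov <- effectiveAxialFov(huVolume(rec(n1$geometry, n1$protocol)), 4, 0.8 * 15)
  list(ms = msFov, wide = wideFov)
})
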