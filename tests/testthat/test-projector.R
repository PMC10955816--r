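test_that("traced paths match analytic chords through a uniform cylinder", {
  ph <- makeContrast(cylDiameter = 50, height = 50, inserts = NULL,
                     voxelSize = 0.5, gridDim = c(128L, 128L, 128L))
  g <- buildGeometry(pixelPitch = 1.0)
  s <- 4L
  zs <- sourcePositions(g)[s]
  fr <- projectFrame(ph, g, s, 0)
  np <- detectorPixels(g)
  vr <- (seq_len(np["nv"]) - (np["nv"] + 1) / 2) * g@pixelPitch
  iv <- which.min(abs(vr - zs))  # central ray, perpendicular to the axis
  uCoord <- g@lateralOffset + (seq_len(np["nu"]) - (np["nu"] + 1) / 2) * g@pixelPitch

  relErr <- vapply(c(0, 10, 23, 30), function(uTarget) {
    iu <- which.min(abs(uCoord - uTarget))
    S <- c(-g@sid, 0); P <- c(g@sdd - g@sid, uCoord[iu])
    d <- (P - S) / sqrt(sum((P - S)^2))
    dist <- abs(S[1] * d[2] - S[2] * d[1])
    chord <- if (dist < 25) 2 * sqrt(25^2 - dist^2) * 0.02 else 0
    abs(fr@data[iu, iv] - chord) / max(chord, 1e-12)
  }, numeric(1))
  expect_lt(relErr[1], 0.005)      # central ray
  expect_true(all(relErr < 0.01))  # off-centre chords
})

test_that("an empty phantom projects to an all-zero frame", {
  ph <- makeDefrise(nDiscs = 0L, voxelSize = 2, gridDim = c(32L, 32L, 16L))
  fr <- projectFrame(ph, buildGeometry(pixelPitch = 4.8), 1L, 33)
  expect_true(all(fr@data == 0))
  expect_error(projectFrame(ph, buildGeometry(), 9L, 0), "out of range")
})

test_that("traced paths agree with a dense point-sampling oracle", {
  ph <- randomPhantom(32L, 2)
  g <- buildGeometry(pixelPitch = 4.8)
  fr <- projectFrame(ph, g, 3L, 40)
  fg <- mscbct:::frameGeometryMatrices(g, 3L, 40, band = "full")
  np <- detectorPixels(g)
  set.seed(11)
  picks <- cbind(sample(np["nu"], 40, replace = TRUE),
                 sample(np["nv"], 40, replace = TRUE))
  traced <- fr@data[picks]
  oracle <- vapply(seq_len(nrow(picks)), function(k) {
    iu <- picks[k, 1]; iv <- picks[k, 2]
    pix <- fg$detc[1, ] + (iu - (np["nu"] + 1) / 2) * g@pixelPitch * fg$uhat[1, ] +
      (iv - (np["nv"] + 1) / 2) * g@pixelPitch * fg$vhat[1, ]
    bruteForcePath(ph, fg$src[1, ], pix)
  }, numeric(1))
  keep <- oracle > 0.05  # rays with substantial intersection
  rms <- sqrt(mean(((traced[keep] - oracle[keep]) / oracle[keep])^2))
  expect_lt(rms, 0.01)
})

test_that("a point at the isocenter projects with SDD/SID magnification", {
  mats <- materialTable(c("air", "metal"), c(-1000, 30000))
  g <- buildGeometry(pixelPitch = 1.0)
  n <- 33L
  lab <- array(1L, c(n, n, n)); lab[17, 17, 17] <- 2L
  ph <- new("VoxelPhantom", voxelSize = 1, labels = lab,
            mu = array(materialTable(c("a", "b"), c(-1000, 30000))$mu[lab], c(n, n, n)),
            truthHu = array(mats$hu[lab], c(n, n, n)), materials = mats)
  np <- detectorPixels(g)
  for (ang in c(0, 37, 122, 260)) {
    fr <- projectFrame(ph, g, 4L, ang)
    hot <- which(fr@data == max(fr@data), arr.ind = TRUE)[1, ]
    # the isocenter maps to detector u-coordinate 0 for every angle
    uPix <- g@lateralOffset + (hot[1] - (np["nu"] + 1) / 2) * g@pixelPitch
    expect_lt(abs(uPix) / g@pixelPitch, 0.5 + 0.5)  # within half a pixel + centre offset
  }
})

test_that("collimation restricts frames to the nominal band", {
  g <- buildGeometry()  # 0.198 mm pixels
  np <- detectorPixels(g)
  fr <- new("ProjectionFrame", data = matrix(1, np["nu"], np["nv"]),
            domain = "intensity", sourceIndex = 4L, angle = 0,
            bandRows = c(NA_integer_, NA_integer_),
            supportRows = c(NA_integer_, NA_integer_),
            maskV = rep(1, np["nv"]))
  cf <- applyCollimation(fr, g)
  width <- cf@bandRows[2] - cf@bandRows[1] + 1
  expect_equal(width, round(32.5 / 0.198), tolerance = 1)
  vr <- (seq_len(np["nv"]) - (np["nv"] + 1) / 2) * g@pixelPitch
  expect_lt(abs(mean(vr[cf@bandRows]) - sourcePositions(g)[4]), g@pixelPitch)

  # wide-beam configuration: no masking
  n1 <- n1Degenerate(g)
  cfN1 <- applyCollimation(initialize(fr, sourceIndex = 1L), n1)
  expect_true(all(cfN1@data == 1))

  # penumbra only removes energy
  gHard <- buildGeometry(penumbraSigma = 0)
  expect_lte(sum(applyCollimation(fr, g)@data),
             sum(fr@data))
  expect_lte(sum(applyCollimation(fr, gHard)@data),
             sum(applyCollimation(fr, g)@data))
})

test_that("intensity conversion follows Beer-Lambert with Poisson sampling", {
  g <- buildGeometry(pixelPitch = 2.4)
  np <- detectorPixels(g)
  mk <- function(p) {
    fr <- new("ProjectionFrame", data = matrix(p, np["nu"], np["nv"]),
              domain = "lineIntegral", sourceIndex = 1L, angle = 0,
              bandRows = c(NA_integer_, NA_integer_),
              supportRows = c(NA_integer_, NA_integer_),
              maskV = rep(1, np["nv"]))
    fr
  }
  expect_equal(unique(as.numeric(toIntensity(mk(0), 1e4)@data)), 1e4)
  expect_equal(unique(as.numeric(toIntensity(mk(log(2)), 1e4)@data)), 5e3)
  expect_error(toIntensity(mk(0), -1), "i0")

  noisy <- toIntensity(mk(log(2)), 1e4, noise = TRUE, seed = 42L)
  m <- mean(noisy@data)
  se <- sqrt(5e3 / length(noisy@data))
  expect_lt(abs(m - 5e3), 3 * se)
})

test_that("a full scan has nViews x nSources frames in (view, source) order", {
  g <- buildGeometry(pixelPitch = 4.8)
  ph <- makeContrast(cylDiameter = 100, height = 60, inserts = NULL,
                     voxelSize = 4, gridDim = c(32L, 32L, 32L))
  p <- acquisitionProtocol(nViews = 3L, photonBudget = Inf)
  scan <- simulateScan(ph, g, p)
  expect_equal(dim(scan@data)[3], 24)
  fi <- frameInfo(scan)
  expect_equal(fi$source, rep(1:8, 3))
  expect_equal(fi$view, rep(1:3, each = 8))
  expect_equal(fi$angle, rep(gantryAngles(p), each = 8))

  p1 <- acquisitionProtocol(nViews = 1L, nSources = 1L, photonBudget = Inf)
  scan1 <- simulateScan(ph, n1Degenerate(g), p1)
  expect_equal(dim(scan1@data)[3], 1)
})

test_that("identical seeds give bit-identical noisy scans", {
  g <- buildGeometry(pixelPitch = 4.8)
  ph <- makeContrast(cylDiameter = 100, height = 60, inserts = NULL,
                     voxelSize = 4, gridDim = c(32L, 32L, 32L))
  p <- acquisitionProtocol(nViews = 2L, photonBudget = 5e3, seed = 9L)
  s1 <- simulateScan(ph, g, p, scatter = scatterModel())
  s2 <- simulateScan(ph, g, p, scatter = scatterModel())
  expect_identical(s1@data, s2@data)
  p2 <- acquisitionProtocol(nViews = 2L, photonBudget = 5e3, seed = 10L)
  expect_false(identical(simulateScan(ph, g, p2)@data, s1@data))
})

test_that("every FOV voxel is seen from at least half of the views", {
  g <- buildGeometry(pixelPitch = 4.8)
  p <- acquisitionProtocol(nViews = 12L, photonBudget = Inf)
  sys <- buildSystem(g, p, c(24L, 24L, 8L), 8)
  nf <- nrow(sys@src)
  perView <- array(0L, c(24L, 24L, 8L))
  for (v in seq_len(p@nViews)) {
    sel <- frameInfo(sys)$view == v
    sub <- sys
    sub@src <- sys@src[sel, , drop = FALSE]
    sub@detc <- sys@detc[sel, , drop = FALSE]
    sub@uhat <- sys@uhat[sel, , drop = FALSE]
    sub@vhat <- sys@vhat[sel, , drop = FALSE]
    sub@band <- sys@band[sel, , drop = FALSE]
    sub@frameInfo <- sys@frameInfo[sel, ]
    cov <- backProject(sub, array(1, c(sys@nu, sys@nv, sum(sel))))
    perView <- perView + (cov > 0)
  }
  c0 <- 12.5
  xy <- (1:24 - c0) * 8
  r <- sqrt(outer(xy^2, xy^2, "+"))
  inFov <- r <= 80  # well inside the 93.5 mm advertised radius
  central <- perView[, , 4][inFov]
  expect_true(all(central >= p@nViews / 2))
})
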