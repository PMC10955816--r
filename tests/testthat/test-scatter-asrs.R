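# helper: a synthetic collimated intensity frame on the desk-scale panel
syntheticFrame <- function(geometry, source = 4L, value = 1000) {
  np <- detectorPixels(geometry)
  fr <- new("ProjectionFrame", data = matrix(value, np["nu"], np["nv"]),
            domain = "intensity", sourceIndex = as.integer(source), angle = 0,
            bandRows = c(NA_integer_, NA_integer_),
            supportRows = c(NA_integer_, NA_integer_),
            maskV = rep(1, np["nv"]))
  applyCollimation(fr, geometry)
}

test_that("zero-amplitude scatter leaves frames unchanged", {
  g <- buildGeometry(pixelPitch = 2.4)
  fr <- syntheticFrame(g)
  out <- injectScatter(fr, scatterModel(amplitude = 0), g)
  expect_identical(out$frame@data, fr@data)
  expect_true(all(out$scatter == 0))
  expect_error(scatterModel(kernelSigma = -1), "kernelSigma")
})

test_that("scatter extends beyond the collimated band and scales with its width", {
  g <- buildGeometry(pixelPitch = 2.4)
  fr <- syntheticFrame(g)
  out <- injectScatter(fr, scatterModel(), g)
  outside <- setdiff(seq_len(ncol(fr@data)), fr@supportRows[1]:fr@supportRows[2])
  expect_gt(sum(out$scatter[, outside]), 0)
  expect_true(all(out$scatter >= 0))

  # in-band SPR is proportional to the band width by construction
  gWide <- buildGeometry(pixelPitch = 2.4, beamFwhm = 65)
  frW <- syntheticFrame(gWide)
  band <- function(f) f@bandRows[1]:f@bandRows[2]
  sprN <- mean(injectScatter(fr, scatterModel(), g)$scatter[, band(fr)]) /
    mean(fr@data[, band(fr)])
  sprW <- mean(injectScatter(frW, scatterModel(), gWide)$scatter[, band(frW)]) /
    mean(frW@data[, band(frW)])
  wN <- length(band(fr)) * g@pixelPitch
  wW <- length(band(frW)) * gWide@pixelPitch
  expect_equal(sprW / sprN, wW / wN, tolerance = 0.02)
})

test_that("the raw adjacent ratio recovers S/(P+S) on constructed frames", {
  g <- buildGeometry(pixelPitch = 2.4, penumbraSigma = 0)
  fr <- syntheticFrame(g, value = 1000)  # uniform primary P in the band
  S <- 250
  fr@data <- fr@data + S                 # uniform scatter everywhere
  m <- measureAdjacentRatio(fr, g, asrsParams(bandRows = 5L))
  expect_equal(unique(round(m$r, 12)), S / (1000 + S))
  # on the physical panel only one side fits each beam at the 50 mm offset
  expect_true(length(m$side) >= 1 && all(m$side %in% c("low", "high")))

  # a taller panel accommodates the sampling band on both sides
  gTall <- buildGeometry(pixelPitch = 2.4, detHeight = 240, penumbraSigma = 0)
  frT <- syntheticFrame(gTall, value = 1000)
  frT@data <- frT@data + S
  mT <- measureAdjacentRatio(frT, gTall, asrsParams(bandRows = 5L))
  expect_setequal(mT$side, c("low", "high"))
  expect_equal(unique(round(mT$r, 12)), S / (1000 + S))

  frZero <- syntheticFrame(g, value = 1000)
  mz <- measureAdjacentRatio(frZero, g, asrsParams(bandRows = 5L))
  expect_true(all(mz$r == 0))
})

test_that("sampling rows sit at the nominal offset from the band centre", {
  g <- buildGeometry()  # 0.198 mm pixels, the physical panel
  fr <- syntheticFrame(g, source = 4L)
  m <- measureAdjacentRatio(fr, g, asrsParams(bandOffset = 50, bandRows = 50L))
  center <- mean(fr@bandRows)
  offRows <- round(50 / 0.198)
  expect_equal(offRows, 253)
  for (s in m$side) {
    rows <- m$rows[[s]]
    expect_length(rows, 50)
    expect_lt(abs(abs(mean(rows) - center) - offRows), 1)
  }
})

test_that("wide-beam frames are flagged unavailable, misconfiguration errors", {
  g <- buildGeometry(pixelPitch = 2.4)
  n1 <- n1Degenerate(g)
  frN1 <- syntheticFrame(n1, source = 1L)
  expect_error(measureAdjacentRatio(frN1, n1, asrsParams(bandRows = 5L)),
               class = "asrsUnavailableError")
  # sampling band overlapping a narrow beam is a configuration error
  fr <- syntheticFrame(g)
  expect_error(measureAdjacentRatio(fr, g, asrsParams(bandOffset = 18,
                                                      bandRows = 5L)),
               "overlaps")
})

test_that("spline smoothing reproduces constants, denoises trends and clips", {
  prm <- asrsParams()
  rConst <- rep(0.3, 80)
  expect_equal(smoothRatio(rConst, prm), rConst)

  set.seed(3)
  trend <- seq(0.1, 0.5, length.out = 200)
  noisy <- trend + rnorm(200, 0, 0.05)
  sm <- smoothRatio(noisy, prm)
  expect_lt(sqrt(mean((sm - trend)^2)), sqrt(mean((noisy - trend)^2)))

  expect_equal(smoothRatio(rep(2, 50), prm), rep(0.95, 50))
  expect_error(smoothRatio(rep(NA_real_, 10), prm), "finite")
})

test_that("uniform scatter is removed exactly and correction is monotone", {
  g <- buildGeometry(pixelPitch = 2.4, penumbraSigma = 0)
  fr <- syntheticFrame(g, value = 1000)
  prim <- fr@data
  fr@data <- fr@data + 250
  cf <- asrsCorrect(fr, g, asrsParams(bandRows = 5L))
  rows <- fr@bandRows[1]:fr@bandRows[2]
  expect_equal(cf@data[, rows], prim[, rows], tolerance = 1e-12)
  expect_true(all(cf@data <= fr@data + 1e-9))
  expect_true(all(cf@rSmooth >= 0 & cf@rSmooth <= 0.95))

  # zero scatter: correction is the identity within floating tolerance
  fr0 <- syntheticFrame(g, value = 1000)
  cf0 <- asrsCorrect(fr0, g, asrsParams(bandRows = 5L))
  expect_equal(cf0@data, fr0@data, tolerance = 1e-12)
})

test_that("ASRS removes most injected scatter in a full simulated scan", {
  s <- fixtureScatterScans()
  expect_gte(scatterRemovalFraction(s$ms, s$corrected$projections), 0.8)
  expect_true(all(s$corrected$diagnostics$corrected))
  expect_true(all(s$corrected$projections@data <= s$ms@data + 1e-9))
})

test_that("narrow beams have proportionally lower SPR than the wide cone", {
  s <- fixtureScatterScans()
  ratio <- meanSpr(s$ms) / meanSpr(s$wide)
  bandRatio <- 32.5 / 113.7
  expect_lt(abs(ratio - bandRatio) / bandRatio, 0.1)
  # ordering: corrected ms < uncorrected ms < wide cone (by construction +
  # correction)
  expect_lt(meanSpr(s$ms), meanSpr(s$wide))
})

test_that("log-normalization inverts Beer-Lambert on the illuminated support", {
  g <- buildGeometry(pixelPitch = 4.8)
  ph <- makeContrast(cylDiameter = 100, height = 60, inserts = NULL,
                     voxelSize = 4, gridDim = c(32L, 32L, 32L))
  p <- acquisitionProtocol(nViews = 2L, photonBudget = Inf)
  scan <- simulateScan(ph, g, p)
  li <- logNormalize(scan)
  expect_equal(li@domain, "lineIntegral")
  expect_true(all(li@data >= 0))
  # umbra rays reproduce the exact forward projection
  sys <- buildSystem(g, p, dim(ph@mu), 4)
  ptrue <- forwardProject(sys, ph@mu)
  sel <- ptrue > 0
  expect_lt(max(abs(li@data[sel] - ptrue[sel])), 1e-9)
})
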