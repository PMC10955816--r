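toySystem <- function() {
  g <- buildGeometry(pixelPitch = 9.6)
  p <- acquisitionProtocol(nViews = 1L, photonBudget = Inf)
  buildSystem(g, p, c(32L, 32L, 32L), 6)
}

test_that("forward and adjoint operators form a matched pair", {
  sys <- toySystem()
  set.seed(5)
  x <- array(runif(prod(sys@gridDim)), dim = sys@gridDim)
  y <- array(runif(sys@nu * sys@nv * nrow(sys@src)),
             dim = c(sys@nu, sys@nv, nrow(sys@src)))
  lhs <- sum(forwardProject(sys, x) * y)
  rhs <- sum(x * backProject(sys, y))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-4)
})

test_that("trivial inputs map through the system model as expected", {
  sys <- toySystem()
  expect_true(all(forwardProject(sys, array(0, sys@gridDim)) == 0))
  zero <- array(0, c(sys@nu, sys@nv, nrow(sys@src)))
  rec <- sirt(zero, sys, nIter = 5L)
  expect_true(all(rec@mu == 0))
  # band-masked pixels contribute nothing in either direction
  pr <- forwardProject(sys, array(1, sys@gridDim))
  fi <- frameInfo(sys)
  outside <- setdiff(seq_len(sys@nv), (sys@band[1, 1] + 1):(sys@band[1, 2] + 1))
  expect_true(all(pr[, outside, 1] == 0))
})

test_that("the single-source system is the multisource system restricted", {
  g <- buildGeometry(pixelPitch = 9.6)
  p <- acquisitionProtocol(nViews = 2L, photonBudget = Inf)
  sysMs <- buildSystem(g, p, c(24L, 24L, 24L), 8)
  n1 <- n1Degenerate(g, p)
  sysN1 <- buildSystem(n1$geometry, n1$protocol, c(24L, 24L, 24L), 8)
  expect_equal(nrow(sysN1@src), 2)
  expect_equal(nrow(sysMs@src), 16)
  expect_equal(sysN1@src[, 1:2], sysMs@src[c(1, 9), 1:2])  # same focal track
  expect_equal(sysN1@src[, 3], c(0, 0))                    # mid-plane source
})

test_that("SIRT recovers an impulse at the right location", {
  g <- buildGeometry(pixelPitch = 4.8)
  p <- acquisitionProtocol(nViews = 12L, photonBudget = Inf)
  sys <- buildSystem(g, p, c(24L, 24L, 24L), 4)
  truth <- array(0, c(24L, 24L, 24L))
  truth[15, 10, 12] <- 0.05
  proj <- forwardProject(sys, truth)
  rec <- sirt(proj, sys, nIter = 60L)
  hot <- which(rec@mu == max(rec@mu), arr.ind = TRUE)[1, ]
  expect_equal(as.integer(hot), c(15L, 10L, 12L))
})

test_that("the SIRT residual is non-increasing on noiseless data", {
  g <- buildGeometry(pixelPitch = 4.8)
  p <- acquisitionProtocol(nViews = 12L, photonBudget = Inf)
  ph <- makeContrast(cylDiameter = 80, height = 60, inserts = NULL,
                     voxelSize = 4, gridDim = c(24L, 24L, 24L))
  sys <- buildSystem(g, p, c(24L, 24L, 24L), 4)
  rec <- sirt(logNormalize(simulateScan(ph, g, p)), sys, nIter = 40L)
  r <- rec@residuals
  expect_true(all(diff(r[-(1:5)]) <= 1e-8 * r[1]))
  expect_error(sirt(array(NaN, c(sys@nu, sys@nv, nrow(sys@src))), sys),
               "non-finite")
})

test_that("TV denoising is the identity at weight zero and on constants", {
  set.seed(2)
  v <- array(rnorm(20^3), c(20L, 20L, 20L))
  expect_identical(tvDenoise(v, 0), v)
  const <- array(3.7, c(12L, 12L, 12L))
  expect_equal(tvDenoise(const, 0.5, 30L), const, tolerance = 1e-6)
})

test_that("TV reduces flat-region variance without moving edges", {
  set.seed(4)
  n <- 24L
  step <- array(0, c(n, n, n))
  step[13:n, , ] <- 1
  noisy <- step + array(rnorm(n^3, 0, 0.15), c(n, n, n))
  den <- tvDenoise(noisy, 0.1, 40L)
  flat <- den[1:10, , ]
  expect_lt(var(as.numeric(flat)), var(as.numeric(noisy[1:10, , ])))
  # half-max crossing along x stays within one voxel of the true edge
  prof <- apply(den, 1, mean)
  cross <- which(prof >= 0.5)[1]
  expect_lte(abs(cross - 13), 1)
})

test_that("two-point HU calibration maps the reference ROIs to 0 and -1000", {
  set.seed(6)
  mu <- array(0.02, c(16L, 16L, 16L))
  mu[1:4, 1:4, ] <- 0.001
  rec <- new("ReconVolume", mu = mu, hu = array(numeric(0), c(0L, 0L, 0L)),
             voxelSize = 1, iterations = 0L, residuals = numeric(),
             provenance = list())
  wm <- array(FALSE, dim(mu)); wm[10:12, 10:12, 8] <- TRUE
  am <- array(FALSE, dim(mu)); am[2:3, 2:3, 8] <- TRUE
  cal <- calibrateHu(rec, wm, am)
  expect_equal(mean(huVolume(cal)[wm]), 0, tolerance = 1e-9)
  expect_equal(mean(huVolume(cal)[am]), -1000, tolerance = 1e-9)
  expect_error(calibrateHu(rec, am, wm), "degenerate")

  lin <- calibrateHuLinear(rec, 0.02)
  expect_equal(huVolume(lin)[8, 8, 8], 0)
})

test_that("noiseless end-to-end recovery hits nominal HU within tolerance", {
  r <- fixtureRecovery()
  m <- mscbct:::pipelineMetrics(r$recon,
                                modifyList(deskSmallConfig(1),
                                           list(phantom = list(
                                             type = "contrast", voxelSize = 4,
                                             gridDim = c(48L, 48L, 48L),
                                             cylDiameter = 160, height = 80))),
                                r$phantom)
  nominal <- contrastInserts()$hu[match(m$inserts$material,
                                        contrastInserts()$material)]
  expect_true(all(abs(m$inserts$mean - nominal) <= 25))
  expect_lt(abs(m$waterMeanHu), 25)
  # interior attenuation error below 5% of water
  d <- dim(r$phantom@mu)
  marg <- round(d * 0.15)
  idx <- lapply(1:3, function(a) (marg[a] + 1):(d[a] - marg[a]))
  err <- r$recon@mu[idx[[1]], idx[[2]], idx[[3]]] -
    r$phantom@mu[idx[[1]], idx[[2]], idx[[3]]]
  expect_lt(sqrt(mean(err^2)) / 0.02, 0.05)
})
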