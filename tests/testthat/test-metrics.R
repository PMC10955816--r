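test_that("nonuniformity is the sd of nine ROI means", {
  slice <- matrix(5, 120, 120)
  rois <- uniformityRois(c(120, 120), 40, side = 10L)
  expect_equal(nonuniformity(slice, rois), 0)
  expect_error(nonuniformity(slice, rois[1:5]), "exactly 9")

  # eight ROI means of 0 and one of 3 give sd 1 with the n-1 denominator
  slice2 <- matrix(0, 120, 120)
  slice2[56:65, 56:65] <- 3  # the central ROI
  expect_equal(nonuniformity(slice2, rois), 1)

  # radial cupping raises the spread over the flat slice
  xy <- (1:120 - 60.5)
  bowl <- 5 - 60 * (1 - outer(xy^2, xy^2, "+") / (2 * 60^2))
  expect_gt(nonuniformity(bowl, rois), nonuniformity(slice, rois))
})

test_that("contrast and CNR follow their ROI definitions", {
  slice <- matrix(0, 80, 80)
  set.seed(8)
  slice[] <- rnorm(length(slice), 0, 10)
  slice[31:40, 31:40] <- slice[31:40, 31:40] + 100
  ins <- list(center = c(35.5, 35.5), side = 10L)
  bgs <- list(list(center = c(15.5, 35.5), side = 10L),
              list(center = c(55.5, 35.5), side = 10L))
  cc <- contrastCnr(slice, ins, bgs)
  expect_equal(cc$contrast, abs(cc$insertMean - cc$backgroundMean))
  expect_equal(cc$cnr, cc$contrast / cc$backgroundSd)
  expect_lt(abs(cc$contrast - 100), 10)

  # affine invariances
  cc2 <- contrastCnr(slice + 500, ins, bgs)
  expect_equal(cc2$contrast, cc$contrast, tolerance = 1e-9)
  expect_equal(cc2$cnr, cc$cnr, tolerance = 1e-9)
  cc3 <- contrastCnr(slice * 2, ins, bgs)
  expect_equal(cc3$contrast, 2 * cc$contrast, tolerance = 1e-9)
  expect_equal(cc3$cnr, cc$cnr, tolerance = 1e-9)

  flat <- matrix(1, 80, 80)
  expect_equal(contrastCnr(flat, ins, bgs)$contrast, 0)
  flat[31:40, 31:40] <- 2
  expect_error(contrastCnr(flat, ins, bgs), "zero")
})

test_that("percentage improvements reproduce the published comparison table", {
  tab <- benchmarkContrastTable()
  # printed improvement columns: contrast 24.6/26.4/17.2/35.8 %,
  # CNR 53.4/38.1/36.2/56.1 % -- recomputation from the printed cells must
  # agree within one point (the table's own cells are rounded)
  impContrast <- improvement(tab$contrast_n1, tab$contrast_ms)
  impCnr <- improvement(tab$cnr_n1, tab$cnr_ms)
  expect_true(all(abs(impContrast - c(24.6, 26.4, 17.2, 35.8)) <= 1))
  expect_true(all(abs(impCnr - c(53.4, 38.1, 36.2, 56.1)) <= 1))
  expect_equal(round(impContrast[4], 1), 35.8)

  expect_equal(improvement(3, 3), 0)
  expect_error(improvement(0, 1), "zero")
})

test_that("HU RMSE reproduces the published accuracy summary", {
  tab <- benchmarkHuTable()
  expect_equal(round(huRmse(tab$ms, tab$mdct)), 145)
  expect_equal(round(huRmse(tab$n1, tab$mdct)), 385)
  expect_equal(round(huRmse(tab$cbct_m, tab$mdct)), 316)
  expect_equal(huRmse(tab$mdct, tab$mdct), 0)
  expect_error(huRmse(1:3, 1:4), "length")
})

test_that("axial profiles and modulation behave on truth volumes", {
  ph <- makeDefrise(voxelSize = 2, gridDim = c(96L, 96L, 64L))
  prof <- axialProfile(huVolume(ph), 48 + 28, 48)  # r = 56 mm line
  expect_length(prof, 64)
  expect_gt(modulation(prof), 0.99)  # near-perfect disc/air alternation

  expect_equal(modulation(rep(100, 30)), 0)
  expect_error(modulation(prof, 60:70), "window")
  expect_error(axialProfile(huVolume(ph), 500, 1), "outside")
})

test_that("effective axial FOV measures the undistorted slice range", {
  hu <- array(0, c(32L, 32L, 40L))
  expect_equal(effectiveAxialFov(hu, 2, 10), 80)  # full height, no distortion
  hu2 <- hu
  hu2[, , 1:5] <- -200
  hu2[, , 36:40] <- -200
  expect_equal(effectiveAxialFov(hu2, 2, 10), 60)
  hu3 <- hu; hu3[, , 20] <- 500  # central slice inconsistent with itself
  expect_equal(effectiveAxialFov(hu3, 2, 10, tolerance = 50), 2)
})

test_that("nonparametric Bland-Altman matches a sort-based percentile oracle", {
  d <- 1:100
  ba <- blandAltmanNonnormal(d + 5, rep(5, 100))
  expect_equal(ba$median, 50.5)
  expect_equal(ba$p2.5, 3.475)
  expect_equal(ba$p97.5, 97.525)

  same <- rnorm(50)
  ba0 <- blandAltmanNonnormal(same, same)
  expect_equal(unlist(ba0[c("median", "p2.5", "p97.5")]),
               c(median = 0, p2.5 = 0, p97.5 = 0))

  set.seed(12)
  for (n in c(10, 131, 251, 1000)) {
    a <- rexp(n); b <- rnorm(n)
    ba <- blandAltmanNonnormal(a, b)
    expect_equal(ba$median, median(a - b))
    expect_equal(ba$p2.5, unname(quantile(a - b, 0.025, type = 7)))
    expect_equal(ba$p97.5, unname(quantile(a - b, 0.975, type = 7)))
  }
  expect_error(blandAltmanNonnormal(1:3, 1:4), "equal length")
  expect_error(blandAltmanNonnormal(1, 2), "at least 2")
})

test_that("threshold segmentation obeys its limiting cases", {
  ph <- makeHead(voxelSize = 4, gridDim = c(48L, 48L, 24L))
  hu <- huVolume(ph)
  expect_true(all(thresholdSegment(hu, -2000)))
  expect_true(!any(thresholdSegment(hu, max(hu) + 1)))

  # small-component removal: an isolated speck disappears
  vol <- array(0, c(20L, 20L, 20L))
  vol[5:10, 5:10, 5:10] <- 100
  vol[18, 18, 18] <- 100
  seg <- thresholdSegment(vol, 50, minComponent = 8L)
  expect_false(seg[18, 18, 18])
  expect_true(all(seg[5:10, 5:10, 5:10]))
})

test_that("metrics are pure functions of their inputs", {
  set.seed(13)
  slice <- matrix(rnorm(100 * 100), 100, 100)
  rois <- uniformityRois(c(100, 100), 30, side = 8L)
  expect_identical(nonuniformity(slice, rois), nonuniformity(slice, rois))
  expect_identical(cuppingMeasure(slice, 30, 8L), cuppingMeasure(slice, 30, 8L))
})
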