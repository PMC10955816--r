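#' Convert Hounsfield units to linear attenuation
#'
#' The package uses a monoenergetic attenuation model throughout:
#' \code{mu = muWater * (1 + hu/1000)}, clipped at zero.  Water maps to
#' \code{muWater}, air (-1000 HU) to zero.
#'
#' @param hu Hounsfield values (>= -1000).
#' @param muWater attenuation of water (mm^-1); the default 0.02 corresponds
#'   to an effective energy near 60-70 keV, typical of a 90 kVp beam.
#' @return attenuation in mm^-1.
#' @export
huToMu <- function(hu, muWater = 0.02) {
  if (any(hu < -1000 - 1e-9, na.rm = TRUE))
    stop("Hounsfield values below -1000 are not physical")
  pmax(0, muWater * (1 + hu / 1000))
}

#' Convert linear attenuation to Hounsfield units (theoretical calibration)
#'
#' Inverse of \code{\link{huToMu}}; used to calibrate noiseless
#' reconstructions of phantoms that contain no water reference region.
#'
#' @param mu attenuation (mm^-1).
#' @param muWater attenuation of water (mm^-1).
#' @return Hounsfield values.
#' @export
muToHu <- function(mu, muWater = 0.02) {
  1000 * (mu / muWater - 1)
}

#' Material table
#'
#' Nominal Hounsfield values of the materials used by the phantom builders.
#' Water is 0 HU and air -1000 HU by definition; acrylic (120), LDPE (-95)
#' and air follow the standard ACR 464 nominal values.  The machinable glass
#' ceramic has no standard nominal value at this beam quality; its default of
#' 2400 HU is a package convention chosen near diagnostic-CT readings of the
#' material and is configurable.
#'
#' @param names character vector of material names.
#' @param hu nominal HU, same length.
#' @param muWater water attenuation used to derive mu (mm^-1).
#' @return data.frame with columns \code{name}, \code{hu}, \code{mu}.
#' @export
materialTable <- function(names, hu, muWater = 0.02) {
  stopifnot(length(names) == length(hu), !anyDuplicated(names))
  data.frame(name = as.character(names), hu = as.numeric(hu),
             mu = huToMu(hu, muWater), stringsAsFactors = FALSE)
}

#' @rdname materialTable
#' @export
defaultMaterials <- function(muWater = 0.02) {
  materialTable(
    c("air", "water", "acrylic", "ldpe", "macor",
      "soft", "cancellous", "cortical"),
    c(-1000, 0, 120, -95, 2400, 40, 300, 1500),
    muWater = muWater)
}

# ---- shape rasterizer -------------------------------------------------------
#
# Phantoms are built from analytic solids rasterized at `supersample` times
# the voxel resolution; mu is averaged over subvoxels (fractional attenuation
# on boundaries), labels take the majority subvoxel material.  Later shapes
# overwrite earlier ones; the background is always air (material index 1).

shapeCylinder <- function(material, cx = 0, cy = 0, radius, z0, z1) {
  list(type = "cylinder", material = material, cx = cx, cy = cy,
       radius = radius, z0 = z0, z1 = z1)
}

shapeEllipticCylinder <- function(material, cx = 0, cy = 0, a, b, z0, z1) {
  list(type = "elliptic", material = material, cx = cx, cy = cy,
       a = a, b = b, z0 = z0, z1 = z1)
}

shapeArcAnnulus <- function(material, cx = 0, cy = 0, r0, r1,
                            angle0, angle1, z0, z1) {
  list(type = "arc", material = material, cx = cx, cy = cy, r0 = r0, r1 = r1,
       angle0 = angle0, angle1 = angle1, z0 = z0, z1 = z1)
}

rasterPhantom <- function(gridDim, voxelSize, shapes, materials,
                          supersample = 2L) {
  ss <- as.integer(supersample)
  nx <- gridDim[1]; ny <- gridDim[2]; nz <- gridDim[3]
  nxs <- nx * ss; nys <- ny * ss; nzs <- nz * ss
  hs <- voxelSize / ss
  xs <- (seq_len(nxs) - 0.5) * hs - nx * voxelSize / 2
  ys <- (seq_len(nys) - 0.5) * hs - ny * voxelSize / 2
  zs <- (seq_len(nzs) - 0.5) * hs - nz * voxelSize / 2
  half <- c(nx, ny, nz) * voxelSize / 2

  subLab <- array(1L, dim = c(nxs, nys, nzs))
  X <- matrix(xs, nxs, nys)
  Y <- matrix(ys, nxs, nys, byrow = TRUE)
  for (sh in shapes) {
    m <- match(sh$material, materials$name)
    if (is.na(m)) stop("unknown material: ", sh$material)
    if (sh$z0 < -half[3] - 1e-9 || sh$z1 > half[3] + 1e-9)
      stop(sprintf("shape [%s] spans z = [%.1f, %.1f] mm but the grid covers [%.1f, %.1f]",
                   sh$material, sh$z0, sh$z1, -half[3], half[3]))
    mask2 <- switch(sh$type,
      cylinder = (X - sh$cx)^2 + (Y - sh$cy)^2 <= sh$radius^2,
      elliptic = ((X - sh$cx) / sh$a)^2 + ((Y - sh$cy) / sh$b)^2 <= 1,
      arc = {
        r2 <- (X - sh$cx)^2 + (Y - sh$cy)^2
        ang <- atan2(Y - sh$cy, X - sh$cx) * 180 / pi
        ang <- (ang - sh$angle0) %% 360
        r2 >= sh$r0^2 & r2 <= sh$r1^2 & ang <= (sh$angle1 - sh$angle0) %% 360
      },
      stop("unknown shape type"))
    if (sh$type %in% c("cylinder", "elliptic")) {
      rmax <- if (sh$type == "cylinder") sh$radius else max(sh$a, sh$b)
      if (abs(sh$cx) + rmax > half[1] + 1e-9 || abs(sh$cy) + rmax > half[2] + 1e-9)
        stop(sprintf("shape [%s] exceeds the transaxial grid extent", sh$material))
    }
    kz <- which(zs >= sh$z0 & zs <= sh$z1)
    if (!length(kz) || !any(mask2)) next
    idx2 <- which(mask2)
    plane <- as.double(nxs) * nys
    tgt <- rep(idx2, times = length(kz)) +
      rep((kz - 1) * plane, each = length(idx2))
    subLab[tgt] <- m
  }

  # aggregate ss^3 blocks: mean mu, majority label
  aggSum <- function(a) {
    out <- array(0, dim = gridDim)
    for (i in seq_len(ss)) for (j in seq_len(ss)) for (k in seq_len(ss))
      out <- out + a[seq(i, nxs, ss), seq(j, nys, ss), seq(k, nzs, ss)]
    out
  }
  muSub <- array(materials$mu[subLab], dim = dim(subLab))
  mu <- aggSum(muSub) / ss^3

  used <- sort(unique(as.integer(subLab)))
  best <- array(0L, dim = gridDim)
  bestCnt <- array(-1L, dim = gridDim)
  for (m in used) {
    cnt <- aggSum(array((subLab == m) * 1L, dim = dim(subLab)))
    sel <- cnt > bestCnt
    best[sel] <- m
    bestCnt[sel] <- cnt[sel]
  }
  truth <- array(materials$hu[best], dim = gridDim)

  new("VoxelPhantom", voxelSize = as.numeric(voxelSize), labels = best,
      mu = mu, truthHu = truth, materials = materials)
}

#' Defrise disc-stack phantom
#'
#' A stack of flat discs perpendicular to the rotation axis separated by air
#' gaps; the canonical probe for cone-beam undersampling artefacts.  The
#' default dimensions are acrylic discs of 160 mm diameter and 4 mm
#' thickness with 4 mm air gaps; the number of discs defaults to 12, sized
#' to fill the multisource axial field of view.
#'
#' @param discDiameter disc diameter (mm).
#' @param discThickness disc thickness (mm).
#' @param gap air gap between discs (mm).
#' @param nDiscs number of discs (0 gives an all-air phantom).
#' @param discHu nominal HU of the disc material (acrylic by default).
#' @param voxelSize isotropic voxel edge (mm).
#' @param gridDim integer c(nx, ny, nz); defaults to a grid with an 8 mm
#'   margin around the stack.
#' @param muWater water attenuation (mm^-1).
#' @return a \code{\linkS4class{VoxelPhantom}}.
#' @export
makeDefrise <- function(discDiameter = 160, discThickness = 4, gap = 4,
                        nDiscs = 12L, discHu = 120, voxelSize = 2,
                        gridDim = NULL, muWater = 0.02) {
  stopifnot(discDiameter > 0, discThickness > 0, gap > 0, nDiscs >= 0)
  stackH <- if (nDiscs > 0) nDiscs * discThickness + (nDiscs - 1) * gap else 0
  if (is.null(gridDim)) {
    nxy <- 2L * as.integer(ceiling((discDiameter / 2 + 8) / voxelSize))
    nz <- 2L * as.integer(ceiling((stackH / 2 + 8) / voxelSize))
    gridDim <- c(nxy, nxy, max(nz, 4L))
  }
  mats <- materialTable(c("air", "disc"), c(-1000, discHu), muWater)
  shapes <- list()
  if (nDiscs > 0) {
    z0 <- -stackH / 2
    for (i in seq_len(nDiscs)) {
      zlo <- z0 + (i - 1) * (discThickness + gap)
      shapes[[i]] <- shapeCylinder("disc", radius = discDiameter / 2,
                                   z0 = zlo, z1 = zlo + discThickness)
    }
  }
  rasterPhantom(gridDim, voxelSize, shapes, mats)
}

#' Default insert layout of the contrast phantom
#'
#' Four 25 mm wells at 45 mm radius, 90 degrees apart: acrylic, low-density
#' polyethylene, air and machinable glass ceramic.
#'
#' @param macorHu nominal HU assigned to the ceramic (no standard nominal
#'   value exists at this beam quality; 2400 is a package convention).
#' @return data.frame describing the inserts.
#' @export
contrastInserts <- function(macorHu = 2400) {
  data.frame(
    material = c("acrylic", "ldpe", "air", "macor"),
    hu = c(120, -95, -1000, macorHu),
    angleDeg = c(0, 90, 180, 270),
    radius = 45,
    diameter = 25,
    stringsAsFactors = FALSE)
}

#' Water-equivalent contrast cylinder with inserts
#'
#' A 16 cm diameter water-equivalent cylinder (0 HU) with cylindrical
#' material inserts running its full height.  With \code{inserts = NULL} the
#' result is a uniform water cylinder, which doubles as the phantom for
#' uniformity, cupping and axial-coverage measurements.
#'
#' @param cylDiameter cylinder diameter (mm).
#' @param height cylinder height (mm).
#' @param inserts data.frame as returned by \code{\link{contrastInserts}},
#'   or \code{NULL} for no inserts.
#' @param voxelSize isotropic voxel edge (mm).
#' @param gridDim integer c(nx, ny, nz); default adds an 8 mm margin.
#' @param muWater water attenuation (mm^-1).
#' @return a \code{\linkS4class{VoxelPhantom}}.
#' @export
makeContrast <- function(cylDiameter = 160, height = 80,
                         inserts = contrastInserts(), voxelSize = 2,
                         gridDim = NULL, muWater = 0.02) {
  stopifnot(cylDiameter > 0, height > 0)
  if (is.null(gridDim)) {
    nxy <- 2L * as.integer(ceiling((cylDiameter / 2 + 8) / voxelSize))
    nz <- 2L * as.integer(ceiling((height / 2 + 8) / voxelSize))
    gridDim <- c(nxy, nxy, nz)
  }
  R <- cylDiameter / 2
  matNames <- c("air", "water"); matHu <- c(-1000, 0)
  shapes <- list(shapeCylinder("water", radius = R,
                               z0 = -height / 2, z1 = height / 2))
  if (!is.null(inserts) && nrow(inserts)) {
    cx <- inserts$radius * cos(inserts$angleDeg * pi / 180)
    cy <- inserts$radius * sin(inserts$angleDeg * pi / 180)
    rr <- inserts$diameter / 2
    if (any(inserts$radius + rr > R + 1e-9))
      stop("insert placement error: an insert extends beyond the cylinder")
    if (nrow(inserts) > 1) {
      dd <- as.matrix(dist(cbind(cx, cy)))
      lim <- outer(rr, rr, "+")
      diag(dd) <- Inf
      if (any(dd < lim)) stop("insert placement error: inserts overlap")
    }
    for (i in seq_len(nrow(inserts))) {
      nm <- inserts$material[i]
      if (!nm %in% matNames) {
        matNames <- c(matNames, nm); matHu <- c(matHu, inserts$hu[i])
      }
      shapes <- c(shapes, list(shapeCylinder(nm, cx = cx[i], cy = cy[i],
                                             radius = rr[i],
                                             z0 = -height / 2, z1 = height / 2)))
    }
  }
  mats <- materialTable(matNames, matHu, muWater)
  rasterPhantom(gridDim, voxelSize, shapes, mats)
}

#' Simplified head phantom
#'
#' A synthetic stand-in for an anthropomorphic head: an elliptical
#' soft-tissue cross-section, a mandible-like bone arc with a cortical shell
#' around a cancellous core, and teeth-like high-attenuation cylinders
#' (labelled as cortical material).  Exactly three tissue classes besides
#' air, suitable for threshold segmentation and slice-wise agreement
#' analysis.
#'
#' @param a,b transaxial semi-axes of the soft-tissue ellipse (mm).
#' @param height phantom height (mm).
#' @param corticalHu,cancellousHu,softHu nominal HU of the tissue classes.
#' @param voxelSize isotropic voxel edge (mm).
#' @param gridDim integer c(nx, ny, nz).
#' @param muWater water attenuation (mm^-1).
#' @return a \code{\linkS4class{VoxelPhantom}}.
#' @export
makeHead <- function(a = 85, b = 65, height = 80, corticalHu = 1500,
                     cancellousHu = 300, softHu = 40, voxelSize = 2,
                     gridDim = NULL, muWater = 0.02) {
  if (is.null(gridDim)) {
    nxy <- 2L * as.integer(ceiling((max(a, b) + 8) / voxelSize))
    nz <- 2L * as.integer(ceiling((height / 2 + 8) / voxelSize))
    gridDim <- c(nxy, nxy, nz)
  }
  mats <- materialTable(c("air", "soft", "cancellous", "cortical"),
                        c(-1000, softHu, cancellousHu, corticalHu), muWater)
  z0 <- -height / 2; z1 <- height / 2
  shapes <- list(
    shapeEllipticCylinder("soft", a = a, b = b, z0 = z0, z1 = z1),
    # mandible-like arc: cortical annulus with a cancellous core
    shapeArcAnnulus("cortical", r0 = 42, r1 = 58, angle0 = -70, angle1 = 250,
                    z0 = z0, z1 = z1),
    shapeArcAnnulus("cancellous", r0 = 46, r1 = 54, angle0 = -65, angle1 = 245,
                    z0 = z0, z1 = z1))
  teethAng <- seq(-50, 230, by = 40)
  for (ang in teethAng) {
    shapes <- c(shapes, list(shapeCylinder(
      "cortical", cx = 66 * cos(ang * pi / 180), cy = 66 * sin(ang * pi / 180),
      radius = 4, z0 = z0, z1 = z1)))
  }
  rasterPhantom(gridDim, voxelSize, shapes, mats)
}

# ---- accessors and show -----------------------------------------------------

#' @rdname muVolume
setMethod("muVolume", "VoxelPhantom", function(object) object@mu)

#' @rdname huVolume
setMethod("huVolume", "VoxelPhantom", function(object) object@truthHu)

#' @rdname voxelSize
setMethod("voxelSize", "VoxelPhantom", function(object) object@voxelSize)

#' @rdname materials
setMethod("materials", "VoxelPhantom", function(object) object@materials)

setMethod("dim", "VoxelPhantom", function(x) dim(x@labels))

setMethod("show", "VoxelPhantom", function(object) {
  d <- dim(object)
  cat(sprintf("VoxelPhantom: %d x %d x %d voxels at %.2f mm (%.0f x %.0f x %.0f mm)\n",
              d[1], d[2], d[3], object@voxelSize,
              d[1] * object@voxelSize, d[2] * object@voxelSize,
              d[3] * object@voxelSize))
  tab <- table(factor(object@materials$name[object@labels],
                      levels = object@materials$name))
  tab <- tab[tab > 0]
  cat("  materials:", paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
                            collapse = ", "), "\n")
})
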