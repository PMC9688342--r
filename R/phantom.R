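# Synthetic neck phantoms: bilateral, cranio-caudally stacked "level"
# structures on a soft-tissue background with a bone-like landmark, so the
# whole pipeline can be exercised without clinical data.

#' Phantom specification
#'
#' Describes a synthetic CT-like neck volume. Each lateral side carries five
#' structures emulating lymph node levels I-V: levels II, III and IV are
#' stacked cranio-caudally as adjacent slabs sharing a lateral band (so
#' that, without angulation, no two of them occupy the same axial slice);
#' level I sits anterior-cranial touching level II; level V posterior,
#' touching levels III/IV. A bone-like cylinder runs cranio-caudally at the
#' midline and the body is an elliptical soft-tissue cylinder surrounded by
#' air.
#'
#' All geometry is in mm. The stack of levels II-IV is centered on the
#' cranio-caudal grid center, then the whole bilateral assembly is shifted
#' by a seed-dependent random offset (\code{jitterMm}) emulating
#' patient-positioning variability between scans. This inter-case
#' variability is what gives the Gaussian patch sampler's
#' center-of-mass distribution a non-zero spread, as anatomical
#' variation does in a real cohort; the labelled volume itself is
#' unaffected by the shift.
#'
#' The phantom's proportions follow the neck-to-patch ratio of the
#' clinical setup rather than absolute neck dimensions: the level
#' structures are superficial (close to the body surface) and the body
#' is narrow enough that training patches sampled around the structures
#' also contain air, bone and body borders, exactly as patches from a
#' real planning CT do.
#'
#' @param shape Grid size per axis (default \code{c(128, 128, 160)}).
#' @param spacing Isotropic voxel size in mm (default 1.25).
#' @param levelExtents Cranio-caudal span in mm of levels I-V
#'   (default \code{c(20, 20, 20, 20, 40)}).
#' @param lateralOffset Distance from the midline to the center of each
#'   side's level band, mm (default 20).
#' @param bandHalfWidth Lateral half-width of the level band, mm
#'   (default 8).
#' @param bodyRadiusMm Lateral and antero-posterior semi-axes of the
#'   elliptical body cylinder, mm (default \code{c(38, 34)}).
#' @param jitterMm Maximum absolute positioning shift of the whole level
#'   assembly per axis in mm, drawn uniformly per phantom (default
#'   \code{c(4, 6, 18)}; largest cranio-caudally, where scan start
#'   position varies most).
#' @param noiseSd Gaussian intensity noise inside the body, HU (default 20).
#' @param tissueHu,nodeHu,boneHu,airHu Mean intensities of soft tissue,
#'   nodal level structures, bone and air in HU (defaults 40, 70, 700,
#'   -1000). The node/tissue contrast is what intensity windowing acts on.
#' @param pitchDeg,tiltDeg Global patient angulation applied after
#'   construction (degrees; default 0).
#' @param seed RNG seed making the phantom deterministic.
#' @return A \code{PhantomSpec} list.
#' @export
phantomSpec <- function(shape = c(128L, 128L, 160L), spacing = 1.25,
                        levelExtents = c(20, 20, 20, 20, 40),
                        lateralOffset = 20, bandHalfWidth = 8,
                        bodyRadiusMm = c(38, 34),
                        jitterMm = c(4, 6, 18),
                        noiseSd = 20, tissueHu = 40, nodeHu = 70,
                        boneHu = 700, airHu = -1000,
                        pitchDeg = 0, tiltDeg = 0, seed = 1L) {
  if (length(levelExtents) != 5L || any(levelExtents <= 0))
    stop("levelExtents must be 5 positive spans (mm)")
  stopifnot(length(jitterMm) == 3L, all(jitterMm >= 0),
            length(bodyRadiusMm) == 2L, all(bodyRadiusMm > 0))
  structure(list(shape = as.integer(shape), spacing = spacing,
                 levelExtents = levelExtents, lateralOffset = lateralOffset,
                 bandHalfWidth = bandHalfWidth, bodyRadiusMm = bodyRadiusMm,
                 jitterMm = jitterMm, noiseSd = noiseSd,
                 tissueHu = tissueHu, nodeHu = nodeHu, boneHu = boneHu,
                 airHu = airHu, pitchDeg = pitchDeg, tiltDeg = tiltDeg,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# evaluate an expression under a fixed seed, restoring the caller's RNG
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic neck phantom
#'
#' Deterministic given the spec's seed. The label map shares the volume's
#' geometry; labels are exactly \code{{0, 1, ..., 5}} with both sides
#' mirrored about the sagittal midplane, and each side's combined I-V
#' structure is one 26-connected, hole-free component.
#'
#' @param spec A \code{\link{phantomSpec}}.
#' @return A list with elements \code{volume} (\linkS4class{ScanVolume})
#'   and \code{labels} (\linkS4class{LabelVolume}).
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  dm <- spec$shape
  sp <- rep(spec$spacing, 3)
  ext <- (dm - 1) * sp
  mid <- ext / 2
  e <- spec$levelExtents

  # voxel center coordinates per axis, mm
  xs <- (seq_len(dm[1]) - 1) * sp[1]
  ys <- (seq_len(dm[2]) - 1) * sp[2]
  zs <- (seq_len(dm[3]) - 1) * sp[3]

  # patient-positioning shift of the whole assembly (bilateral, so the
  # sagittal mirror symmetry is kept); drawn first so the noise draw
  # below stays aligned with the seed
  jit <- withSeed(spec$seed,
                  runif(3, -spec$jitterMm, spec$jitterMm) + 0)
  mid <- mid + c(0, jit[2], jit[3]) # y/z shifts move the assembly center
  off0 <- spec$lateralOffset + jit[1]

  # cranio-caudal layout: II-IV stack centered on (shifted) mid z
  zIV0 <- mid[3] - (e[2] + e[3] + e[4]) / 2
  zIII0 <- zIV0 + e[4]
  zII0 <- zIII0 + e[3]
  zII1 <- zII0 + e[2]
  zI0 <- zII0 + e[2] / 3
  zV0 <- zIV0 + e[4] / 3
  ranges <- list(
    I   = c(zI0, zI0 + e[1]),
    II  = c(zII0, zII1),
    III = c(zIII0, zII0),
    IV  = c(zIV0, zIII0),
    V   = c(zV0, zV0 + e[5]))
  zmax <- max(vapply(ranges, max, numeric(1)))
  zmin <- min(vapply(ranges, min, numeric(1)))
  if (zmin < 0 || zmax > ext[3] + sp[3] / 2)
    stop("level extents exceed the cranio-caudal grid extent")

  # lateral band and anterior/posterior compartments
  off <- off0
  hw <- spec$bandHalfWidth
  yBand <- c(mid[2] - 10, mid[2] + 10)
  yI <- c(mid[2] - 24, mid[2] - 10)
  yV <- c(mid[2] + 10, mid[2] + 24)
  # level I reaches the midline (the submental compartment is a midline
  # structure), joining the two sides into one combined structure
  xI <- c(0, off + hw - 4)
  if (off + hw > ext[1] / 2 || yI[1] < 0 || yV[2] > ext[2])
    stop("lateral geometry exceeds the grid extent")

  inR <- function(v, r) v >= r[1] & v < r[2]
  lab <- array(0L, dm)
  for (side in c(-1, 1)) {
    xc <- mid[1] + side * c(off - hw, off + hw)
    xr <- sort(xc)
    xir <- sort(mid[1] + side * xI)
    mx <- inR(xs, xr)
    mxI <- inR(xs, xir)
    # column: II, III, IV
    xyBand <- outer(mx, inR(ys, yBand), "&")
    for (lev in c("II", "III", "IV")) {
      l <- match(lev, c("I", "II", "III", "IV", "V"))
      lab[outer(xyBand, inR(zs, ranges[[lev]]), "&")] <- l
    }
    lab[outer(outer(mxI, inR(ys, yI), "&"), inR(zs, ranges$I), "&")] <- 1L
    lab[outer(outer(mx, inR(ys, yV), "&"), inR(zs, ranges$V), "&")] <- 5L
  }

  # intensities
  body <- outer((xs - mid[1])^2 / spec$bodyRadiusMm[1]^2,
                (ys - mid[2])^2 / spec$bodyRadiusMm[2]^2, "+") <= 1
  bone <- outer((xs - mid[1])^2, (ys - (mid[2] + 2))^2, "+") <= 7^2
  hu <- array(spec$airHu, dm)
  bodyArr <- array(body, dm)
  hu[bodyArr] <- spec$tissueHu
  hu[array(bone & body, dm)] <- spec$boneHu
  hu[lab > 0L] <- spec$nodeHu
  vol <- withSeed(spec$seed, {
    noise <- array(0, dm)
    nb <- sum(bodyArr)
    noise[bodyArr] <- rnorm(nb, 0, spec$noiseSd)
    hu + noise
  })

  out <- list(volume = scanVolume(vol, spacing = sp),
              labels = labelVolume(lab, spacing = sp, nClasses = 6L))
  if (spec$pitchDeg != 0 || spec$tiltDeg != 0)
    out <- angulate(out$volume, out$labels, spec$pitchDeg, spec$tiltDeg)
  out
}

#' Apply patient angulation (pitch/tilt) to a volume and label map
#'
#' Rigid rotation about the volume center: pitch rotates in the sagittal
#' plane (about the left-right axis), tilt in the coronal plane (about the
#' antero-posterior axis). The image is interpolated with 3rd-order
#' B-splines, the labels with nearest neighbour, so the label set is
#' preserved.
#'
#' @param vol A \linkS4class{ScanVolume}.
#' @param lab The paired \linkS4class{LabelVolume}.
#' @param pitchDeg,tiltDeg Rotation angles in degrees, |angle| <= 20.
#' @return A list with rotated \code{volume} and \code{labels}.
#' @export
angulate <- function(vol, lab, pitchDeg = 0, tiltDeg = 0) {
  stopifnot(is(vol, "ScanVolume"), is(lab, "LabelVolume"))
  checkSameGeometry(vol, lab, "volume and labels")
  if (abs(pitchDeg) > 20 || abs(tiltDeg) > 20)
    stop("|angle| must be <= 20 degrees")
  if (pitchDeg == 0 && tiltDeg == 0)
    return(list(volume = vol, labels = lab))
  R <- rotX(pitchDeg * pi / 180) %*% rotY(tiltDeg * pi / 180)
  d <- dim(voxelData(vol))
  sp <- voxelSpacing(vol)
  # source voxel = cvox + S^-1 R^T S (target voxel - cvox), S = diag(spacing)
  A <- diag(1 / sp) %*% t(R) %*% diag(sp)
  cvox <- (d - 1) / 2
  b <- as.numeric(cvox - A %*% cvox)
  coef <- .bspline_prefilter(voxelData(vol), d)
  vr <- .affine_sample(coef, d, A, b, d, 3L)
  lr <- .affine_sample(voxelData(lab) + 0, d, A, b, d, 0L)
  list(volume = scanVolume(vr, sp, voxelOrigin(vol)),
       labels = labelVolume(lr, sp, voxelOrigin(lab),
                            nClasses = nClasses(lab)))
}

rotX <- function(t) rbind(c(1, 0, 0), c(0, cos(t), -sin(t)),
                          c(0, sin(t), cos(t)))
rotY <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                          c(-sin(t), 0, cos(t)))
rotZ <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))
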