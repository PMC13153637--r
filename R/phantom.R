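## Digital abdomen phantom.
##
## The phantom is assembled from additive density components so that
## projections of a rigidly displaced component can be formed by shifting the
## component's projection in the image plane (exact for parallel rays):
##   static   : body ellipse (water) + spine cylinder
##   lung     : negative density delta above the diaphragm dome (moves in z
##              with respiration)
##   moving   : target sphere, bowel-gas pockets and fiducial deltas -- the
##              soft-tissue block that carries the full 3D target motion.

#' Configuration of the digital abdomen phantom
#'
#' Builds a validated configuration list for [buildPhantom()]. All lengths are
#' mm, densities in g/cm^3. The phantom is centred on the volume origin; the
#' body is an elliptical cylinder of water-equivalent density containing a
#' bright spine cylinder (posterior), a diaphragm dome with lung-density
#' tissue above it, a spherical pancreas target carrying optional fiducial
#' markers, and a configurable number of gas pockets.
#'
#' @param volSize voxels per side (scalar or length 3).
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param bodyAxes semi-axes of the body ellipse in x and y (mm).
#' @param bodyDensity soft-tissue density.
#' @param spineCentre x/y centre of the spine cylinder (mm).
#' @param spineRadius,spineDensity spine cylinder radius (mm) and density.
#' @param lungDensity density above the diaphragm.
#' @param diaphragmApex z of the diaphragm dome apex (mm).
#' @param diaphragmRadius radius of curvature of the dome (mm).
#' @param nGasPockets number of bowel-gas pockets.
#' @param gasRadiusRange min/max gas-pocket radius (mm).
#' @param nTextureBlobs number of soft-tissue texture blobs that move with
#'   the target block, providing the lateral image structure that real
#'   abdominal anatomy (bowel, vessels) supplies.
#' @param textureRadiusRange min/max blob radius (mm).
#' @param textureContrast min/max absolute density contrast of the blobs
#'   (sign drawn at random).
#' @param organBlockSemi semi-axes (mm) of the denser visceral block that
#'   surrounds the target and moves with it (the pancreatic/duodenal organ
#'   mass whose boundary is visible on kV images).
#' @param organBlockDelta density contrast of that block.
#' @param targetCentre 3-vector, pancreas target centre (mm).
#' @param targetRadius,targetDensity target sphere radius (mm) and density.
#' @param ptvMargin CTV-to-PTV margin (mm), 3 or 5 in clinical practice.
#' @param nFiducials number of implanted fiducial markers.
#' @param fiducialRadius,fiducialDensity fiducial radius (mm) and density;
#'   the density must exceed 1.869 so that DRR density clipping hides them.
#' @param seed integer seed controlling fiducial and gas placement.
#' @return a named list of class \code{"phantomConfig"}.
#' @export
phantomConfig <- function(volSize = 128L, spacing = 2,
                          bodyAxes = c(110, 85), bodyDensity = 1.0,
                          spineCentre = c(0, -68), spineRadius = 11,
                          spineDensity = 1.6,
                          lungDensity = 0.26, diaphragmApex = 90,
                          diaphragmRadius = 65,
                          nGasPockets = 4L, gasRadiusRange = c(8, 16),
                          nTextureBlobs = 12L,
                          textureRadiusRange = c(8, 20),
                          textureContrast = c(0.03, 0.08),
                          organBlockSemi = c(45, 35, 60),
                          organBlockDelta = 0.06,
                          targetCentre = c(34, 22, -15), targetRadius = 12,
                          targetDensity = 1.2, ptvMargin = 5,
                          nFiducials = 3L, fiducialRadius = 1.6,
                          fiducialDensity = 8.0, seed = 1L) {
  if (length(volSize) == 1L) volSize <- rep(volSize, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  cfg <- list(volSize = as.integer(volSize), spacing = as.numeric(spacing),
              bodyAxes = bodyAxes, bodyDensity = bodyDensity,
              spineCentre = spineCentre, spineRadius = spineRadius,
              spineDensity = spineDensity, lungDensity = lungDensity,
              diaphragmApex = diaphragmApex, diaphragmRadius = diaphragmRadius,
              nGasPockets = as.integer(nGasPockets),
              gasRadiusRange = gasRadiusRange,
              nTextureBlobs = as.integer(nTextureBlobs),
              textureRadiusRange = textureRadiusRange,
              textureContrast = textureContrast,
              organBlockSemi = organBlockSemi,
              organBlockDelta = organBlockDelta,
              targetCentre = targetCentre, targetRadius = targetRadius,
              targetDensity = targetDensity, ptvMargin = ptvMargin,
              nFiducials = as.integer(nFiducials),
              fiducialRadius = fiducialRadius,
              fiducialDensity = fiducialDensity, seed = as.integer(seed))
  dens <- c(bodyDensity, spineDensity, lungDensity, targetDensity,
            fiducialDensity)
  if (any(dens < 0)) stop("densities must be non-negative")
  if (nFiducials > 0L && fiducialDensity <= 1.869)
    stop("fiducialDensity must exceed 1.869 so DRR clipping hides the markers")
  half <- (cfg$volSize - 1) / 2 * cfg$spacing
  if (any(abs(targetCentre) + targetRadius > half))
    stop("target lies outside the phantom volume")
  if (sum((targetCentre[1:2] / bodyAxes)^2) >= 1)
    stop("target lies outside the body ellipse")
  class(cfg) <- "phantomConfig"
  cfg
}

# Physical coordinates of voxel centres (volume centred on the origin).
.gridAxes <- function(volSize, spacing) {
  lapply(1:3, function(a)
    (seq_len(volSize[a]) - (volSize[a] + 1) / 2) * spacing[a])
}

.phantomOrigin <- function(cfg)
  -(cfg$volSize - 1) / 2 * cfg$spacing

# Logical mask of a sphere on the phantom grid.
.sphereMask <- function(ax, centre, radius) {
  dx2 <- (ax[[1]] - centre[1])^2
  dy2 <- (ax[[2]] - centre[2])^2
  dz2 <- (ax[[3]] - centre[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
}

.ellipsoidMask <- function(ax, centre, semi) {
  dx2 <- ((ax[[1]] - centre[1]) / semi[1])^2
  dy2 <- ((ax[[2]] - centre[2]) / semi[2])^2
  dz2 <- ((ax[[3]] - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

# Bowel-gas density delta (negative, zeroing out soft tissue inside each
# pocket), redrawn per fraction to emulate day-to-day bowel state. Pockets
# sit in the anterior abdomen below the diaphragm, away from the target,
# and travel with the moving soft-tissue block.
.gasDelta <- function(cfg, seed, phantom = NULL) {
  ax <- .gridAxes(cfg$volSize, cfg$spacing)
  delta <- array(0, cfg$volSize)
  if (cfg$nGasPockets < 1L) return(delta)
  rng <- .localRNG(seed)
  on.exit(rng$restore())
  pockets <- array(FALSE, cfg$volSize)
  for (p in seq_len(cfg$nGasPockets)) {
    repeat {
      cx <- rng$runif(1, -0.55, 0.55) * cfg$bodyAxes[1]
      cy <- rng$runif(1, 0.05, 0.7) * cfg$bodyAxes[2]
      r <- rng$runif(1, cfg$gasRadiusRange[1], cfg$gasRadiusRange[2])
      domeFloor <- cfg$diaphragmApex - cfg$diaphragmRadius
      cz <- rng$runif(1, -60, domeFloor - r - 5)
      far <- sqrt(sum((c(cx, cy, cz) - cfg$targetCentre)^2)) >
             r + cfg$targetRadius + 4
      if (far) break
    }
    pockets <- pockets | .sphereMask(ax, c(cx, cy, cz), r)
  }
  if (is.null(phantom)) {
    delta[pockets] <- -cfg$bodyDensity
  } else {
    pockets <- pockets & phantom$blockRegion
    delta[pockets] <- -phantom$movingBase[pockets]
  }
  delta
}

# Run a block of random draws under a private RNG state.
.localRNG <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(
    runif = function(n, min = 0, max = 1) stats::runif(n, min, max),
    rnorm = function(n, mean = 0, sd = 1) stats::rnorm(n, mean, sd),
    sample = function(x, size, replace = FALSE) sample(x, size, replace),
    restore = function() {
      if (is.null(state)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(list = ".Random.seed", envir = globalenv())
      } else assign(".Random.seed", state, envir = globalenv())
    })
}

#' Build the digital abdomen phantom
#'
#' Constructs the component density volumes, structure masks and fiducial
#' coordinates from a [phantomConfig()]. Deterministic for a fixed
#' configuration seed. The planning target volume (PTV) is the clinical
#' target volume (CTV, the target sphere) dilated by the configured margin.
#'
#' @param config a [phantomConfig()].
#' @return a list of class \code{"orthoPhantom"} with the component
#'   density volumes \code{static} (spine), \code{lung} (tissue above the
#'   diaphragm dome), \code{movingBase} / \code{movingBaseClipped} (the
#'   abdominal soft-tissue block carrying target, texture and fiducials,
#'   without/with DRR density clipping), the logical \code{blockRegion},
#'   \code{masks} (named list of \linkS4class{StructureMask}: CTV, PTV,
#'   spine, stomach, duodenum, bowel), \code{fiducials} (n x 3 matrix, mm),
#'   \code{spacing}, \code{origin} and \code{config}.
#' @export
buildPhantom <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "phantomConfig"))
  ax <- .gridAxes(cfg$volSize, cfg$spacing)
  origin <- .phantomOrigin(cfg)

  body <- outer((ax[[1]] / cfg$bodyAxes[1])^2,
                (ax[[2]] / cfg$bodyAxes[2])^2, "+") <= 1
  body3 <- array(rep(body, cfg$volSize[3]), cfg$volSize)
  spine <- outer((ax[[1]] - cfg$spineCentre[1])^2,
                 (ax[[2]] - cfg$spineCentre[2])^2, "+") <= cfg$spineRadius^2
  spine3 <- array(rep(spine & body, cfg$volSize[3]), cfg$volSize)

  # diaphragm dome: lung-density tissue above the dome surface (spine spared)
  domeZ <- matrix(cfg$diaphragmApex - cfg$diaphragmRadius, cfg$volSize[1],
                  cfg$volSize[2])
  r2 <- outer(ax[[1]]^2, ax[[2]]^2, "+")
  inDome <- r2 <= cfg$diaphragmRadius^2
  domeZ[inDome] <- cfg$diaphragmApex - cfg$diaphragmRadius +
    sqrt(cfg$diaphragmRadius^2 - r2[inDome])
  lungRegion <- array(FALSE, cfg$volSize)
  for (k in seq_len(cfg$volSize[3]))
    lungRegion[, , k] <- body & !spine & (ax[[3]][k] > domeZ)

  # component partition of the body: static spine, lung above the
  # diaphragm (follows respiration in z), and the abdominal soft-tissue
  # block below it, which carries the full 3D target motion
  static <- array(0, cfg$volSize)
  static[spine3] <- cfg$spineDensity
  lung <- array(0, cfg$volSize)
  lung[lungRegion] <- cfg$lungDensity
  blockRegion <- body3 & !spine3 & !lungRegion
  movingBase <- array(0, cfg$volSize)
  movingBase[blockRegion] <- cfg$bodyDensity

  ctv <- .sphereMask(ax, cfg$targetCentre, cfg$targetRadius)

  # visceral organ block around the target
  if (cfg$organBlockDelta != 0) {
    blk <- .ellipsoidMask(ax, cfg$targetCentre + c(-5, -5, 0),
                          cfg$organBlockSemi) & blockRegion
    movingBase[blk] <- movingBase[blk] + cfg$organBlockDelta
  }

  rng <- .localRNG(cfg$seed)
  # soft-tissue texture: blobs embedded in the moving block
  if (cfg$nTextureBlobs > 0L) {
    zlo <- origin[3] + 15
    zhi <- cfg$diaphragmApex - cfg$diaphragmRadius - 5
    for (b in seq_len(cfg$nTextureBlobs)) {
      repeat {
        cx <- rng$runif(1, -0.8, 0.8) * cfg$bodyAxes[1]
        cy <- rng$runif(1, -0.75, 0.75) * cfg$bodyAxes[2]
        cz <- rng$runif(1, zlo, zhi)
        r <- rng$runif(1, cfg$textureRadiusRange[1],
                       cfg$textureRadiusRange[2])
        inBody <- sum((c(cx, cy) / (0.9 * cfg$bodyAxes))^2) < 1
        offTarget <- sqrt(sum((c(cx, cy, cz) - cfg$targetCentre)^2)) >
          r + cfg$targetRadius
        if (inBody && offTarget) break
      }
      contrast <- sign(rng$runif(1, -1, 1)) *
        rng$runif(1, cfg$textureContrast[1], cfg$textureContrast[2])
      bm <- .sphereMask(ax, c(cx, cy, cz), r) & blockRegion
      movingBase[bm] <- movingBase[bm] + contrast
    }
  }
  movingBase[ctv] <- cfg$targetDensity
  fid <- matrix(numeric(0), 0, 3)
  if (cfg$nFiducials > 0L) {
    u <- matrix(rng$rnorm(3 * cfg$nFiducials), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- rng$runif(cfg$nFiducials, 0.2, 0.75) * cfg$targetRadius
    fid <- sweep(u * rad, 2, cfg$targetCentre, "+")
    for (f in seq_len(cfg$nFiducials)) {
      fm <- .sphereMask(ax, fid[f, ], cfg$fiducialRadius)
      if (!any(fm)) {  # marker smaller than a voxel: mark the nearest voxel
        ii <- vapply(1:3, function(a) which.min(abs(ax[[a]] - fid[f, a])), 1L)
        fm <- array(FALSE, cfg$volSize); fm[ii[1], ii[2], ii[3]] <- TRUE
      }
      movingBase[fm] <- cfg$fiducialDensity
    }
  }
  rng$restore()

  # DRR density clipping: total density above 1.869 is rendered as 1.0
  movingBaseClipped <- movingBase
  movingBaseClipped[movingBase > 1.869] <- 1.0

  ptv <- .dilateMask(ctv, cfg$ptvMargin, cfg$spacing)
  tc <- cfg$targetCentre
  masks <- list(
    CTV = ctv, PTV = ptv, spine = spine3,
    stomach = .ellipsoidMask(ax, tc + c(-35, 22, 12), c(30, 18, 26)) & body3,
    duodenum = .ellipsoidMask(ax, tc + c(26, 2, -6), c(11, 11, 30)) & body3,
    bowel = .ellipsoidMask(ax, tc + c(0, 32, -45), c(52, 24, 30)) & body3)
  masks <- mapply(function(m, lab)
    StructureMask(m, spacing = cfg$spacing, origin = origin, label = lab),
    masks, names(masks), SIMPLIFY = FALSE)

  structure(list(static = static, lung = lung,
                 movingBase = movingBase,
                 movingBaseClipped = movingBaseClipped,
                 blockRegion = blockRegion,
                 masks = masks, fiducials = fid,
                 spacing = cfg$spacing, origin = origin, config = cfg),
            class = "orthoPhantom")
}

# Binary dilation by a Euclidean ball of the given physical radius.
.dilateMask <- function(mask, margin, spacing) {
  if (margin <= 0) return(mask)
  d <- dim(mask)
  rv <- floor(margin / spacing)
  offs <- expand.grid(i = -rv[1]:rv[1], j = -rv[2]:rv[2], k = -rv[3]:rv[3])
  keep <- sqrt((offs$i * spacing[1])^2 + (offs$j * spacing[2])^2 +
               (offs$k * spacing[3])^2) <= margin
  offs <- offs[keep, , drop = FALSE]
  out <- array(FALSE, d)
  for (r in seq_len(nrow(offs))) {
    di <- offs$i[r]; dj <- offs$j[r]; dk <- offs$k[r]
    si <- max(1, 1 + di):min(d[1], d[1] + di)
    sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
    sk <- max(1, 1 + dk):min(d[3], d[3] + dk)
    out[si, sj, sk] <- out[si, sj, sk] |
      mask[si - di, sj - dj, sk - dk]
  }
  out
}

#' Total density volume of a phantom
#'
#' Sums the phantom's density components into a single volume, optionally
#' applying the DRR density clipping rule (density above 1.869 g/cm^3 is
#' set to 1.0, hiding fiducial markers) and adding a bowel-gas component.
#'
#' @param phantom an \code{"orthoPhantom"} from [buildPhantom()].
#' @param clipped apply the DRR density clipping rule.
#' @param gasDelta optional gas density-delta array (see [buildPhantom()]);
#'   by default the configuration's own seed is used to draw the pockets.
#' @return a \linkS4class{DoseGrid} holding densities.
#' @export
phantomVolume <- function(phantom, clipped = FALSE, gasDelta = NULL) {
  if (is.null(gasDelta))
    gasDelta <- .gasDelta(phantom$config, phantom$config$seed, phantom)
  mov <- if (clipped) phantom$movingBaseClipped else phantom$movingBase
  vox <- phantom$static + phantom$lung + mov + gasDelta
  vox[vox < 0] <- 0
  DoseGrid(vox, spacing = phantom$spacing, origin = phantom$origin)
}

#' Respiratory and inter-fraction motion trace for one treatment fraction
#'
#' The target position at time \eqn{t} is
#' \code{baseline + amplitude * w(t)}, where \code{w} is a unit periodic
#' waveform: \code{"cos"} gives \eqn{\cos(2\pi t/T + \phi)} and the default
#' \code{"cos4"} gives \eqn{2\cos^4(\pi t/T + \phi/2) - 1}, which dwells near
#' end-exhale as real abdominal traces do. \code{amplitude} is therefore half
#' the peak-to-peak excursion per axis.
#'
#' @param baseline per-fraction baseline offset, mm (3-vector).
#' @param amplitude respiratory half peak-to-peak amplitude per axis, mm.
#' @param period respiratory period, seconds.
#' @param phase phase offset, radians.
#' @param waveform \code{"cos4"} or \code{"cos"}.
#' @param sampleTimes optional sample times (s); defaults to 7 s spacing.
#' @return a list of class \code{"motionTrace"}.
#' @export
motionTrace <- function(baseline = c(0, 0, 0), amplitude = c(2, 2, 8),
                        period = 4, phase = 0, waveform = c("cos4", "cos"),
                        sampleTimes = NULL) {
  waveform <- match.arg(waveform)
  structure(list(baseline = as.numeric(baseline),
                 amplitude = as.numeric(amplitude),
                 period = period, phase = phase, waveform = waveform,
                 sampleTimes = sampleTimes), class = "motionTrace")
}

#' Sample ground-truth target positions from a motion trace
#'
#' @param trace a [motionTrace()].
#' @param nImages number of image instants to sample.
#' @return a list with \code{positions} (nImages x 3 matrix, mm, columns
#'   x/y/z), \code{times} (s) and \code{mean} (the per-fraction mean
#'   position, mm).
#' @export
samplePositions <- function(trace, nImages) {
  stopifnot(inherits(trace, "motionTrace"), nImages >= 1)
  t <- trace$sampleTimes
  if (is.null(t)) t <- (seq_len(nImages) - 1) * 7
  t <- t[seq_len(nImages)]
  w <- switch(trace$waveform,
    cos = cos(2 * pi * t / trace$period + trace$phase),
    cos4 = 2 * cos(pi * t / trace$period + trace$phase / 2)^4 - 1)
  pos <- outer(w, trace$amplitude)
  pos <- sweep(pos, 2, trace$baseline, "+")
  colnames(pos) <- c("x", "y", "z")
  list(positions = pos, times = t, mean = colMeans(pos))
}
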