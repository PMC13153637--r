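## Parallel-ray DRR renderer for the +/-45 degree orthogonal view pair.
##
## Both views are integrated on a common rotated coordinate frame
## (u, w, z): u is the image-A column axis, w the image-B column axis,
##   x = R (u + w),  y = R (w - u),  z = z,  R = sqrt(2)/2,
## and rays of view A run along +w while rays of view B run along +u.
## Image rows run superior -> inferior, i.e. z decreases with row index.

.MU_120KV <- 0.0171   # attenuation coefficient at 120 kV, mm^-1
.DENSITY_CLIP <- 1.869

# Sample a volume on the rotated (u, w, z) grid and integrate along u and w.
# The integration axis extends beyond the image field of view to the full
# in-plane diagonal of the volume, so a detector field narrower than the
# body still integrates complete ray paths. Returns both view projections
# as [row = z, col] matrices.
.projectBothViews <- function(vox, spacing, origin, geometry) {
  N <- imageSize(geometry)
  sp <- pixelSpacing(geometry)
  R <- .R_CONST
  cvals <- (seq_len(N) - (N + 1) / 2) * sp       # u (view A) / w (view B)
  zvals <- -(seq_len(N) - (N + 1) / 2) * sp      # rows, superior down
  d <- dim(vox)
  ext <- sqrt(sum((d[1:2] * spacing[1:2] / 2)^2)) +
    max(abs(origin[1:2] + (d[1:2] - 1) * spacing[1:2] / 2))
  m <- max(0L, ceiling((ext - max(cvals)) / sp))
  uw <- (((1 - m):(N + m)) - (N + 1) / 2) * sp   # integration axis
  Nuw <- length(uw)
  keep <- (m + 1L):(m + N)                       # image columns within uw
  A <- matrix(0, N, N)
  B <- matrix(0, N, N)
  uu <- rep(uw, times = Nuw)                     # u fast, w slow
  ww <- rep(uw, each = Nuw)
  px <- R * (uu + ww)
  py <- R * (ww - uu)
  i <- (px - origin[1]) / spacing[1] + 1
  j <- (py - origin[2]) / spacing[2] + 1
  for (r in seq_len(N)) {
    k <- rep((zvals[r] - origin[3]) / spacing[3] + 1, length(px))
    rho <- matrix(.trilinear(vox, i, j, k), Nuw, Nuw)   # [u, w]
    A[r, ] <- rowSums(rho)[keep] * sp * .MU_120KV       # integrate over w
    B[r, ] <- colSums(rho)[keep] * sp * .MU_120KV       # integrate over u
  }
  list(A = A, B = B)
}

#' Render a digitally reconstructed radiograph
#'
#' Ray-traces a density volume into one of the two orthogonal views using
#' parallel rays at +/-45 degrees in the axial plane. Each pixel holds the
#' attenuation-style line integral \eqn{\mu \int \rho \, dl} with
#' \eqn{\mu = 0.0171} mm\eqn{^{-1}} (120 kV), so dense anatomy is bright.
#' Before tracing, voxels with density above 1.869 g/cm^3 are set to
#' 1.0 g/cm^3, which hides implanted fiducial markers.
#'
#' @param volume a \linkS4class{DoseGrid} holding densities, or an
#'   \code{"orthoPhantom"} (rendered with its own gas component).
#' @param geometry an \linkS4class{ImagingGeometry}.
#' @param view \code{"A"} or \code{"B"}.
#' @param clip apply the density clipping rule (default TRUE).
#' @return an \linkS4class{Image2D}.
#' @export
renderDRR <- function(volume, geometry, view = c("A", "B"), clip = TRUE) {
  view <- match.arg(view)
  if (inherits(volume, "orthoPhantom"))
    volume <- phantomVolume(volume, clipped = clip)
  stopifnot(is(volume, "DoseGrid"))
  vox <- voxelData(volume)
  if (clip) vox[vox > .DENSITY_CLIP] <- 1.0
  pr <- .projectBothViews(vox, voxelSpacing(volume), gridOrigin(volume),
                          geometry)
  Image2D(pr[[view]], pixelSpacing = pixelSpacing(geometry))
}

#' Project the phantom components for fast treatment-image synthesis
#'
#' Renders the static anatomy, the diaphragm/lung component and the moving
#' soft-tissue block (with and without fiducial density clipping) into both
#' views once, so that individual treatment images can then be produced by
#' shifting the component projections in the image plane -- exact for rigid
#' translations under parallel-ray geometry.
#'
#' @param phantom an \code{"orthoPhantom"}.
#' @param geometry an \linkS4class{ImagingGeometry}.
#' @param gasDelta optional gas density-delta array for this fraction.
#' @param base optional precomputed static/lung projections (from a previous
#'   call on the same phantom and geometry), reused across fractions.
#' @return a list of class \code{"projectedPhantom"} with per-view component
#'   projections and the reference DRR pair.
#' @export
projectPhantom <- function(phantom, geometry, gasDelta = NULL, base = NULL,
                           pad = 24L) {
  stopifnot(inherits(phantom, "orthoPhantom"))
  if (is.null(gasDelta))
    gasDelta <- .gasDelta(phantom$config, phantom$config$seed, phantom)
  sp <- phantom$spacing; orig <- phantom$origin
  # components are projected on a canvas `pad` pixels wider than the field
  # of view, so that image-plane shifts slide real anatomy (not zero fill)
  # into the image before cropping
  if (is.null(base)) {
    geomExt <- ImagingGeometry(imageSize(geometry) + 2L * pad,
                               pixelSpacing(geometry))
    base <- list(
      static = .projectBothViews(phantom$static, sp, orig, geomExt),
      lung = .projectBothViews(phantom$lung, sp, orig, geomExt),
      movingBase = .projectBothViews(phantom$movingBase, sp, orig, geomExt),
      pad = as.integer(pad))
    base$movingBaseClipped <-
      if (phantom$config$nFiducials > 0L)
        .projectBothViews(phantom$movingBaseClipped, sp, orig, geomExt)
      else base$movingBase
  } else {
    geomExt <- ImagingGeometry(imageSize(geometry) + 2L * base$pad,
                               pixelSpacing(geometry))
  }
  gas <- .projectBothViews(gasDelta, sp, orig, geomExt)
  moving <- list(A = base$movingBase$A + gas$A,
                 B = base$movingBase$B + gas$B)
  movingClipped <- list(A = base$movingBaseClipped$A + gas$A,
                        B = base$movingBaseClipped$B + gas$B)
  crop <- function(m) {
    p <- base$pad; N <- imageSize(geometry)
    m[(p + 1L):(p + N), (p + 1L):(p + N)]
  }
  drr <- list(A = crop(base$static$A + base$lung$A + movingClipped$A),
              B = crop(base$static$B + base$lung$B + movingClipped$B))
  structure(list(static = base$static, lung = base$lung, moving = moving,
                 movingClipped = movingClipped, drr = drr, base = base,
                 pad = base$pad, geometry = geometry,
                 intensityScale = diff(range(drr$A, drr$B))),
            class = "projectedPhantom")
}

#' Synthesize a noisy treatment image at a known target position
#'
#' Produces the kV treatment image of one view with the moving soft-tissue
#' block (target, gas, fiducials) rigidly displaced by \code{truePosition}
#' and the diaphragm displaced by its superior--inferior component. Fiducial
#' markers are \emph{not} density-clipped here, so they appear as bright
#' spots for the removal operator to find. Additive Gaussian noise and a
#' smooth multiplicative intensity field (low-order polynomial) emulate the
#' intensity mismatch between real kV images and DRRs.
#'
#' @param projected a \code{"projectedPhantom"} from [projectPhantom()], or
#'   an \code{"orthoPhantom"} (projected on the fly).
#' @param geometry an \linkS4class{ImagingGeometry} (ignored when a
#'   projected phantom already carries one).
#' @param truePosition 3-vector, the target displacement in mm.
#' @param noiseLevel Gaussian noise standard deviation as a fraction of the
#'   DRR intensity range.
#' @param intensityPerturbation amplitude of the smooth multiplicative field.
#' @param seed integer seed for the noise and field realization.
#' @param view \code{"A"} or \code{"B"}.
#' @return an \linkS4class{Image2D}.
#' @export
renderTreatmentImage <- function(projected, geometry = NULL,
                                 truePosition = c(0, 0, 0),
                                 noiseLevel = 0, intensityPerturbation = 0,
                                 seed = 1L, view = c("A", "B")) {
  view <- match.arg(view)
  if (inherits(projected, "orthoPhantom")) {
    stopifnot(!is.null(geometry))
    projected <- projectPhantom(projected, geometry)
  }
  stopifnot(inherits(projected, "projectedPhantom"))
  if (any(!is.finite(truePosition)) || length(truePosition) != 3L)
    stop("truePosition must be a finite 3-vector")
  geometry <- projected$geometry
  sp <- pixelSpacing(geometry)
  cs <- projectOffset(truePosition)          # mm
  iPx <- (if (view == "A") cs@iA else cs@iB) / sp
  jPx <- cs@jAB / sp
  ext <- projected$static[[view]] +
    .shiftImage(projected$lung[[view]], dRow = jPx, dCol = 0) +
    .shiftImage(projected$moving[[view]], dRow = jPx, dCol = iPx)
  p <- projected$pad; N <- imageSize(geometry)
  img <- ext[(p + 1L):(p + N), (p + 1L):(p + N)]
  if (noiseLevel > 0 || intensityPerturbation > 0) {
    rng <- .localRNG(seed)
    on.exit(rng$restore())
    N <- nrow(img)
    if (intensityPerturbation > 0) {
      X <- matrix(rep(seq(-1, 1, length.out = N), each = N), N, N)
      Y <- t(X)
      a <- rng$runif(5, -1, 1)
      S <- a[1] * X + a[2] * Y + a[3] * X * Y +
           a[4] * (X^2 - 1 / 3) + a[5] * (Y^2 - 1 / 3)
      S <- S / max(abs(S), 1e-12)
      img <- img * (1 + intensityPerturbation * S)
    }
    if (noiseLevel > 0)
      img <- img + matrix(rng$rnorm(N * N, 0,
                                    noiseLevel * projected$intensityScale),
                          N, N)
  }
  Image2D(img, pixelSpacing = sp)
}

# Beam's-eye-view bounding box of a structure mask in one view, in pixels,
# with a margin in mm. Returns list(rows = c(r0, r1), cols = c(c0, c1)).
.maskBBox <- function(mask, geometry, view = c("A", "B"), margin = 20) {
  view <- match.arg(view)
  stopifnot(is(mask, "StructureMask"))
  idx <- which(voxelData(mask), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty structure mask: ", mask@label)
  sp3 <- voxelSpacing(mask); orig <- gridOrigin(mask)
  x <- orig[1] + (idx[, 1] - 1) * sp3[1]
  y <- orig[2] + (idx[, 2] - 1) * sp3[2]
  z <- orig[3] + (idx[, 3] - 1) * sp3[3]
  R <- .R_CONST
  lat <- if (view == "A") R * (x - y) else R * (x + y)   # u or w, mm
  N <- imageSize(geometry); sp <- pixelSpacing(geometry)
  colOf <- function(c_mm) c_mm / sp + (N + 1) / 2
  rowOf <- function(z_mm) -z_mm / sp + (N + 1) / 2
  cols <- range(colOf(range(lat) + c(-margin, margin)))
  rows <- range(rowOf(range(z) + c(-margin, margin)))
  list(rows = pmin(pmax(c(floor(rows[1]), ceiling(rows[2])), 1L), N),
       cols = pmin(pmax(c(floor(cols[1]), ceiling(cols[2])), 1L), N))
}
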