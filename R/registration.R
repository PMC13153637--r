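## Two-stage grid-search registration of treatment images to DRRs.
##
## Stage 1 registers the whole images in a coupled manner: one shared
## superior-inferior shift J applied to both views, independent lateral
## shifts I_A and I_B.  Stage 2 refines each of 25 overlapping subregions
## per image independently, and runs one further coupled registration on the
## PTV beam's-eye-view rectangle (+20 mm margin).  Every candidate shift is
## scored by gamma = NMS x NMI.

# Histogram bin edges (128 bins) from the union intensity range of the DRR
# region and the treatment region sampled at the given reference shift.
.binRange <- function(drr, trt, rows, cols, shift) {
  d <- drr[rows, cols]
  tr <- rows + shift[2]; tc <- cols + shift[1]
  tr <- tr[tr >= 1 & tr <= nrow(trt)]
  tc <- tc[tc >= 1 & tc <= ncol(trt)]
  tv <- if (length(tr) && length(tc)) trt[tr, tc] else numeric(0)
  range(c(d, tv))
}

# Extract the overlapping DRR/treatment pixel pairs for a candidate shift.
.shiftedPair <- function(drr, trt, rows, cols, I, J) {
  keepR <- rows + J >= 1 & rows + J <= nrow(trt)
  keepC <- cols + I >= 1 & cols + I <= ncol(trt)
  if (!any(keepR) || !any(keepC)) stop("empty overlap at shift (",
                                       I, ", ", J, ")")
  r <- rows[keepR]; cc <- cols[keepC]
  list(D = drr[r, cc, drop = FALSE],
       T = trt[r + J, cc + I, drop = FALSE])
}

#' Normalized mean-square similarity of a shifted region pair
#'
#' \deqn{NMS = 1 - \frac{1}{Nn}\sum_{ij}(T(i+I, j+J) - D(i,j))^2}
#' with \eqn{n} the number of overlapping pixels and the normalization
#' \eqn{N = [\max(D_{max} - T_{min},\; T_{max} - D_{min})]^2}, the largest
#' mean square that could be encountered, computed over the region at the
#' evaluated shift. Treatment pixels falling outside the image are excluded
#' and \eqn{n} reduced accordingly. Identical content gives exactly 1.
#'
#' @param drr,treatment numeric matrices (full images).
#' @param rows,cols integer index vectors delimiting the DRR region.
#' @param shift integer \code{c(I, J)}: column and row shift of the
#'   treatment image sample.
#' @return the NMS value (unitless, \eqn{\le 1}).
#' @export
nmsScore <- function(drr, treatment, rows = seq_len(nrow(drr)),
                     cols = seq_len(ncol(drr)), shift = c(0L, 0L)) {
  p <- .shiftedPair(drr, treatment, rows, cols, shift[1], shift[2])
  .nmsFromPair(p)
}

#' Normalized mutual information of a shifted region pair
#'
#' Intensities of both regions are binned into 128 equal-width bins; the
#' joint histogram \strong{M} is normalized to probabilities, the marginals
#' are its row and column sums, and
#' \deqn{NMI = (\Psi(D) + \Psi(T)) / \Psi(M)}
#' with \eqn{\Psi = -\sum p \ln p} (and \eqn{0 \ln 0 = 0}). Identical
#' regions with at least two occupied bins give 2; independent intensities
#' give 1. If both regions are constant (\eqn{\Psi(M) = 0}) the pair is a
#' degenerate perfect match and the value 2 is returned.
#'
#' @inheritParams nmsScore
#' @param bins number of histogram bins (default 128).
#' @param binRange optional fixed intensity range for the bins; by default
#'   the union range of the two regions at the evaluated shift. During a
#'   search the range is computed once at the search's start shift and held
#'   fixed so the bin edges are stable across candidates.
#' @return the NMI value (unitless, \eqn{\ge 0}).
#' @export
nmiScore <- function(drr, treatment, rows = seq_len(nrow(drr)),
                     cols = seq_len(ncol(drr)), shift = c(0L, 0L),
                     bins = 128L, binRange = NULL) {
  p <- .shiftedPair(drr, treatment, rows, cols, shift[1], shift[2])
  .nmiFromPair(p, bins, binRange)
}

#' Registration objective gamma = NMS x NMI
#'
#' Composes [nmsScore()] and [nmiScore()] into the search objective; higher
#' is better. The NMS term maps spatial structure; the NMI term adds
#' robustness against residual intensity mismatch between DRR and treatment
#' image.
#'
#' @inheritParams nmiScore
#' @return a list with elements \code{nms}, \code{nmi} and \code{gamma}.
#' @export
registrationObjective <- function(drr, treatment, rows = seq_len(nrow(drr)),
                                  cols = seq_len(ncol(drr)),
                                  shift = c(0L, 0L), bins = 128L,
                                  binRange = NULL) {
  p <- .shiftedPair(drr, treatment, rows, cols, shift[1], shift[2])
  nms <- .nmsFromPair(p)
  nmi <- .nmiFromPair(p, bins, binRange)
  list(nms = nms, nmi = nmi, gamma = nms * nmi)
}

.nmsFromPair <- function(p) {
  N <- max(max(p$D) - min(p$T), max(p$T) - min(p$D))^2
  if (N == 0) return(1)
  1 - sum((p$T - p$D)^2) / (N * length(p$D))
}

.nmiFromPair <- function(p, bins, binRange) {
  if (is.null(binRange)) binRange <- range(c(p$D, p$T))
  lo <- binRange[1]; wid <- (binRange[2] - binRange[1]) / bins
  if (wid <= 0) return(2)
  bd <- pmin(pmax(floor((p$D - lo) / wid), 0), bins - 1)
  bt <- pmin(pmax(floor((p$T - lo) / wid), 0), bins - 1)
  joint <- tabulate(bd + bins * bt + 1, nbins = bins * bins)
  M <- joint / sum(joint)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  psiM <- ent(M)
  if (psiM == 0) return(2)
  Mm <- matrix(M, bins, bins)
  (ent(rowSums(Mm)) + ent(colSums(Mm))) / psiM
}

# gamma for one candidate; a candidate whose shifted window has no overlap
# with the image scores -Inf (it can never win the search).
.gammaSafe <- function(drr, trt, rows, cols, shift, bins, binRange) {
  tryCatch(registrationObjective(drr, trt, rows, cols, shift, bins,
                                 binRange)$gamma,
           error = function(e) {
             if (grepl("empty overlap", conditionMessage(e))) -Inf
             else stop(e)
           })
}

# gamma for a vector of candidate I at fixed J (one image, one region).
.gammaProfile <- function(drr, trt, rows, cols, Is, J, bins, binRange) {
  vapply(Is, function(I)
    .gammaSafe(drr, trt, rows, cols, c(I, J), bins, binRange), numeric(1))
}

# Deterministic argmax: best value, ties by smallest shift norm then by
# candidate order (raster order of the search grid).
.bestIndex <- function(vals, norms) {
  best <- max(vals)
  cand <- which(vals >= best - 1e-12)
  cand[order(norms[cand])][1]
}

#' Coupled whole-image registration of the orthogonal view pair
#'
#' Maximizes the summed objective
#' \eqn{\gamma(I_A, I_B, J) = \gamma_A(I_A, J) + \gamma_B(I_B, J)} by nested
#' exhaustive grid search: the outer loop scans the shared
#' superior--inferior shift \eqn{J}, and for each \eqn{J} the lateral shifts
#' \eqn{I_A} and \eqn{I_B} are maximized independently. The default
#' schedule runs a coarse pass (range +/-20 pixels, step 4) followed by a
#' fine pass (+/-2, step 1) centred on the coarse optimum. Ties are broken
#' by the smallest shift norm, then candidate order.
#'
#' @param drrA,drrB,trtA,trtB numeric matrices or \linkS4class{Image2D}s.
#' @param regionA,regionB optional regions \code{list(rows=, cols=)}; whole
#'   image by default.
#' @param passes list of \code{c(range, step)} pairs.
#' @param start integer \code{c(iA, iB, jAB)} starting shift in pixels.
#' @param bins histogram bins for the NMI term.
#' @return a \linkS4class{CoupledShift} in pixels with attribute
#'   \code{"gamma"} (the summed objective at the optimum).
#' @export
coupledSearch <- function(drrA, drrB, trtA, trtB,
                          regionA = NULL, regionB = NULL,
                          passes = list(c(20, 4), c(2, 1)),
                          start = c(0L, 0L, 0L), bins = 128L) {
  dA <- if (is(drrA, "Image2D")) pixelData(drrA) else drrA
  dB <- if (is(drrB, "Image2D")) pixelData(drrB) else drrB
  tA <- if (is(trtA, "Image2D")) pixelData(trtA) else trtA
  tB <- if (is(trtB, "Image2D")) pixelData(trtB) else trtB
  if (is.null(regionA)) regionA <- list(rows = seq_len(nrow(dA)),
                                        cols = seq_len(ncol(dA)))
  if (is.null(regionB)) regionB <- list(rows = seq_len(nrow(dB)),
                                        cols = seq_len(ncol(dB)))
  if (!length(regionA$rows) || !length(regionA$cols) ||
      !length(regionB$rows) || !length(regionB$cols))
    stop("empty registration region")
  cur <- as.integer(start)
  brA <- .binRange(dA, tA, regionA$rows, regionA$cols, cur[c(1, 3)])
  brB <- .binRange(dB, tB, regionB$rows, regionB$cols, cur[c(2, 3)])
  bestGamma <- -Inf
  for (p in passes) {
    steps <- seq(-p[1], p[1], by = p[2])
    Js <- cur[3] + steps
    resIA <- integer(length(Js)); resIB <- integer(length(Js))
    resG <- numeric(length(Js))
    for (jj in seq_along(Js)) {
      J <- Js[jj]
      IsA <- cur[1] + steps
      gA <- .gammaProfile(dA, tA, regionA$rows, regionA$cols, IsA, J,
                          bins, brA)
      kA <- .bestIndex(gA, sqrt(IsA^2 + J^2))
      IsB <- cur[2] + steps
      gB <- .gammaProfile(dB, tB, regionB$rows, regionB$cols, IsB, J,
                          bins, brB)
      kB <- .bestIndex(gB, sqrt(IsB^2 + J^2))
      resIA[jj] <- IsA[kA]; resIB[jj] <- IsB[kB]
      resG[jj] <- gA[kA] + gB[kB]
    }
    kJ <- .bestIndex(resG, sqrt(resIA^2 + resIB^2 + Js^2))
    cur <- c(resIA[kJ], resIB[kJ], Js[kJ])
    bestGamma <- resG[kJ]
  }
  out <- CoupledShift(cur[1], cur[2], cur[3], unit = "pixels")
  attr(out, "gamma") <- bestGamma
  out
}

#' Layout of the 5 x 5 overlapping subregion grid
#'
#' Region width is \code{floor(2 * size / 6)} pixels so that five regions
#' with ~50\% overlap tile the image; region start positions are spaced
#' evenly from the first pixel to \code{size - width + 1} (the last region
#' is clamped to the image edge).
#'
#' @param size image size in pixels.
#' @return a list with \code{width} and the five start positions
#'   \code{starts}.
#' @export
subregionLayout <- function(size) {
  w <- floor(2 * size / 6)
  starts <- round(seq(1, size - w + 1, length.out = 5))
  list(width = w, starts = as.integer(starts))
}

#' Independent subregion refinement on one image
#'
#' Runs a region-specific 2D grid search in each of the 25 overlapping
#' subregions, seeded at the whole-image shift: a coarse pass (+/-10
#' pixels, step 2) then a fine pass (+/-1, step 1). Each image is refined
#' independently (no coupling of J across views at this stage). Regions are
#' enumerated row-major: (row 1, col 1), (row 1, col 2), ...
#'
#' @param drr,treatment numeric matrices or \linkS4class{Image2D}s.
#' @param start integer \code{c(I, J)} seed from the coupled stage.
#' @param passes list of \code{c(range, step)} pairs.
#' @param bins histogram bins.
#' @return a 25 x 2 matrix of per-region \code{(I, J)} shifts in pixels.
#' @export
subregionSearch <- function(drr, treatment, start = c(0L, 0L),
                            passes = list(c(10, 2), c(1, 1)), bins = 128L) {
  d <- if (is(drr, "Image2D")) pixelData(drr) else drr
  tr <- if (is(treatment, "Image2D")) pixelData(treatment) else treatment
  lay <- subregionLayout(nrow(d))
  out <- matrix(0L, 25L, 2L, dimnames = list(NULL, c("I", "J")))
  reg <- 0L
  for (gr in 1:5) for (gc in 1:5) {
    reg <- reg + 1L
    rows <- lay$starts[gr]:(lay$starts[gr] + lay$width - 1L)
    cols <- lay$starts[gc]:(lay$starts[gc] + lay$width - 1L)
    out[reg, ] <- .search2D(d, tr, rows, cols, as.integer(start), passes,
                            bins)
  }
  out
}

# 2D (I, J) grid search over one region of one image.
.search2D <- function(d, tr, rows, cols, start, passes, bins) {
  br <- .binRange(d, tr, rows, cols, start)
  cur <- start
  for (p in passes) {
    steps <- seq(-p[1], p[1], by = p[2])
    cand <- expand.grid(I = cur[1] + steps, J = cur[2] + steps)
    g <- mapply(function(I, J)
      .gammaSafe(d, tr, rows, cols, c(I, J), bins, br), cand$I, cand$J)
    k <- .bestIndex(g, sqrt(cand$I^2 + cand$J^2))
    cur <- c(cand$I[k], cand$J[k])
  }
  as.integer(cur)
}

#' Coupled registration of the PTV beam's-eye-view region
#'
#' Runs the coupled search of [coupledSearch()] restricted to the rectangle
#' encompassing the PTV projection plus a 20 mm margin in each view, seeded
#' at the whole-image shift and using the subregion pass schedule
#' (+/-10 step 2, then +/-1 step 1). No further adjustment is made after
#' this registration.
#'
#' @inheritParams coupledSearch
#' @param bboxA,bboxB regions \code{list(rows = c(r0, r1), cols = c(c0,
#'   c1))} from projecting the PTV mask into each view.
#' @return a \linkS4class{CoupledShift} in pixels.
#' @export
ptvRegionSearch <- function(drrA, drrB, trtA, trtB, bboxA, bboxB,
                            start = c(0L, 0L, 0L),
                            passes = list(c(10, 2), c(1, 1)), bins = 128L) {
  expand <- function(b) {
    if (b$rows[2] < b$rows[1] || b$cols[2] < b$cols[1])
      stop("empty PTV bounding box")
    list(rows = b$rows[1]:b$rows[2], cols = b$cols[1]:b$cols[2])
  }
  coupledSearch(drrA, drrB, trtA, trtB, expand(bboxA), expand(bboxB),
                passes = passes, start = start, bins = bins)
}

#' Assemble the 104-component registration vector
#'
#' Stacks the 25 grid-region shifts and the PTV-region shift of each image
#' into the fixed component order of \linkS4class{RegistrationVector}
#' (image A grid rows then PTV, then image B likewise; each region
#' contributes (I, J)), converting pixels to mm. The coupled PTV result
#' contributes \code{(iA, jAB)} to image A's PTV slot and \code{(iB, jAB)}
#' to image B's.
#'
#' @param gridA,gridB 25 x 2 matrices from [subregionSearch()] (pixels).
#' @param ptv the \linkS4class{CoupledShift} from [ptvRegionSearch()]
#'   (pixels).
#' @param pixelSpacing mm per pixel.
#' @param patient,fraction,image provenance indices.
#' @return a \linkS4class{RegistrationVector} (mm).
#' @export
assembleVector <- function(gridA, gridB, ptv, pixelSpacing = 1,
                           patient = NA_integer_, fraction = NA_integer_,
                           image = NA_integer_) {
  stopifnot(identical(dim(gridA), c(25L, 2L)),
            identical(dim(gridB), c(25L, 2L)),
            is(ptv, "CoupledShift"))
  if (ptv@unit != "pixels") stop("ptv shift must be in pixels")
  vals <- c(t(gridA), ptv@iA, ptv@jAB,
            t(gridB), ptv@iB, ptv@jAB) * pixelSpacing
  RegistrationVector(vals, patient = patient, fraction = fraction,
                     image = image)
}

#' Register one treatment image pair against its DRRs
#'
#' The full registration chain of one image instant: coupled whole-image
#' search, 25-subregion refinement per image, coupled PTV-region search,
#' assembly of the 104-component registration vector, and back-projection
#' of the PTV-region shift to a 3D target position estimate.
#'
#' @param drrA,drrB preprocessed DRRs (\linkS4class{Image2D}).
#' @param trtA,trtB preprocessed treatment images.
#' @param bboxA,bboxB PTV beam's-eye-view bounding boxes.
#' @param geometry an \linkS4class{ImagingGeometry}.
#' @param bins histogram bins.
#' @return a list with \code{vector} (\linkS4class{RegistrationVector}),
#'   \code{globalShift} and \code{ptvShift} (\linkS4class{CoupledShift},
#'   pixels) and \code{ptvPosition} (3-vector, mm, from back-projecting the
#'   PTV-region shift).
#' @export
registerImagePair <- function(drrA, drrB, trtA, trtB, bboxA, bboxB,
                              geometry, bins = 128L) {
  glob <- coupledSearch(drrA, drrB, trtA, trtB, bins = bins)
  gridA <- subregionSearch(drrA, trtA, start = c(glob@iA, glob@jAB),
                           bins = bins)
  gridB <- subregionSearch(drrB, trtB, start = c(glob@iB, glob@jAB),
                           bins = bins)
  ptv <- ptvRegionSearch(drrA, drrB, trtA, trtB, bboxA, bboxB,
                         start = c(glob@iA, glob@iB, glob@jAB), bins = bins)
  sp <- pixelSpacing(geometry)
  vec <- assembleVector(gridA, gridB, ptv, pixelSpacing = sp)
  mm <- convertShift(ptv, "mm", geometry)
  list(vector = vec, globalShift = glob, ptvShift = ptv,
       ptvPosition = backprojectShift(mm))
}
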