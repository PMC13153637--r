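## Dosimetric impact of residual tracking errors: rigid per-beam shifting
## of the planned dose, stochastic accumulation over fractions and repeats,
## the expectation dose over all residual shifts, and DVH metrics.

.checkAligned <- function(a, b) {
  if (!identical(dim(voxelData(a)), dim(voxelData(b))) ||
      !isTRUE(all.equal(voxelSpacing(a), voxelSpacing(b))) ||
      !isTRUE(all.equal(gridOrigin(a), gridOrigin(b))))
    stop("misaligned grids")
}

#' Rigidly shift a dose grid
#'
#' Repositions the dose cloud by \code{offset} (mm, patient frame): the
#' returned grid holds \code{dose(p - offset)} by trilinear resampling;
#' samples falling outside the original grid are zero.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param offset numeric 3-vector, mm.
#' @return the shifted \linkS4class{DoseGrid}.
#' @export
shiftDose <- function(dose, offset) {
  stopifnot(is(dose, "DoseGrid"))
  if (length(offset) != 3L || any(!is.finite(offset)))
    stop("offset must be a finite 3-vector")
  if (all(offset == 0)) return(dose)
  vox <- voxelData(dose); sp <- voxelSpacing(dose)
  dv <- offset / sp                        # offset in voxel units
  # a rigid translation has constant trilinear weights, so the resampling
  # is a weighted sum of the 8 integer-shifted copies of the grid
  i0 <- floor(dv); f <- dv - i0
  out <- array(0, dim(vox))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[1] else 1 - f[1]) *
         (if (cy) f[2] else 1 - f[2]) *
         (if (cz) f[3] else 1 - f[3])
    if (w == 0) next
    out <- out + w * .translateInt(vox, i0 + c(cx, cy, cz))
  }
  DoseGrid(out, spacing = sp, origin = gridOrigin(dose))
}

# Integer-voxel translation with zero fill: out[r] = a[r - k].
.translateInt <- function(a, k) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    lo <- max(1L, 1L + k[ax]); hi <- min(d[ax], d[ax] + k[ax])
    if (lo > hi) return(out)
    dst[[ax]] <- lo:hi
    src[[ax]] <- (lo - k[ax]):(hi - k[ax])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Stochastically accumulate residual tracking errors over a course
#'
#' Models the stochastic nature of tracking, in which a different residual
#' shift applies during delivery of each beam: for every repeat, fraction
#' and beam, a residual-shift index is drawn uniformly over the available
#' shifts, the beam's per-fraction dose (total beam dose / fractions) is
#' rigidly shifted by that residual, and everything is summed into one
#' accumulated course dose per repeat. Deterministic for a fixed seed.
#'
#' @param beamDoses list of per-beam \linkS4class{DoseGrid}s (whole-course
#'   beam doses).
#' @param shifts n x 3 matrix of residual shifts (mm, predicted minus
#'   reference).
#' @param nFractions treatment fractions (default 5).
#' @param nRepeats stochastic repeats (default 10).
#' @param seed integer seed.
#' @return a list of \code{nRepeats} accumulated \linkS4class{DoseGrid}s.
#' @export
stochasticAccumulate <- function(beamDoses, shifts, nFractions = 5L,
                                 nRepeats = 10L, seed = 1L) {
  shifts <- as.matrix(shifts)
  if (!length(beamDoses)) stop("no beam doses supplied")
  if (nrow(shifts) < 1L) stop("empty residual shift series")
  for (b in beamDoses) .checkAligned(b, beamDoses[[1]])
  nb <- length(beamDoses); ns <- nrow(shifts)
  rng <- .localRNG(seed)
  on.exit(rng$restore())
  # one uniform shift index per (repeat, fraction, beam)
  idx <- array(rng$sample(ns, nRepeats * nFractions * nb, replace = TRUE),
               dim = c(nFractions, nb, nRepeats))
  # duplicate shift vectors are pooled so each is resampled only once
  key <- apply(shifts, 1, paste, collapse = "\r")
  uniq <- which(!duplicated(key))
  idx[] <- uniq[match(key[idx], key[uniq])]
  d <- dim(voxelData(beamDoses[[1]]))
  acc <- lapply(seq_len(nRepeats), function(r) array(0, d))
  # beam-major accumulation: each distinct (beam, shift) is resampled once
  for (b in seq_len(nb)) {
    counts <- matrix(apply(idx[, b, , drop = FALSE], 3,
                           function(v) tabulate(v, nbins = ns)),
                     nrow = ns)                           # ns x nRepeats
    for (s in which(rowSums(counts) > 0)) {
      sh <- voxelData(shiftDose(beamDoses[[b]], shifts[s, ]))
      for (r in which(counts[s, ] > 0))
        acc[[r]] <- acc[[r]] + (counts[s, r] / nFractions) * sh
    }
  }
  lapply(acc, DoseGrid, spacing = voxelSpacing(beamDoses[[1]]),
         origin = gridOrigin(beamDoses[[1]]))
}

#' Expectation dose over all residual shifts
#'
#' The limit of infinitely many stochastic deliveries: every part of the
#' plan receives every residual shift, so the expectation dose is the mean
#' over all shifts of the rigidly shifted total plan.
#'
#' @param totalDose the planned total \linkS4class{DoseGrid}.
#' @param shifts n x 3 matrix of residual shifts (mm).
#' @return the expectation \linkS4class{DoseGrid}.
#' @export
expectationDose <- function(totalDose, shifts) {
  shifts <- as.matrix(shifts)
  if (nrow(shifts) < 1L) stop("empty residual shift series")
  acc <- array(0, dim(voxelData(totalDose)))
  for (s in seq_len(nrow(shifts)))
    acc <- acc + voxelData(shiftDose(totalDose, shifts[s, ]))
  DoseGrid(acc / nrow(shifts), spacing = voxelSpacing(totalDose),
           origin = gridOrigin(totalDose))
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose level, on
#' a fixed dose axis with 0.1 Gy steps from zero to the structure maximum.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask a \linkS4class{StructureMask} aligned to it.
#' @param binWidth dose step, Gy (default 0.1).
#' @return a data.frame with columns \code{dose_Gy} and
#'   \code{volume_fraction} (monotonically non-increasing, 1 at zero dose).
#' @export
dvhCurve <- function(dose, mask, binWidth = 0.1) {
  .checkAligned(dose, mask)
  d <- voxelData(dose)[voxelData(mask)]
  if (!length(d)) stop("empty structure mask: ", mask@label)
  grid <- seq(0, ceiling(max(d) / binWidth) * binWidth + binWidth,
              by = binWidth)
  srt <- sort(d)
  # volume fraction receiving >= D: count of d >= D
  nBelow <- findInterval(grid, srt, left.open = TRUE)
  data.frame(dose_Gy = grid,
             volume_fraction = (length(d) - nBelow) / length(d))
}

#' Point dose metrics of a structure
#'
#' \code{D95} is the dose received by at least 95\% of the structure
#' volume; \code{D0.5cc} is the dose received by the hottest 0.5 cm^3.
#' Both are read off the exact sorted voxel list with linear interpolation
#' on the cumulative-volume curve (not the binned DVH).
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask a \linkS4class{StructureMask}.
#' @return a named list: \code{D95}, \code{D0.5cc}, \code{Dmin},
#'   \code{Dmax}, \code{Dmean} (Gy). \code{D0.5cc} errors if the structure
#'   volume is not larger than 0.5 cm^3.
#' @export
doseMetrics <- function(dose, mask) {
  .checkAligned(dose, mask)
  d <- voxelData(dose)[voxelData(mask)]
  if (!length(d)) stop("empty structure mask: ", mask@label)
  vv <- prod(voxelSpacing(mask))            # mm^3 per voxel
  srt <- sort(d, decreasing = TRUE)
  atVolume <- function(volMM3) {
    # cumulative-volume curve: j voxels cover j*vv mm^3 at dose srt[j]
    jf <- volMM3 / vv
    if (jf <= 1) return(srt[1])
    j0 <- floor(jf)
    if (j0 >= length(srt)) return(srt[length(srt)])
    srt[j0] + (jf - j0) * (srt[j0 + 1] - srt[j0])
  }
  totalMM3 <- length(d) * vv
  out <- list(D95 = atVolume(0.95 * totalMM3),
              Dmin = min(d), Dmax = max(d), Dmean = mean(d))
  if (totalMM3 <= 500)
    stop("structure '", mask@label,
         "' is not larger than 0.5 cm^3; D0.5cc undefined")
  out$`D0.5cc` <- atVolume(500)
  out[c("D95", "D0.5cc", "Dmin", "Dmax", "Dmean")]
}

#' Dosimetric impact report of residual tracking errors
#'
#' Compares planned, stochastic and expectation doses per structure:
#' D95/D0.5cc of the planned and expectation distributions with their
#' differences, and a DVH band giving, at each dose level, the min and max
#' volume fraction over the stochastic repeats.
#'
#' @param planned the planned total \linkS4class{DoseGrid}.
#' @param repeats list of accumulated \linkS4class{DoseGrid}s from
#'   [stochasticAccumulate()].
#' @param expectation the \linkS4class{DoseGrid} from [expectationDose()].
#' @param masks named list of \linkS4class{StructureMask}s.
#' @param binWidth DVH dose step, Gy.
#' @return a list with \code{metrics} (data.frame: structure, planned and
#'   expectation D95/D0.5cc and deltas, Gy) and \code{dvh} (data.frame:
#'   structure, dose_Gy, planned, expectation, band_min, band_max volume
#'   fractions).
#' @export
impactReport <- function(planned, repeats, expectation, masks,
                         binWidth = 0.1) {
  for (rep_ in repeats) .checkAligned(planned, rep_)
  .checkAligned(planned, expectation)
  metrics <- NULL; dvhAll <- NULL
  for (nm in names(masks)) {
    mask <- masks[[nm]]
    mp <- doseMetrics(planned, mask)
    me <- doseMetrics(expectation, mask)
    metrics <- rbind(metrics, data.frame(
      structure = nm,
      planned_D95_Gy = mp$D95, expectation_D95_Gy = me$D95,
      delta_D95_Gy = mp$D95 - me$D95,
      planned_D05cc_Gy = mp$`D0.5cc`, expectation_D05cc_Gy = me$`D0.5cc`,
      delta_D05cc_Gy = mp$`D0.5cc` - me$`D0.5cc`))
    maxDose <- max(voxelData(planned)[voxelData(mask)],
                   voxelData(expectation)[voxelData(mask)],
                   vapply(repeats, function(r)
                     max(voxelData(r)[voxelData(mask)]), numeric(1)))
    grid <- seq(0, ceiling(maxDose / binWidth) * binWidth + binWidth,
                by = binWidth)
    volAt <- function(dg) {
      d <- voxelData(dg)[voxelData(mask)]
      (length(d) - findInterval(grid, sort(d), left.open = TRUE)) / length(d)
    }
    reps <- vapply(repeats, volAt, numeric(length(grid)))
    dvhAll <- rbind(dvhAll, data.frame(
      structure = nm, dose_Gy = grid,
      planned = volAt(planned), expectation = volAt(expectation),
      band_min = apply(reps, 1, min), band_max = apply(reps, 1, max)))
  }
  list(metrics = metrics, dvh = dvhAll)
}
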