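## Image conditioning chain applied before registration: bandpass
## sharpening, fiducial marker removal, DRR-to-treatment equalization.

#' Radial gain of the sharpening bandpass filter
#'
#' The gain is \eqn{1 + gf} for radial frequencies \eqn{f \le 0.5 f_{max}}
#' and, by default, the continuous complement \eqn{1 + g(f_{max} - f)} for
#' \eqn{0.5 f_{max} < f \le f_{max}} so that the gain peaks at
#' \eqn{1 + 0.5 g f_{max}} and returns to 1 at the Nyquist frequency.
#' Frequencies are in discrete-transform bin units, \eqn{f_{max}} = half the
#' image size (160 for a 320-pixel image). With \code{literal = TRUE} the
#' second branch is \eqn{1 + g(f - f_{max})}, which is discontinuous at
#' \eqn{0.5 f_{max}} and dips below 1. Radial frequencies beyond
#' \eqn{f_{max}} (corner bins of the square spectrum) get gain 1.
#'
#' @param f radial frequency in bin units.
#' @param g filter gradient (default 0.02).
#' @param fmax Nyquist frequency in bin units.
#' @param literal use the discontinuous second branch.
#' @return the gain, same length as \code{f}.
#' @export
bandpassGain <- function(f, g = 0.02, fmax, literal = FALSE) {
  gain <- rep(1, length(f))
  lo <- f <= 0.5 * fmax
  hi <- !lo & f <= fmax
  gain[lo] <- 1 + g * f[lo]
  gain[hi] <- if (literal) 1 + g * (f[hi] - fmax) else 1 + g * (fmax - f[hi])
  gain
}

#' Bandpass-sharpen a projection image
#'
#' Multiplies the 2D discrete-frequency spectrum by the radial gain of
#' [bandpassGain()] and inverse-transforms, discarding the imaginary
#' residue. The DC gain is exactly 1, so the image mean is preserved.
#'
#' @param image an \linkS4class{Image2D} (square).
#' @param g filter gradient (default 0.02).
#' @param literal use the discontinuous second branch of the gain.
#' @return the filtered \linkS4class{Image2D}.
#' @export
bandpassFilter <- function(image, g = 0.02, literal = FALSE) {
  stopifnot(is(image, "Image2D"))
  m <- pixelData(image)
  N <- nrow(m)
  if (ncol(m) != N) stop("bandpassFilter requires a square image")
  if (g == 0) return(image)
  # signed frequency index of each DFT bin
  k <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1))
  if (N %% 2 == 0) k <- c(0:(N / 2 - 1), -(N / 2):-1)
  f <- sqrt(outer(k^2, k^2, "+"))
  gain <- matrix(bandpassGain(as.vector(f), g = g, fmax = N / 2,
                              literal = literal), N, N)
  out <- Re(fft(fft(m) * gain, inverse = TRUE)) / (N * N)
  Image2D(out, pixelSpacing = pixelSpacing(image))
}

#' Remove fiducial markers from a treatment image
#'
#' Selects the brightest fraction of pixels (default 0.5\%) within the
#' central region spanning 0.25 to 0.75 of the image width and height, and
#' replaces each selected pixel and its 8 immediate neighbours with the mean
#' of the four pixels located \code{neighbourOffset} pixels left, right,
#' above and below the selected pixel. Pixels outside the central region are
#' never selected. The selection count is
#' \code{ceiling(topFraction * central-region pixel count)}; ties at the
#' threshold intensity are broken in raster order. Neighbour offsets are
#' clamped to the image bounds.
#'
#' @param image an \linkS4class{Image2D}.
#' @param topFraction fraction of central-region pixels to treat.
#' @param neighbourOffset sampling offset in pixels (default 10).
#' @return the cleaned \linkS4class{Image2D}.
#' @export
removeFiducials <- function(image, topFraction = 0.005,
                            neighbourOffset = 10L) {
  stopifnot(is(image, "Image2D"))
  m <- pixelData(image)
  nr <- nrow(m); nc <- ncol(m)
  if (nc < 4L * neighbourOffset || nr < 4L * neighbourOffset)
    stop("image too small for the requested neighbour offset")
  r0 <- floor(0.25 * nr) + 1L; r1 <- floor(0.75 * nr)
  c0 <- floor(0.25 * nc) + 1L; c1 <- floor(0.75 * nc)
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  vals <- m[cbind(rows, cols)]
  nSel <- ceiling(topFraction * length(vals))
  # raster order = column-major order of (rows, cols) as built above
  ord <- order(-vals)
  sel <- ord[seq_len(nSel)]
  out <- m
  off <- as.integer(neighbourOffset)
  for (s in sel) {
    r <- rows[s]; cc <- cols[s]
    repl <- mean(c(m[r, max(1L, cc - off)], m[r, min(nc, cc + off)],
                   m[max(1L, r - off), cc], m[min(nr, r + off), cc]))
    rr <- max(1L, r - 1L):min(nr, r + 1L)
    ccr <- max(1L, cc - 1L):min(nc, cc + 1L)
    out[rr, ccr] <- repl
  }
  Image2D(out, pixelSpacing = pixelSpacing(image))
}

# 25th/75th percentile anchor surfaces for equalization: percentiles are
# computed in the four corner regions of a 5x5 partition and interpolated
# bilinearly between the corner-region centres, with clamped extrapolation.
.cornerPercentiles <- function(m, grid = 5L) {
  nr <- nrow(m); nc <- ncol(m)
  bR <- floor(seq(0, nr, length.out = grid + 1))
  bC <- floor(seq(0, nc, length.out = grid + 1))
  corners <- list(c(1L, 1L), c(1L, grid), c(grid, 1L), c(grid, grid))
  q <- lapply(corners, function(cr) {
    rows <- (bR[cr[1]] + 1L):bR[cr[1] + 1L]
    cols <- (bC[cr[2]] + 1L):bC[cr[2] + 1L]
    v <- m[rows, cols]
    c(lo = unname(stats::quantile(v, 0.25, type = 7)),
      hi = unname(stats::quantile(v, 0.75, type = 7)),
      rowCentre = mean(range(rows)), colCentre = mean(range(cols)))
  })
  q
}

# Bilinear interpolation of the four corner anchor values over the image,
# clamped outside the anchor rectangle. Returns an nr x nc matrix.
.interpCorners <- function(q, field, nr, nc) {
  rA <- q[[1]]["rowCentre"]; rB <- q[[3]]["rowCentre"]
  cA <- q[[1]]["colCentre"]; cB <- q[[2]]["colCentre"]
  tR <- pmin(pmax((seq_len(nr) - rA) / (rB - rA), 0), 1)
  tC <- pmin(pmax((seq_len(nc) - cA) / (cB - cA), 0), 1)
  v11 <- q[[1]][field]; v12 <- q[[2]][field]
  v21 <- q[[3]][field]; v22 <- q[[4]][field]
  outer(1 - tR, 1 - tC) * v11 + outer(1 - tR, tC) * v12 +
    outer(tR, 1 - tC) * v21 + outer(tR, tC) * v22
}

#' Equalize a DRR's intensities to a treatment image
#'
#' Matches the interquartile range of the DRR to that of the treatment image
#' in a smoothly varying way: 25th/75th percentiles are computed in the four
#' corner regions of a 5x5 partition of each image, interpolated bilinearly
#' over the whole image (anchored at the corner-region centres, clamped
#' outside), and each DRR pixel is remapped as
#' \deqn{D^{eq} = (D - d_{min}) s + t_{min}, \qquad
#'       s = (t_{max} - t_{min}) / (d_{max} - d_{min}),}
#' where \eqn{d} and \eqn{t} are the interpolated DRR and treatment
#' percentile surfaces.
#'
#' @param drr,treatment \linkS4class{Image2D}s of identical dimensions.
#' @param grid partition size (fixed at 5 in the processing chain).
#' @return the equalized DRR as an \linkS4class{Image2D}.
#' @export
equalizeImage <- function(drr, treatment, grid = 5L) {
  stopifnot(is(drr, "Image2D"), is(treatment, "Image2D"))
  D <- pixelData(drr); Tm <- pixelData(treatment)
  if (!identical(dim(D), dim(Tm)))
    stop("drr and treatment images must have identical dimensions")
  qd <- .cornerPercentiles(D, grid)
  qt <- .cornerPercentiles(Tm, grid)
  iqr <- vapply(qd, function(q) q["hi"] - q["lo"], numeric(1))
  if (any(iqr <= 0)) {
    bad <- c("top-left", "top-right", "bottom-left",
             "bottom-right")[which(iqr <= 0)[1]]
    stop("degenerate contrast (d_max = d_min) in DRR corner region: ", bad)
  }
  nr <- nrow(D); nc <- ncol(D)
  dmin <- .interpCorners(qd, "lo", nr, nc)
  dmax <- .interpCorners(qd, "hi", nr, nc)
  tmin <- .interpCorners(qt, "lo", nr, nc)
  tmax <- .interpCorners(qt, "hi", nr, nc)
  s <- (tmax - tmin) / (dmax - dmin)
  Image2D((D - dmin) * s + tmin, pixelSpacing = pixelSpacing(drr))
}
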