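## Synthetic patient cohorts with known ground-truth motion.

#' Specification of a synthetic tracking cohort
#'
#' Defines the study conditions for [generateCohort()]: the number of
#' patients, fractions and images, the imaging geometry, the image noise
#' and intensity-perturbation levels, and the inter-fraction baseline
#' spread (Gaussian sigma per axis). Per-patient respiratory amplitudes
#' are drawn within the peak-to-peak ranges seen clinically for pancreas
#' (left-right up to ~28 mm, antero-posterior up to ~22 mm,
#' supero-inferior up to ~34 mm).
#'
#' @param nPatients number of patients M.
#' @param nFractions fractions per patient.
#' @param nImages image pairs per fraction.
#' @param geometry an \linkS4class{ImagingGeometry}.
#' @param noiseLevel additive Gaussian noise sigma as a fraction of the
#'   DRR intensity range.
#' @param intensityPerturbation amplitude of the smooth multiplicative
#'   intensity field on treatment images.
#' @param baselineSigma per-axis sigma of the per-fraction baseline
#'   offset, mm (default 5).
#' @param amplitudeScale multiplier on the drawn respiratory amplitudes
#'   (0 gives a respiration-free cohort).
#' @param ptvMargin CTV-to-PTV margin, mm.
#' @param nFiducials fiducials per patient (present on treatment images,
#'   hidden on DRRs).
#' @param seed master seed; per-patient seeds are derived from it.
#' @return a list of class \code{"cohortSpec"}.
#' @export
cohortSpec <- function(nPatients = 4L, nFractions = 3L, nImages = 6L,
                       geometry = ImagingGeometry(128L, 1.25),
                       noiseLevel = 0.02, intensityPerturbation = 0.05,
                       baselineSigma = 5, amplitudeScale = 1,
                       ptvMargin = 5, nFiducials = 3L,
                       seed = 1L) {
  stopifnot(nPatients >= 1L, nFractions >= 1L, nImages >= 1L)
  structure(list(nPatients = as.integer(nPatients),
                 nFractions = as.integer(nFractions),
                 nImages = as.integer(nImages), geometry = geometry,
                 noiseLevel = noiseLevel,
                 intensityPerturbation = intensityPerturbation,
                 baselineSigma = baselineSigma,
                 amplitudeScale = amplitudeScale, ptvMargin = ptvMargin,
                 nFiducials = as.integer(nFiducials),
                 seed = as.integer(seed)), class = "cohortSpec")
}

.patientSeed <- function(master, p)
  as.integer((as.numeric(master) * 1009 + p * 9176) %% 2147483647)

#' Generate a synthetic tracking cohort
#'
#' For each patient: a patient-specific abdomen phantom (jittered anatomy,
#' respiratory amplitude and period drawn within clinical pancreas ranges),
#' a planning DRR pair (planning-day bowel-gas state, fiducials hidden by
#' density clipping), and per fraction a Gaussian baseline offset, a
#' redrawn bowel-gas state, and noisy treatment image pairs sampled along
#' the respiratory trace with fiducials visible. Ground truth target
#' positions are recorded per image pair. Deterministic for a fixed seed.
#'
#' @param spec a [cohortSpec()].
#' @param dir optional directory; when given, the on-disk cohort layout
#'   (DRRs, treatment images, masks, truth.csv) is written there.
#' @param verbose print per-patient progress.
#' @return a list of class \code{"orthoCohort"}: \code{spec},
#'   \code{geometry}, \code{patients} (each with \code{drr}, \code{ptvBBox},
#'   \code{masks}, \code{fractions} holding images and positions) and
#'   \code{truth} (data.frame: patient, fraction, image, x_mm, y_mm, z_mm).
#' @export
generateCohort <- function(spec, dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "cohortSpec"))
  geometry <- spec$geometry
  patients <- vector("list", spec$nPatients)
  truth <- NULL
  for (p in seq_len(spec$nPatients)) {
    pSeed <- .patientSeed(spec$seed, p)
    rng <- .localRNG(pSeed)
    cfg <- phantomConfig(
      targetCentre = c(34, 22, -15) + rng$runif(3, -6, 6),
      bodyAxes = c(110, 85) + rng$runif(2, -8, 8),
      diaphragmApex = 80 + rng$runif(1, -10, 10),
      ptvMargin = spec$ptvMargin, nFiducials = spec$nFiducials,
      seed = pSeed)
    amplitude <- spec$amplitudeScale *
      c(rng$runif(1, 3.5, 14),               # half peak-to-peak, mm
        rng$runif(1, 3.75, 11),
        rng$runif(1, 7, 17))
    period <- rng$runif(1, 3.2, 5)
    phases <- rng$runif(spec$nFractions, 0, 2 * pi)
    baselines <- matrix(rng$rnorm(3 * spec$nFractions, 0,
                                  spec$baselineSigma),
                        spec$nFractions, 3, byrow = TRUE)
    rng$restore()
    phantom <- buildPhantom(cfg)
    planProj <- projectPhantom(phantom, geometry,
                               gasDelta = .gasDelta(cfg, pSeed, phantom))
    base <- planProj$base
    fractions <- vector("list", spec$nFractions)
    for (f in seq_len(spec$nFractions)) {
      gas <- .gasDelta(cfg, pSeed + 7000L + f, phantom)
      proj <- projectPhantom(phantom, geometry, gasDelta = gas, base = base)
      trace <- motionTrace(baseline = baselines[f, ],
                           amplitude = amplitude, period = period,
                           phase = phases[f])
      sp_ <- samplePositions(trace, spec$nImages)
      images <- vector("list", spec$nImages)
      for (n in seq_len(spec$nImages)) {
        iSeed <- pSeed %% 100000L + f * 1000L + n
        images[[n]] <- list(
          A = renderTreatmentImage(proj, truePosition = sp_$positions[n, ],
                                   noiseLevel = spec$noiseLevel,
                                   intensityPerturbation =
                                     spec$intensityPerturbation,
                                   seed = iSeed, view = "A"),
          B = renderTreatmentImage(proj, truePosition = sp_$positions[n, ],
                                   noiseLevel = spec$noiseLevel,
                                   intensityPerturbation =
                                     spec$intensityPerturbation,
                                   seed = iSeed + 500000L, view = "B"))
      }
      fractions[[f]] <- list(images = images, positions = sp_$positions,
                             baseline = baselines[f, ])
      truth <- rbind(truth, data.frame(
        patient = p, fraction = f, image = seq_len(spec$nImages),
        x_mm = sp_$positions[, 1], y_mm = sp_$positions[, 2],
        z_mm = sp_$positions[, 3]))
    }
    sp <- pixelSpacing(geometry)
    patients[[p]] <- list(
      index = p,
      drr = list(A = Image2D(planProj$drr$A, sp),
                 B = Image2D(planProj$drr$B, sp)),
      ptvBBox = list(A = .maskBBox(phantom$masks$PTV, geometry, "A"),
                     B = .maskBBox(phantom$masks$PTV, geometry, "B")),
      masks = phantom$masks, fractions = fractions,
      prescription = 35)
    if (verbose) message("patient ", p, " generated")
  }
  rownames(truth) <- NULL
  cohort <- structure(list(spec = spec, geometry = geometry,
                           patients = patients, truth = truth),
                      class = "orthoCohort")
  if (!is.null(dir)) writeCohort(cohort, dir)
  cohort
}

#' Track a whole synthetic cohort
#'
#' Runs the preprocessing chain (bandpass sharpening of DRRs and treatment
#' images, fiducial removal on treatment images, DRR-to-treatment
#' equalization) and the full registration of every image pair, assembling
#' the motion-model observations.
#'
#' @param cohort an \code{"orthoCohort"}.
#' @param g bandpass filter gradient.
#' @param topFraction,neighbourOffset fiducial-removal parameters.
#' @param bins NMI histogram bins.
#' @param verbose print per-fraction progress with timing.
#' @return a list with \code{observations} (a [motionObservations()]
#'   pairing each 104-component registration vector with its ground-truth
#'   position) and \code{records} (data.frame with the back-projected
#'   PTV-region position per image pair).
#' @export
trackCohort <- function(cohort, g = 0.02, topFraction = 0.005,
                        neighbourOffset = 10L, bins = 128L,
                        verbose = FALSE) {
  stopifnot(inherits(cohort, "orthoCohort"))
  geometry <- cohort$geometry
  vs <- NULL; recs <- NULL
  pats <- integer(0); fracs <- integer(0)
  for (pat in cohort$patients) {
    drrA <- bandpassFilter(pat$drr$A, g = g)
    drrB <- bandpassFilter(pat$drr$B, g = g)
    for (f in seq_along(pat$fractions)) {
      t0 <- Sys.time()
      fr <- pat$fractions[[f]]
      for (n in seq_along(fr$images)) {
        trtA <- removeFiducials(bandpassFilter(fr$images[[n]]$A, g = g),
                                topFraction, neighbourOffset)
        trtB <- removeFiducials(bandpassFilter(fr$images[[n]]$B, g = g),
                                topFraction, neighbourOffset)
        eqA <- equalizeImage(drrA, trtA)
        eqB <- equalizeImage(drrB, trtB)
        reg <- registerImagePair(eqA, eqB, trtA, trtB,
                                 pat$ptvBBox$A, pat$ptvBBox$B,
                                 geometry, bins = bins)
        vs <- rbind(vs, reg$vector@values)
        pats <- c(pats, pat$index); fracs <- c(fracs, f)
        recs <- rbind(recs, data.frame(
          patient = pat$index, fraction = f, image = n,
          ptv_x_mm = reg$ptvPosition[1], ptv_y_mm = reg$ptvPosition[2],
          ptv_z_mm = reg$ptvPosition[3]))
      }
      if (verbose)
        message(sprintf("patient %d fraction %d tracked (%.1f s)",
                        pat$index, f,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  r <- as.matrix(cohort$truth[, c("x_mm", "y_mm", "z_mm")])
  list(observations = motionObservations(vs, r, pats, fracs),
       records = cbind(recs, cohort$truth[, c("x_mm", "y_mm", "z_mm")]))
}

#' Simulate motion-model observations directly
#'
#' Generates (registration vector, position) observations from a known
#' linear map without rendering images: ground-truth positions follow
#' per-fraction Gaussian baselines plus a per-patient respiratory trace,
#' and each registration vector is the geometric image response
#' \eqn{v = G r} of its position, perturbed by i.i.d. per-image noise and a
#' per-fraction structured nuisance (emulating day-to-day bowel-state
#' change, which shifts the whole registration state of a fraction). The
#' map G follows the stereo projection of each region slot, scaled by
#' fixed per-region response weights.
#'
#' @param nPatients,nFractions,nImages cohort dimensions.
#' @param baselineSigma per-fraction baseline sigma, mm (default 5).
#' @param imageNoise per-component registration noise sigma, mm.
#' @param fractionNoise per-fraction structured nuisance sigma, mm.
#' @param seed master seed.
#' @return a list with \code{observations} (a [motionObservations()]) and
#'   \code{map} (the 104 x 3 response matrix G).
#' @export
simulateObservationCohort <- function(nPatients = 4L, nFractions = 3L,
                                      nImages = 20L, baselineSigma = 5,
                                      imageNoise = 0.5, fractionNoise = 1.5,
                                      seed = 1L) {
  G <- .regionResponseMap()
  rng <- .localRNG(seed)
  on.exit(rng$restore())
  v <- NULL; r <- NULL; pats <- integer(0); fracs <- integer(0)
  for (p in seq_len(nPatients)) {
    amplitude <- c(rng$runif(1, 3.5, 14), rng$runif(1, 3.75, 11),
                   rng$runif(1, 7, 17))
    period <- rng$runif(1, 3.2, 5)
    for (f in seq_len(nFractions)) {
      baseline <- rng$rnorm(3, 0, baselineSigma)
      phase <- rng$runif(1, 0, 2 * pi)
      t <- (seq_len(nImages) - 1) * 7
      w <- 2 * cos(pi * t / period + phase / 2)^4 - 1
      pos <- sweep(outer(w, amplitude), 2, baseline, "+")
      nuisance <- rng$rnorm(104, 0, fractionNoise)
      for (n in seq_len(nImages)) {
        vi <- drop(G %*% pos[n, ]) + nuisance +
          rng$rnorm(104, 0, imageNoise)
        v <- rbind(v, vi); r <- rbind(r, pos[n, ])
        pats <- c(pats, p); fracs <- c(fracs, f)
      }
    }
  }
  list(observations = motionObservations(v, r, pats, fracs), map = G)
}

# Fixed 104 x 3 response map: each region slot responds to the projected
# shift of its view with a region-specific weight (deterministic).
.regionResponseMap <- function() {
  R <- .R_CONST
  rngState <- .localRNG(760219L)
  wts <- rngState$runif(52, 0.2, 1)
  rngState$restore()
  G <- matrix(0, 104, 3)
  slot <- 0L
  for (img in c("A", "B")) for (reg in 1:26) {
    wI <- wts[(if (img == "A") 0 else 26) + reg]
    wJ <- wts[(if (img == "A") 26 else 0) + reg]
    iRow <- if (img == "A") R * c(1, -1, 0) else R * c(1, 1, 0)
    G[slot + 1L, ] <- wI * iRow
    G[slot + 2L, ] <- wJ * c(0, 0, -1)
    slot <- slot + 2L
  }
  G
}
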