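test_that("phantom with no stochastic structure uses only configured densities", {
  cfg <- phantomConfig(volSize = 48L, spacing = 4, nGasPockets = 0L,
                      nFiducials = 0L, nTextureBlobs = 0L,
                      organBlockDelta = 0)
  ph <- buildPhantom(cfg)
  vol <- voxelData(phantomVolume(ph))
  expect_true(all(vol %in% c(0, cfg$bodyDensity, cfg$spineDensity,
                             cfg$lungDensity, cfg$targetDensity)))
})

test_that("PTV is the CTV dilated by the margin (distance-transform oracle)", {
  cfg <- phantomConfig(volSize = 48L, spacing = 2, ptvMargin = 5,
                      nGasPockets = 0L, nFiducials = 0L,
                      targetCentre = c(10, 6, -8), targetRadius = 8)
  ph <- buildPhantom(cfg)
  ctv <- voxelData(ph$masks$CTV); ptv <- voxelData(ph$masks$PTV)
  expect_true(all(ptv[ctv]))
  # brute-force distance check on the PTV surface
  ci <- which(ctv, arr.ind = TRUE)
  pi_ <- which(ptv & !ctv, arr.ind = TRUE)
  maxd <- 0
  for (r in seq_len(nrow(pi_))) {
    d2 <- colSums((t(ci) - pi_[r, ])^2) * 4  # spacing 2mm isotropic
    maxd <- max(maxd, sqrt(min(d2)))
  }
  expect_lte(maxd, 5 + 2 * sqrt(3))  # margin + one voxel diagonal
  # and no dilated voxel is omitted: voxels within margin of CTV are in PTV
  outside <- which(!ptv, arr.ind = TRUE)
  somePts <- outside[seq(1, nrow(outside), length.out = 500), , drop = FALSE]
  for (r in seq_len(nrow(somePts))) {
    d2 <- min(colSums((t(ci) - somePts[r, ])^2)) * 4
    expect_gte(sqrt(d2), 5 - 2 * sqrt(3))
  }
})

test_that("phantom construction is deterministic for a fixed seed", {
  cfg <- phantomConfig(volSize = 40L, spacing = 4, seed = 11L)
  a <- buildPhantom(cfg); b <- buildPhantom(cfg)
  expect_identical(a$movingBase, b$movingBase)
  expect_identical(a$static, b$static)
  expect_identical(voxelData(phantomVolume(a)), voxelData(phantomVolume(b)))
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantomConfig(targetCentre = c(300, 0, 0)), "outside")
  expect_error(phantomConfig(nFiducials = 2L, fiducialDensity = 1.5),
               "1.869")
})

test_that("motion traces follow baseline + amplitude * waveform", {
  tz <- motionTrace(baseline = c(0, 0, 0), amplitude = c(0, 0, 0))
  expect_equal(samplePositions(tz, 5)$positions,
               matrix(0, 5, 3, dimnames = list(NULL, c("x", "y", "z"))))
  # cosine trace sampled half a period apart: peak-to-peak 20 mm
  tr <- motionTrace(amplitude = c(0, 0, 10), period = 4, phase = 0,
                    waveform = "cos", sampleTimes = c(0, 2))
  p <- samplePositions(tr, 2)$positions
  expect_equal(unname(p[1, "z"] - p[2, "z"]), 20)
  # determinism and reported mean
  t1 <- motionTrace(baseline = c(1, 2, 3), amplitude = c(2, 2, 8))
  s1 <- samplePositions(t1, 7); s2 <- samplePositions(t1, 7)
  expect_identical(s1$positions, s2$positions)
  expect_equal(s1$mean, colMeans(s1$positions))
})

test_that("cos4 waveform has the configured peak-to-peak range", {
  tr <- motionTrace(amplitude = c(0, 0, 8), period = 4, phase = 0,
                    sampleTimes = seq(0, 8, by = 0.01))
  z <- samplePositions(tr, 801)$positions[, "z"]
  expect_equal(max(z) - min(z), 16, tolerance = 1e-3)
})

test_that("DRR line integral matches the analytic path through a cube", {
  # uniform density-1 cube, 100 mm side; a 45-degree ray through its centre
  # crosses 100*sqrt(2) mm, so the pixel value is 0.0171 * 141.42 = 2.418
  n <- 60L; sp <- 2.5
  vox <- array(0, c(n, n, n))
  ax <- (seq_len(n) - (n + 1) / 2) * sp
  inside <- abs(ax) <= 50
  vox[inside, inside, inside] <- 1
  grid <- DoseGrid(vox, spacing = sp, origin = rep(ax[1], 3))
  g <- ImagingGeometry(65L, 2.5)    # odd size: a pixel sits on the axis
  drr <- renderDRR(grid, g, view = "A")
  centre <- pixelData(drr)[33, 33]
  expect_equal(centre, 0.0171 * 100 * sqrt(2), tolerance = 0.02)
  # empty volume renders to zero
  empty <- DoseGrid(array(0, c(n, n, n)), spacing = sp, origin = rep(ax[1], 3))
  expect_true(all(pixelData(renderDRR(empty, g, "A")) == 0))
})

test_that("density clipping hides high-density voxels in the DRR", {
  n <- 40L; sp <- 2
  ax <- (seq_len(n) - (n + 1) / 2) * sp
  vox <- array(0, c(n, n, n))
  vox[16:25, 16:25, 16:25] <- 3.0   # would be clipped to 1.0
  ref <- array(0, c(n, n, n)); ref[16:25, 16:25, 16:25] <- 1.0
  g <- ImagingGeometry(64L, 2)
  a <- renderDRR(DoseGrid(vox, spacing = sp, origin = rep(ax[1], 3)), g, "A")
  b <- renderDRR(DoseGrid(ref, spacing = sp, origin = rep(ax[1], 3)), g, "A")
  expect_equal(pixelData(a), pixelData(b))
})

test_that("treatment image equals the DRR for the identity case", {
  cfg <- phantomConfig(nFiducials = 0L, seed = 3L)
  ph <- buildPhantom(cfg)
  g <- ImagingGeometry(128L, 1.25)
  proj <- projectPhantom(ph, g)
  trt <- renderTreatmentImage(proj, truePosition = c(0, 0, 0),
                              noiseLevel = 0, intensityPerturbation = 0)
  expect_equal(pixelData(trt), proj$drr$A, tolerance = 1e-9)
})

test_that("a vertical target displacement moves the diaphragm edge", {
  fix <- testPhantomProjection()
  dz <- 10
  trt <- renderTreatmentImage(fix$proj, truePosition = c(0, 0, dz))
  drr <- fix$proj$drr$A
  # locate the diaphragm edge by the maximum row-gradient of the column sums
  profile <- function(m) rowSums(m)
  edgeRow <- function(m) which.max(abs(diff(profile(m))))
  shiftRows <- edgeRow(pixelData(trt)) - edgeRow(drr)
  expect_equal(shiftRows, round(-dz / 1.25), tolerance = 1)
})

test_that("treatment rendering is deterministic for a fixed seed", {
  fix <- testPhantomProjection()
  a <- renderTreatmentImage(fix$proj, truePosition = c(1, 2, 3),
                            noiseLevel = 0.05, intensityPerturbation = 0.05,
                            seed = 9L)
  b <- renderTreatmentImage(fix$proj, truePosition = c(1, 2, 3),
                            noiseLevel = 0.05, intensityPerturbation = 0.05,
                            seed = 9L)
  expect_identical(pixelData(a), pixelData(b))
})

test_that("cohort generation yields the declared counts and determinism", {
  spec <- cohortSpec(nPatients = 1L, nFractions = 1L, nImages = 3L,
                     geometry = ImagingGeometry(64L, 2.5), seed = 5L)
  co <- generateCohort(spec)
  expect_length(co$patients, 1L)
  expect_length(co$patients[[1]]$fractions[[1]]$images, 3L)
  expect_equal(nrow(co$truth), 3L)
  co2 <- generateCohort(spec)
  expect_identical(co$truth, co2$truth)
  expect_identical(pixelData(co$patients[[1]]$fractions[[1]]$images[[2]]$A),
                   pixelData(co2$patients[[1]]$fractions[[1]]$images[[2]]$A))
  # zero-motion cohort has an all-zero truth table
  spec0 <- cohortSpec(nPatients = 1L, nFractions = 1L, nImages = 2L,
                      geometry = ImagingGeometry(64L, 2.5),
                      baselineSigma = 0, amplitudeScale = 0, seed = 5L)
  co0 <- generateCohort(spec0)
  expect_true(all(co0$truth[, c("x_mm", "y_mm", "z_mm")] == 0))
})

test_that("synthetic plan is conformal, normalized and conserves components", {
  fix <- testPhantomProjection()
  masks <- orthoTrack:::.cropMasks(fix$phantom$masks[c("CTV", "PTV")], 30)
  plan <- syntheticPlan(masks$PTV, nBeams = 5L, prescription = 35)
  expect_equal(doseMetrics(plan$total, masks$PTV)$D95, 35, tolerance = 0.01)
  # sum of per-beam components equals the total voxelwise
  acc <- array(0, dim(voxelData(plan$total)))
  for (b in plan$beams) acc <- acc + voxelData(b)
  expect_equal(acc, voxelData(plan$total), tolerance = 1e-12)
  # single beam: the total is that component
  p1 <- syntheticPlan(masks$PTV, nBeams = 1L, prescription = 20)
  expect_equal(voxelData(p1$beams[[1]]), voxelData(p1$total))
  expect_error(syntheticPlan(StructureMask(array(FALSE, c(4, 4, 4)),
                                           label = "PTV")), "empty")
})
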