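# A small Gaussian dose blob on a padded grid, plus a spherical mask.
gaussianDose <- function(n = 24L, sp = 2, sigma = 10, amp = 35) {
  ax <- (seq_len(n) - (n + 1) / 2) * sp
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  DoseGrid(amp * exp(-r2 / (2 * sigma^2)), spacing = sp,
           origin = rep(ax[1], 3))
}

sphereMaskOn <- function(grid, radius, label = "CTV") {
  d <- dim(voxelData(grid)); sp <- voxelSpacing(grid)
  org <- gridOrigin(grid)
  ax <- lapply(1:3, function(a) org[a] + (seq_len(d[a]) - 1) * sp[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  StructureMask(r2 <= radius^2, spacing = sp, origin = org, label = label)
}

test_that("rigid dose shifts behave like exact translations", {
  g <- gaussianDose()
  expect_identical(voxelData(shiftDose(g, c(0, 0, 0))), voxelData(g))
  # one full voxel along x: interior voxels shift by exactly one index
  s <- voxelData(shiftDose(g, c(2, 0, 0)))
  expect_equal(s[2:24, , ], voxelData(g)[1:23, , ], tolerance = 1e-12)
  # shift then inverse-shift recovers a smooth dose within 2% of max
  gs <- gaussianDose(n = 30L, sigma = 15)
  s2 <- shiftDose(shiftDose(gs, c(3.3, -1.7, 0.9)), -c(3.3, -1.7, 0.9))
  expect_lt(max(abs(voxelData(s2) - voxelData(gs))[4:27, 4:27, 4:27]),
            0.02 * max(voxelData(gs)))
  expect_error(shiftDose(g, c(1, NA, 0)), "finite")
})

test_that("integral dose is conserved up to boundary outflow", {
  # compact dose on a well-padded grid, as the synthetic plans provide
  g <- gaussianDose(n = 40L, sigma = 5)
  for (off in list(c(5, 0, 0), c(-8, 12, 3), c(0, 0, 20))) {
    s <- shiftDose(g, unlist(off))
    expect_equal(sum(voxelData(s)), sum(voxelData(g)),
                 tolerance = 1e-3)
  }
})

test_that("stochastic accumulation degenerates correctly", {
  g <- gaussianDose()
  beams <- lapply(1:3, function(b)
    DoseGrid(voxelData(g) / 3, voxelSpacing(g), gridOrigin(g)))
  total <- array(0, dim(voxelData(g)))
  for (b in beams) total <- total + voxelData(b)
  # zero residuals reproduce the planned total bit-exactly
  reps <- stochasticAccumulate(beams, matrix(0, 4, 3), nFractions = 5L,
                               nRepeats = 3L, seed = 1L)
  for (r in reps) expect_identical(voxelData(r), total)
  # a single shift in the series reproduces the shifted plan
  sh <- matrix(c(4, -2, 6), 1, 3)
  reps1 <- stochasticAccumulate(beams, sh, nFractions = 5L, nRepeats = 2L,
                                seed = 2L)
  ref <- voxelData(shiftDose(DoseGrid(total, voxelSpacing(g),
                                      gridOrigin(g)), sh[1, ]))
  for (r in reps1) expect_equal(voxelData(r), ref, tolerance = 1e-12)
  # determinism
  set.seed(99)
  shm <- matrix(rnorm(15), 5, 3)
  a <- stochasticAccumulate(beams, shm, seed = 3L)
  b <- stochasticAccumulate(beams, shm, seed = 3L)
  expect_identical(lapply(a, voxelData), lapply(b, voxelData))
  expect_error(stochasticAccumulate(list(), sh), "beam")
  expect_error(stochasticAccumulate(beams, sh[0, , drop = FALSE]), "empty")
})

test_that("expectation dose is the mean over shifted plans", {
  g <- gaussianDose()
  expect_equal(voxelData(expectationDose(g, matrix(0, 1, 3))),
               voxelData(g))
  # +d/-d on a linear ramp leaves interior voxels unchanged
  n <- 20L
  ramp <- DoseGrid(array(rep(seq_len(n), times = n * n), c(n, n, n)),
                   spacing = 2, origin = c(0, 0, 0))
  e <- expectationDose(ramp, rbind(c(4, 0, 0), c(-4, 0, 0)))
  expect_equal(voxelData(e)[4:17, , ], voxelData(ramp)[4:17, , ],
               tolerance = 1e-12)
  # convexity: voxelwise bounded by min/max over the shifted grids
  g2 <- gaussianDose()
  shifts <- rbind(c(3, 1, -2), c(-5, 0, 4), c(0, 2, 0))
  shifted <- lapply(seq_len(nrow(shifts)), function(s)
    voxelData(shiftDose(g2, shifts[s, ])))
  e2 <- voxelData(expectationDose(g2, shifts))
  lo <- pmin(shifted[[1]], shifted[[2]], shifted[[3]])
  hi <- pmax(shifted[[1]], shifted[[2]], shifted[[3]])
  expect_true(all(e2 >= lo - 1e-12 & e2 <= hi + 1e-12))
})

test_that("stochastic accumulation converges to the expectation dose", {
  g <- gaussianDose(n = 16L)
  set.seed(60)
  shifts <- matrix(rnorm(24, 0, 4), 8, 3)
  reps <- stochasticAccumulate(list(g), shifts, nFractions = 5L,
                               nRepeats = 200L, seed = 61L)
  arr <- simplify2array(lapply(reps, voxelData))
  meanRep <- apply(arr, 1:3, mean)
  seRep <- apply(arr, 1:3, sd) / sqrt(200)
  expd <- voxelData(expectationDose(g, shifts))
  expect_true(all(abs(meanRep - expd) <= 3 * seRep + 1e-9))
})

test_that("DVH curve matches a sorting oracle", {
  g <- gaussianDose()
  mask <- sphereMaskOn(g, 16)
  curve <- dvhCurve(g, mask)
  d <- voxelData(g)[voxelData(mask)]
  oracle <- vapply(curve$dose_Gy, function(x) mean(d >= x), numeric(1))
  expect_equal(curve$volume_fraction, oracle)
  expect_equal(curve$volume_fraction[1], 1)
  expect_true(all(diff(curve$volume_fraction) <= 0))
  # uniform dose: a step function at the dose level
  u <- DoseGrid(array(35, dim(voxelData(g))), voxelSpacing(g),
                gridOrigin(g))
  cu <- dvhCurve(u, mask)
  expect_true(all(cu$volume_fraction[cu$dose_Gy <= 35] == 1))
  expect_true(all(cu$volume_fraction[cu$dose_Gy > 35] == 0))
  # two-voxel mask with doses 10 and 30
  m2 <- array(FALSE, dim(voxelData(g))); m2[1:2] <- TRUE
  d2 <- array(0, dim(voxelData(g))); d2[1] <- 10; d2[2] <- 30
  c2 <- dvhCurve(DoseGrid(d2, voxelSpacing(g), gridOrigin(g)),
                 StructureMask(m2, voxelSpacing(g), gridOrigin(g), "x"))
  mid <- c2$dose_Gy > 10 & c2$dose_Gy <= 30
  expect_true(all(c2$volume_fraction[mid] == 0.5))
})

test_that("dose metrics follow the sorted cumulative-volume curve", {
  g <- gaussianDose()
  mask <- sphereMaskOn(g, 16)
  u <- DoseGrid(array(35, dim(voxelData(g))), voxelSpacing(g),
                gridOrigin(g))
  mu <- doseMetrics(u, mask)
  expect_equal(mu$D95, 35)
  expect_equal(mu$`D0.5cc`, 35)
  # 1000 voxels of 8 mm^3 with linearly spaced doses: 0.5 cc = 62.5 voxels
  n <- 10L
  doses <- array(seq(0, 39.96, length.out = 1000), c(n, n, n))
  dg <- DoseGrid(doses, spacing = 2, origin = c(0, 0, 0))
  allm <- StructureMask(array(TRUE, c(n, n, n)), spacing = 2,
                        origin = c(0, 0, 0), label = "block")
  srt <- sort(doses, decreasing = TRUE)
  expected <- srt[62] + 0.5 * (srt[63] - srt[62])
  expect_equal(doseMetrics(dg, allm)$`D0.5cc`, expected, tolerance = 1e-12)
  # D95 <= D0.5cc always (order statistics)
  set.seed(62)
  rd <- DoseGrid(array(runif(n^3, 0, 40), c(n, n, n)), spacing = 2,
                 origin = c(0, 0, 0))
  mr <- doseMetrics(rd, allm)
  expect_lte(mr$D95, mr$`D0.5cc`)
  # tiny structures cannot report D0.5cc
  tiny <- array(FALSE, c(n, n, n)); tiny[1:10] <- TRUE
  expect_error(doseMetrics(dg, StructureMask(tiny, spacing = 2,
                                             origin = c(0, 0, 0),
                                             label = "seed")), "seed")
})

test_that("impact report compares planned, stochastic and expectation dose", {
  g <- gaussianDose(n = 20L)
  beams <- list(DoseGrid(voxelData(g), voxelSpacing(g), gridOrigin(g)))
  masks <- list(CTV = sphereMaskOn(g, 12))
  zero <- matrix(0, 3, 3)
  reps <- stochasticAccumulate(beams, zero, nRepeats = 4L, seed = 63L)
  expd <- expectationDose(g, zero)
  rep0 <- impactReport(g, reps, expd, masks)
  expect_equal(rep0$metrics$delta_D95_Gy, 0, tolerance = 1e-9)
  expect_true(all(rep0$dvh$band_max - rep0$dvh$band_min < 1e-12))
  # nonzero spread cannot raise the cold-quantile coverage
  set.seed(64)
  sh <- matrix(rnorm(30, 0, 5), 10, 3)
  expd2 <- expectationDose(g, sh)
  reps2 <- stochasticAccumulate(beams, sh, nRepeats = 4L, seed = 65L)
  rep2 <- impactReport(g, reps2, expd2, masks)
  expect_lte(rep2$metrics$expectation_D95_Gy, rep2$metrics$planned_D95_Gy)
  # the band encloses the mean of repeats at every level
  arr <- simplify2array(lapply(reps2, function(r)
    dvhCurve(r, masks$CTV,
             binWidth = diff(rep2$dvh$dose_Gy[1:2]))$volume_fraction))
  expect_true(all(rep2$dvh$band_min <= rep2$dvh$band_max))
  # misaligned grids are rejected
  bad <- DoseGrid(voxelData(g), voxelSpacing(g) * 2, gridOrigin(g))
  expect_error(impactReport(bad, reps2, expd2, masks), "misaligned")
})
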