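test_that("NMS matches the hand-computed normalization", {
  # D = [0, 2], T = [1, 3]: N = max(2-1, 3-0)^2 = 9, NMS = 1 - 2/(9*2) = 8/9
  D <- matrix(c(0, 2), 1, 2)
  T_ <- matrix(c(1, 3), 1, 2)
  expect_equal(nmsScore(D, T_), 8 / 9, tolerance = 1e-12)
  # identical content scores exactly 1
  m <- textureImage(32, seed = 1)
  expect_equal(nmsScore(m, m), 1)
  # upper bound holds for arbitrary content
  set.seed(2)
  for (k in 1:20) {
    a <- matrix(rnorm(64), 8, 8); b <- matrix(rnorm(64), 8, 8)
    expect_lte(nmsScore(a, b), 1)
  }
})

test_that("NMI reproduces closed-form entropy identities", {
  # identical images with >= 2 occupied bins: diagonal joint histogram
  m <- textureImage(32, seed = 3)
  expect_equal(nmiScore(m, m), 2, tolerance = 1e-12)
  # independent two-level images, joint uniform over 4 cells: NMI = 1
  D <- matrix(c(0, 0, 1, 1), 2, 2)
  T_ <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(nmiScore(D, T_), 1, tolerance = 1e-12)
  # both regions constant: degenerate perfect match, mapped to 2
  expect_equal(nmiScore(matrix(1, 4, 4), matrix(1, 4, 4)), 2)
})

test_that("the gamma objective composes NMS and NMI", {
  m <- textureImage(32, seed = 4)
  o <- registrationObjective(m, m)
  expect_equal(o$gamma, 2, tolerance = 1e-12)
  expect_equal(o$gamma, o$nms * o$nmi)
  D <- matrix(c(0, 2), 1, 2)
  T_ <- matrix(c(1, 3), 1, 2)
  o2 <- registrationObjective(D, T_)
  expect_equal(o2$gamma, o2$nms * o2$nmi, tolerance = 1e-12)
  expect_error(nmsScore(m, m, rows = 1:4, cols = 1:4, shift = c(40L, 0L)),
               "overlap")
})

test_that("gamma peaks at the true shift on noise-free shifted pairs", {
  for (seed in 1:5) {
    set.seed(seed + 20)
    I <- sample(-6:6, 1); J <- sample(-6:6, 1)
    p <- shiftedTexturePair(48, I, J, seed = seed)
    best <- registrationObjective(p$drr, p$trt, shift = c(I, J))$gamma
    for (dI in -8:8) for (dJ in c(-8, -3, 0, 3, 8)) {
      if (dI == I && dJ == J) next
      expect_lte(registrationObjective(p$drr, p$trt,
                                       shift = c(dI, dJ))$gamma, best)
    }
  }
})

test_that("gamma is invariant under joint affine intensity rescaling", {
  p <- shiftedTexturePair(48, 3, -2, seed = 9)
  g1 <- registrationObjective(p$drr, p$trt, shift = c(3L, -2L))$gamma
  g2 <- registrationObjective(5 * p$drr + 1, 5 * p$trt + 1,
                              shift = c(3L, -2L))$gamma
  expect_equal(g1, g2, tolerance = 1e-6)
})

test_that("coupled search recovers exact shifts and matches identity pairs", {
  # identical pairs register to zero
  a <- textureImage(64, seed = 11); b <- textureImage(64, seed = 12)
  z <- coupledSearch(a, b, a, b)
  expect_equal(c(z@iA, z@iB, z@jAB), c(0, 0, 0))
  # known integer shifts on the coarse lattice are found exactly
  pA <- shiftedTexturePair(64, 6, 8, seed = 13)
  pB <- shiftedTexturePair(64, -4, 8, seed = 14)
  s <- coupledSearch(pA$drr, pB$drr, pA$trt, pB$trt)
  expect_equal(c(s@iA, s@iB, s@jAB), c(6, -4, 8))
  expect_equal(shiftUnit(s), "pixels")
  # results always lie within the reachable window
  pC <- shiftedTexturePair(64, 21, 0, seed = 15)
  pD <- shiftedTexturePair(64, 0, 0, seed = 16)
  sC <- coupledSearch(pC$drr, pD$drr, pC$trt, pD$trt)
  expect_true(all(abs(c(sC@iA, sC@iB, sC@jAB)) <= 22))
})

test_that("subregion refinement localizes piecewise motion", {
  # identical images: all 25 region shifts are zero
  m <- textureImage(96, seed = 17)
  g0 <- subregionSearch(m, m, start = c(0L, 0L))
  expect_equal(g0, matrix(0L, 25, 2, dimnames = list(NULL, c("I", "J"))))
  # lower half shifted down 6 rows, upper half static
  big <- textureImage(96 + 40, seed = 18)
  base <- big[21:116, 21:116]
  moved <- base
  moved[61:96, ] <- big[(61:96) + 20 - 6, 21:116]
  grid <- subregionSearch(base, moved, start = c(0L, 0L))
  lay <- subregionLayout(96)
  topRows <- grid[1:5, "J"]        # regions in grid row 1 (top)
  botRows <- grid[21:25, "J"]      # grid row 5 (bottom)
  expect_true(all(topRows == 0))
  expect_true(all(botRows == 6))
  # search-bound contract
  expect_true(all(abs(grid) <= 11))
})

test_that("PTV-region coupled search recovers a target-only displacement", {
  fix <- testPhantomProjection()
  proj <- fix$proj; g <- fix$geometry
  pos <- c(3, 0, 0)                       # lateral-only displacement
  tA <- renderTreatmentImage(proj, truePosition = pos)
  tB <- renderTreatmentImage(proj, truePosition = pos, view = "B")
  ptv <- ptvRegionSearch(proj$drr$A, proj$drr$B,
                         pixelData(tA), pixelData(tB),
                         fix$bbA, fix$bbB, start = c(0L, 0L, 0L))
  exp_ <- projectOffset(pos)
  expect_equal(ptv@iA, round(exp_@iA / 1.25), tolerance = 1.01)
  expect_equal(ptv@iB, round(exp_@iB / 1.25), tolerance = 1.01)
  expect_equal(ptv@jAB, 0, tolerance = 1.01)
  # identical pairs give zero; empty box errors
  z <- ptvRegionSearch(proj$drr$A, proj$drr$B, proj$drr$A, proj$drr$B,
                       fix$bbA, fix$bbB)
  expect_equal(c(z@iA, z@iB, z@jAB), c(0, 0, 0))
  expect_error(ptvRegionSearch(proj$drr$A, proj$drr$B,
                               pixelData(tA), pixelData(tB),
                               list(rows = c(5, 4), cols = c(1, 2)),
                               fix$bbB), "empty")
})

test_that("registration vector assembly follows the fixed component order", {
  z <- assembleVector(matrix(0L, 25, 2), matrix(0L, 25, 2),
                      CoupledShift(0, 0, 0, unit = "pixels"))
  expect_equal(z@values, rep(0, 104))
  # only the PTV slots populated: exactly 4 non-zero components
  p <- assembleVector(matrix(0L, 25, 2), matrix(0L, 25, 2),
                      CoupledShift(2, 3, -1, unit = "pixels"),
                      pixelSpacing = 1)
  expect_equal(sum(p@values != 0), 4L)
  expect_equal(p@values[51:52], c(2, -1))    # image A PTV (I, J)
  expect_equal(p@values[103:104], c(3, -1))  # image B PTV (I, J)
  # unit conversion by pixel spacing
  u <- assembleVector(matrix(1L, 25, 2), matrix(1L, 25, 2),
                      CoupledShift(1, 1, 1, unit = "pixels"),
                      pixelSpacing = 0.5)
  expect_true(all(u@values == 0.5))
  expect_error(assembleVector(matrix(0L, 24, 2), matrix(0L, 25, 2),
                              CoupledShift(0, 0, 0, unit = "pixels")))
})

test_that("two-pass search equals single-pass exhaustive search on the lattice", {
  exhaustive <- function(dA, dB, tA, tB, range = 22L) {
    coupledSearch(dA, dB, tA, tB, passes = list(c(range, 1)))
  }
  set.seed(30)
  for (k in 1:5) {
    sh <- c(sample(seq(-20, 20, 4), 2, replace = TRUE),
            sample(seq(-20, 20, 4), 1))
    pA <- shiftedTexturePair(64, sh[1], sh[3], seed = 300 + k)
    pB <- shiftedTexturePair(64, sh[2], sh[3], seed = 400 + k)
    two <- coupledSearch(pA$drr, pB$drr, pA$trt, pB$trt)
    one <- exhaustive(pA$drr, pB$drr, pA$trt, pB$trt)
    expect_equal(c(two@iA, two@iB, two@jAB), sh)
    expect_equal(c(one@iA, one@iB, one@jAB), c(two@iA, two@iB, two@jAB))
  }
})

test_that("noise-free phantom pairs register to the projected ground truth", {
  fix <- testPhantomProjection()
  proj <- fix$proj; g <- fix$geometry
  set.seed(31)
  for (k in 1:3) {
    pos <- c(runif(1, -8, 8), runif(1, -8, 8), runif(1, -10, 10))
    tA <- renderTreatmentImage(proj, truePosition = pos)
    tB <- renderTreatmentImage(proj, truePosition = pos, view = "B")
    reg <- registerImagePair(Image2D(proj$drr$A, 1.25),
                             Image2D(proj$drr$B, 1.25),
                             pixelData(tA), pixelData(tB),
                             fix$bbA, fix$bbB, g)
    # back-projected PTV shift within one pixel-equivalent per axis
    expect_true(all(abs(reg$ptvPosition - pos) <= 1.25 + 1e-9))
  }
})

test_that("median registration error does not decrease with noise", {
  fix <- testPhantomProjection()
  proj <- fix$proj; g <- fix$geometry
  medianErr <- function(noise) {
    errs <- numeric(6)
    for (k in 1:6) {
      set.seed(500 + k)
      pos <- c(runif(1, -8, 8), runif(1, -8, 8), runif(1, -10, 10))
      tA <- renderTreatmentImage(proj, truePosition = pos,
                                 noiseLevel = noise,
                                 intensityPerturbation = 0, seed = k)
      tB <- renderTreatmentImage(proj, truePosition = pos,
                                 noiseLevel = noise,
                                 intensityPerturbation = 0, seed = k + 60,
                                 view = "B")
      reg <- registerImagePair(Image2D(proj$drr$A, 1.25),
                               Image2D(proj$drr$B, 1.25),
                               pixelData(tA), pixelData(tB),
                               fix$bbA, fix$bbB, g)
      errs[k] <- sqrt(sum((reg$ptvPosition - pos)^2))
    }
    median(errs)
  }
  e <- vapply(c(0, 0.1, 0.4), medianErr, numeric(1))
  expect_lte(e[1], e[2] + 1e-9)
  expect_lte(e[2], e[3] + 1e-9)
})
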