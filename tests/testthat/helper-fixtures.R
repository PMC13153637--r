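# Programmatic fixtures shared across the suite.

# Smooth random texture: iid noise blurred by repeated 3x3 box averaging,
# rescaled to approximately [0, 1]. Rich enough that shifted copies have a
# unique registration optimum.
textureImage <- function(n, seed = 1L, smoothPasses = 3L) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  for (p in seq_len(smoothPasses)) {
    padded <- rbind(m[1, ], m, m[n, ])
    padded <- cbind(padded[, 1], padded, padded[, n])
    m <- (padded[1:n, 1:n] + padded[1:n, 2:(n + 1)] + padded[1:n, 3:(n + 2)] +
          padded[2:(n + 1), 1:n] + padded[2:(n + 1), 2:(n + 1)] +
          padded[2:(n + 1), 3:(n + 2)] +
          padded[3:(n + 2), 1:n] + padded[3:(n + 2), 2:(n + 1)] +
          padded[3:(n + 2), 3:(n + 2)]) / 9
  }
  (m - min(m)) / (max(m) - min(m))
}

# A DRR/treatment pair of size n where the treatment content is the texture
# rigidly shifted by (I, J) pixels (rows move by J, columns by I), with no
# zero fill: both windows are cut from a larger texture.
shiftedTexturePair <- function(n, I, J, seed = 1L, pad = 30L) {
  big <- textureImage(n + 2L * pad, seed = seed)
  base <- big[(pad + 1):(pad + n), (pad + 1):(pad + n)]
  trt <- big[(pad + 1 - J):(pad + n - J), (pad + 1 - I):(pad + n - I)]
  list(drr = base, trt = trt)
}

# Small phantom + projections reused by rendering/registration tests.
testPhantomProjection <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- buildPhantom(phantomConfig(seed = 7L))
      g <- ImagingGeometry(128L, 1.25)
      cache <<- list(phantom = ph, geometry = g,
                     proj = projectPhantom(ph, g),
                     bbA = orthoTrack:::.maskBBox(ph$masks$PTV, g, "A"),
                     bbB = orthoTrack:::.maskBBox(ph$masks$PTV, g, "B"))
    }
    cache
  }
})

# Observations from a known affine map r = t([v; 1]) %*% C plus noise.
linearObservations <- function(n, C, sigma = 0, seed = 1L) {
  set.seed(seed)
  v <- matrix(runif(n * 104, -10, 10), n, 104)
  r <- cbind(v, 1) %*% C + matrix(rnorm(n * 3, 0, sigma), n, 3)
  list(v = v, r = r)
}

randomCoefMatrix <- function(seed = 1L, scale = 0.2) {
  set.seed(seed)
  matrix(rnorm(105 * 3, 0, scale), 105, 3)
}
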