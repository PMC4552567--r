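test_that("Gaussian noise has the requested sd, clips at zero, reproduces", {
  v <- voxelVolume(array(100, c(100, 100, 100)))
  n1 <- addGaussianNoise(v, 0.02, seed = 3)
  resid <- intensities(n1) - 100
  expect_equal(sd(resid), 2, tolerance = 0.02 * 2)
  expect_equal(mean(resid), 0, tolerance = 0.01)
  expect_identical(intensities(addGaussianNoise(v, 0.02, seed = 3)),
                   intensities(n1))
  expect_false(identical(intensities(addGaussianNoise(v, 0.02, seed = 4)),
                         intensities(n1)))
  # sigma 0 is the identity
  expect_identical(addGaussianNoise(v, 0), v)
  # clipping: a dim volume cannot go negative
  vd <- voxelVolume(array(0.01, c(20, 20, 20)))
  expect_gte(min(intensities(addGaussianNoise(vd, 0.5, seed = 1))), 0)
})

test_that("maxThreshold brackets the step where segments disappear", {
  # two-level network: bright trunk at 100 with faint child arms at 60;
  # above t = 60 only the trunk (with its rounded junction cap) remains
  ph <- layoutAndVoxelize(treeSpec(K = 1, r0 = 4, l0 = 24), voxel_mm = 1)
  arr <- intensities(ph$volume)
  d <- dim(arr)
  coords <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  mm <- sweep((coords - 1) * 1, 2, voxelOrigin(ph$volume), "+")
  ax <- ph$axes[1, ]  # trunk axis
  t_ <- pmin(1, pmax(0, ((mm[, 1] - ax[1]) * (ax[4] - ax[1]) +
                           (mm[, 2] - ax[2]) * (ax[5] - ax[2]) +
                           (mm[, 3] - ax[3]) * (ax[6] - ax[3])) /
                       sum((ax[4:6] - ax[1:3])^2)))
  q <- cbind(ax[1] + t_ * (ax[4] - ax[1]), ax[2] + t_ * (ax[5] - ax[2]),
             ax[3] + t_ * (ax[6] - ax[3]))
  inTrunk <- rowSums((mm - q)^2) <= ph$truth$radius_mm[1]^2
  faint <- arr[coords] > 50 & !inTrunk
  arr[coords[faint, , drop = FALSE]] <- 60
  v <- voxelVolume(arr)
  n_lo <- sum(segments(extractNetwork(v, 50))$well_segmented)
  n_hi <- tryCatch(sum(segments(extractNetwork(v, 60))$well_segmented),
                   error = function(e) 0L)
  expect_gt(n_lo, n_hi)
  tmax <- maxThreshold(v, 50, min_segments = n_lo)
  expect_gte(tmax, 50)
  expect_lt(tmax, 60)
  expect_error(maxThreshold(v, 50, min_segments = 1000), "sweep impossible")
})

test_that("threshold sweep is anchored at the baseline and spans [0, 1]", {
  ph <- softPhantom()
  sw <- thresholdSweep(ph$volume, 50, step = 0.25, min_segments = 20)
  steps <- unique(sw[, c("s", "threshold", "n_segments", "n_well")])
  expect_equal(steps$s, seq(0, 1, by = 0.25))
  expect_equal(steps$threshold[1], 50)
  # s = 0 reproduces the baseline extraction bit-for-bit
  base <- extractNetwork(ph$volume, 50)
  baseTab <- scalingExponentTable(base)
  s0 <- sw[sw$s == 0, c("method", "dimension", "N", "value")]
  rownames(s0) <- NULL
  expect_equal(s0, baseTab[, c("method", "dimension", "N", "value")])
  # segment counts are non-increasing in the threshold
  expect_false(is.unsorted(rev(steps$n_well)))
})

test_that("noise sweep at multiple 0 reproduces the clean run", {
  ph <- acceptancePhantom()
  ns <- noiseSweep(ph$volume, 50, multiples = c(0, 1), seed = 11)
  clean <- ns[ns$noise_multiple == 0, ]
  noisy <- ns[ns$noise_multiple == 1, ]
  base <- scalingExponentTable(acceptanceTree())
  expect_equal(clean$value, base$value)
  # determinism of the noisy branch
  ns2 <- noiseSweep(ph$volume, 50, multiples = 1, seed = 11)
  expect_equal(ns2$value, noisy$value)
})
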