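test_that("findRoot returns the deepest voxel, verified against brute force", {
  bv <- ballVolume(radius = 4)
  m <- makeNetworkMask(bv, 50)
  ctr <- (dim(intensities(bv)) + 1) / 2
  expect_equal(findRoot(m), as.integer(ctr))
  # brute-force EDT agreement on the ball
  dt <- angioscale:::maskEDT(m)
  bdt <- bruteEDT(maskArray(m))
  expect_equal(array(dt, dim(bdt)), bdt, tolerance = 1e-9)
  # single voxel mask
  g <- array(FALSE, c(3, 3, 3)); g[2, 2, 2] <- TRUE
  m1 <- largestComponent(g, 26)
  expect_equal(findRoot(m1), c(2L, 2L, 2L))
})

test_that("findRoot lands on the wide cylinder of a two-radius mask", {
  # radius-5 tube joined to a radius-2 tube along the same axis
  dims <- c(13, 13, 30)
  arr <- array(0, dims)
  coords <- as.matrix(expand.grid(1:13, 1:13, 1:30))
  lat2 <- (coords[, 1] - 7)^2 + (coords[, 2] - 7)^2
  wide <- lat2 <= 25 & coords[, 3] <= 15
  narrow <- lat2 <= 4 & coords[, 3] > 15
  arr[coords[wide | narrow, , drop = FALSE]] <- 100
  m <- makeNetworkMask(voxelVolume(arr), 50)
  root <- findRoot(m)
  expect_equal(root[1:2], c(7L, 7L))   # on the axis
  expect_lte(root[3], 15)              # inside the wide part
})

test_that("detectEndpoints finds tube tips, cross-checked by brute geodesic", {
  v <- tubeVolume(radius = 2, len = 14)
  m <- makeNetworkMask(v, 50)
  root <- findRoot(m)
  eps <- detectEndpoints(m, root, min_separation = 3)
  # root sits on the axis EDT plateau; at least the far tip must appear,
  # and every endpoint must lie near a tube end, close to the axis
  expect_gte(nrow(eps), 1)
  expect_lte(nrow(eps), 2)
  axis_ctr <- (dim(intensities(v))[1] + 1) / 2
  for (i in seq_len(nrow(eps))) {
    expect_lte(sqrt(sum((eps[i, 1:2] - axis_ctr)^2)), 1.5)
    expect_true(eps[i, 3] <= 5 || eps[i, 3] >= 15)
  }
  # endpoints are geodesic-far voxels: brute-force check
  gd <- bruteGeodesic(maskArray(m), root)
  for (i in seq_len(nrow(eps)))
    expect_gte(gd[eps[i, 1], eps[i, 2], eps[i, 3]], max(gd[is.finite(gd)]) - 3)
})

test_that("a Y-shaped tube yields one endpoint per arm", {
  ph <- layoutAndVoxelize(treeSpec(K = 1, r0 = 4, l0 = 24), voxel_mm = 1)
  m <- makeNetworkMask(ph$volume, 50)
  root <- findRoot(m)
  eps <- detectEndpoints(m, root, min_separation = 10)
  expect_equal(nrow(eps), 2)
})

test_that("a ball yields at most one endpoint under a wide suppression radius", {
  bv <- ballVolume(radius = 4)
  m <- makeNetworkMask(bv, 50)
  eps <- detectEndpoints(m, findRoot(m), min_separation = 12)
  expect_lte(nrow(eps), 1)
})

test_that("skeletonize reduces a solid bar to the 9-voxel axis path", {
  arr <- array(0, c(5, 5, 11)); arr[2:4, 2:4, 2:10] <- 100
  m <- makeNetworkMask(voxelVolume(arr), 50)
  sk <- skeletonize(m, rbind(c(3, 3, 2), c(3, 3, 10)))
  vox <- skeletonVoxels(sk)
  expect_equal(nrow(vox), 9)
  expect_true(all(vox[, 1] == 3 & vox[, 2] == 3))
  expect_setequal(vox[, 3], 2:10)
  paths <- classifyAndSplit(sk)
  expect_length(paths, 1)
  expect_equal(nrow(paths[[1]]), 9)
  expect_equal(sum(voxelLabels(sk) == "endpoint"), 2)
})

test_that("an L-shaped bar skeletonizes into two runs meeting at a corner", {
  arr <- array(0, c(12, 5, 12))
  arr[2:4, 2:4, 2:11] <- 100    # vertical leg
  arr[2:11, 2:4, 9:11] <- 100   # horizontal leg
  m <- makeNetworkMask(voxelVolume(arr), 50)
  sk <- skeletonize(m, rbind(c(3, 3, 2), c(11, 3, 10)))
  vox <- skeletonVoxels(sk)
  expect_equal(sum(voxelLabels(sk) == "endpoint"), 2)
  expect_equal(sum(voxelLabels(sk) == "branch"), 0)
  # both protected endpoints survive and stay connected
  expect_true(any(vox[, 1] == 3 & vox[, 2] == 3 & vox[, 3] == 2))
  expect_true(any(vox[, 1] == 11 & vox[, 2] == 3 & vox[, 3] == 10))
  expect_length(classifyAndSplit(sk), 1)
})

test_that("an already-thin path is its own skeleton", {
  arr <- array(0, c(3, 3, 9)); arr[2, 2, 2:8] <- 100
  m <- makeNetworkMask(voxelVolume(arr), 50)
  sk <- skeletonize(m, rbind(c(2, 2, 2), c(2, 2, 8)))
  expect_equal(nrow(skeletonVoxels(sk)), 7)
  # point-list debug export round-trips coordinates 0-based
  f <- tempfile(fileext = ".tsv")
  writeSkeletonPoints(sk, f)
  pts <- utils::read.delim(f)
  expect_equal(nrow(pts), 7)
  expect_setequal(pts$z, 1:7)
  expect_setequal(unique(pts$label), c("endpoint", "regular"))
})

test_that("disconnected endpoints are rejected before erosion", {
  g <- array(FALSE, c(9, 3, 3))
  g[1:3, 2, 2] <- TRUE; g[7:9, 2, 2] <- TRUE
  m <- largestComponent(g, 26)  # keeps only the first bar
  # endpoint outside the mask
  expect_error(skeletonize(m, rbind(c(1, 2, 2), c(9, 2, 2))), "inside")
})

test_that("skeletons of voxelized cylinders stay near the analytic axis", {
  for (r in c(2, 4)) {
    v <- tubeVolume(radius = r, len = 21)
    m <- makeNetworkMask(v, 50)
    ctr <- (dim(intensities(v))[1] + 1) / 2
    zr <- range(which(apply(intensities(v) > 50, 3, any)))
    sk <- skeletonize(m, rbind(c(ctr, ctr, zr[1]), c(ctr, ctr, zr[2])))
    vox <- skeletonVoxels(sk)
    offAxis <- sqrt((vox[, 1] - ctr)^2 + (vox[, 2] - ctr)^2)
    expect_lte(max(offAxis), 1.5)
    expect_lte(nrow(vox), sum(maskArray(m)))
  }
})

test_that("classifyAndSplit counts paths on Y and binary-tree skeletons", {
  # Y: three 5-voxel diagonal arms from one hub, drawn as a thin skeleton;
  # arm directions chosen so the first arm voxels are not 26-adjacent to
  # each other (otherwise the hub is a cluster, not a single branch voxel)
  g <- array(FALSE, c(13, 13, 13))
  hub <- c(7, 7, 7)
  dirs <- rbind(c(1, 1, 0), c(-1, 1, 0), c(0, -1, 1))
  tips <- list()
  g[hub[1], hub[2], hub[3]] <- TRUE
  for (k in 1:3) {
    for (i in 1:5) {
      v <- hub + i * dirs[k, ]
      g[v[1], v[2], v[3]] <- TRUE
    }
    tips[[k]] <- hub + 5 * dirs[k, ]
  }
  m <- largestComponent(g, 26)
  sk <- skeletonize(m, do.call(rbind, tips))
  expect_equal(sum(voxelLabels(sk) == "endpoint"), 3)
  expect_equal(sum(voxelLabels(sk) == "branch"), 1)
  paths <- classifyAndSplit(sk)
  expect_length(paths, 3)
  # every skeleton voxel belongs to at least one path
  covered <- unique(do.call(rbind, paths))
  expect_equal(nrow(covered), nrow(skeletonVoxels(sk)))
  # consecutive voxels are 26-neighbours and interiors are regular
  for (p in paths) {
    steps <- abs(diff(p))
    expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
  }
})
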