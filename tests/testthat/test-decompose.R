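test_that("assignVoxels attributes voxels to the nearest centerline", {
  # two parallel disjoint tubes
  arr <- array(0, c(15, 5, 10))
  arr[3, 3, 2:9] <- 100
  arr[12, 3, 2:9] <- 100
  arr[2:4, 2:4, 2:9] <- 100
  arr[11:13, 2:4, 2:9] <- 100
  g <- arr > 50
  m <- largestComponent(g, 26)  # connected? two blobs: keeps bigger/first
  # build a mask holding both tubes explicitly
  m@mask <- g
  paths <- list(cbind(3, 3, 2:9), cbind(12, 3, 2:9))
  asg <- assignVoxels(m, paths)
  left <- asg$maskVox[, 1] <= 7
  expect_true(all(asg$segment[left] == 1))
  expect_true(all(asg$segment[!left] == 2))
  expect_equal(length(asg$segment), sum(g))
  # single tube: everything goes to the only segment
  m2 <- largestComponent(array(arr[1:7, , ] > 50, c(7, 5, 10)), 26)
  asg2 <- assignVoxels(m2, paths[1])
  expect_true(all(asg2$segment == 1))
  # equidistant voxels break ties to the lower segment id
  g3 <- array(TRUE, c(3, 1, 1))
  m3 <- largestComponent(g3, 26)
  asg3 <- assignVoxels(m3, list(cbind(1, 1, 1), cbind(3, 1, 1)))
  expect_equal(asg3$segment[asg3$maskVox[, 1] == 2], 1L)
})

test_that("measureSegment inverts V = pi r^2 l and measures path length", {
  # analytic cylinder: V = 125.664 mm^3 over l = 10 mm inverts to r = 2 mm
  expect_equal(sqrt(125.664 / (pi * 10)), 2, tolerance = 1e-4)
  p11 <- cbind(2, 2, 1:11)   # 10 steps of 1 mm
  res <- measureSegment(126L, p11, c(1, 1, 1))
  expect_equal(res$length_mm, 10)
  expect_equal(res$volume_mm3, 126)
  expect_equal(res$radius_mm, sqrt(126 / (pi * 10)))
  # straight 9-voxel path at 0.8 mm spacing: 8 steps
  p9 <- cbind(3, 3, 1:9)
  res9 <- measureSegment(100, p9, c(0.8, 0.8, 0.8))
  expect_equal(res9$length_mm, 6.4)
  # diagonal steps use the Euclidean step length
  pd <- cbind(1:4, 1:4, 1:4)
  expect_equal(measureSegment(10, pd, c(1, 1, 1))$length_mm, 3 * sqrt(3))
  # single-voxel path degenerates to one voxel width
  expect_equal(measureSegment(5, cbind(2, 2, 2), c(0.9, 0.9, 0.9))$length_mm,
               0.9)
  expect_error(measureSegment(0, cbind(1, 1, 1), c(1, 1, 1)), "at least")
})

test_that("quality filter applies the 20% / (r+1) and 4-voxel rules", {
  expect_true(qualityFilter(0.0, 100L))
  expect_false(qualityFilter(0.0, 3L))       # volume rule
  expect_false(qualityFilter(0.25, 100L))    # circularity rule
  expect_true(qualityFilter(0.20, 4L))       # boundary values pass
  expect_equal(qualityFilter(c(0, 0.3), c(10L, 10L)), c(TRUE, FALSE))
})

test_that("far fractions match a brute-force recount on the Y phantom", {
  ph <- layoutAndVoxelize(treeSpec(K = 1, r0 = 4, l0 = 24), voxel_mm = 1)
  tr <- extractNetwork(ph$volume, 50)
  s <- segments(tr)
  m <- makeNetworkMask(ph$volume, 50)
  asg <- assignVoxels(m, s$centerline)
  w <- mean(spacing(m))
  for (i in seq_len(nrow(s))) {
    sel <- asg$segment == i
    rVox <- s$radius_mm[i] / w
    brute <- mean(asg$dist_mm[sel] / w > rVox + 1)
    expect_equal(s$far_fraction[i], brute)
    expect_equal(s$n_voxels[i], sum(sel))
  }
})

test_that("buildTree roots at max radius, orients edges and counts tips", {
  # full binary tree of depth 2 given as an explicit segment graph
  segdf <- data.frame(
    segment_id = 1:7,
    radius_mm = c(4, 2.8, 2.8, 2, 2, 2, 2),
    length_mm = c(10, 8, 8, 6, 6, 6, 6),
    volume_mm3 = NA, n_voxels = 100L, far_fraction = 0,
    well_segmented = TRUE,
    node_a = c("n0", "n1", "n1", "n2", "n2", "n3", "n3"),
    node_b = c("n1", "n2", "n3", "t1", "t2", "t3", "t4"))
  tree <- buildTree(segdf)
  s <- segments(tree)
  expect_equal(rootId(tree), 1L)
  expect_true(is.na(s$parent_id[s$segment_id == 1]))
  expect_equal(s$n_downstream_tips[order(s$segment_id)],
               c(4L, 2L, 2L, 1L, 1L, 1L, 1L))
  expect_false(any(s$in_loop))
  j <- junctions(tree)
  expect_equal(nrow(j), 3)
  expect_true(all(j$arity == 2))
  expect_true(all(j$all_children_smaller_radius))
})

test_that("cycles are flagged in_loop and excluded from junction records", {
  # triangle of segments plus one pendant: A(n1-n2), B(n2-n3), C(n3-n1),
  # D(n3-t1); A has the greatest radius
  segdf <- data.frame(
    segment_id = 1:4, radius_mm = c(5, 3, 3, 2),
    length_mm = c(10, 9, 9, 5), volume_mm3 = NA, n_voxels = 50L,
    far_fraction = 0, well_segmented = TRUE,
    node_a = c("n1", "n2", "n3", "n3"),
    node_b = c("n2", "n3", "n1", "t1"))
  tree <- buildTree(segdf)
  s <- segments(tree)
  expect_equal(sort(s$segment_id[s$in_loop]), 1:3)
  expect_false(s$in_loop[s$segment_id == 4])
  expect_equal(nrow(junctions(tree)), 0)
  # multiple components are an error
  bad <- segdf
  bad$node_a <- c("n1", "n2", "x1", "x1")
  bad$node_b <- c("n2", "n1", "x2", "x3")
  expect_error(buildTree(bad), "components")
})

test_that("junction records carry strict smaller-than-parent flags", {
  # root(5) -> A(4) -> {B(4.2), C(2)}: B exceeds its parent A even though
  # the tree roots correctly at the widest segment
  segdf <- data.frame(
    segment_id = 1:5, radius_mm = c(5, 4, 4.2, 2, 3),
    length_mm = c(12, 6, 9, 5, 7), volume_mm3 = NA, n_voxels = 50L,
    far_fraction = 0, well_segmented = TRUE,
    node_a = c("n0", "n1", "n2", "n2", "n1"),
    node_b = c("n1", "n2", "t1", "t2", "t3"))
  tree <- buildTree(segdf)
  expect_equal(rootId(tree), 1L)
  j <- junctions(tree)
  expect_equal(nrow(j), 2)
  jA <- j[j$parent_id == 2, ]
  expect_false(jA$all_children_smaller_radius)  # 4.2 > 4
  expect_false(jA$all_children_smaller_length)  # 9 > 6
  jroot <- j[j$parent_id == 1, ]
  expect_true(jroot$all_children_smaller_radius)
  expect_true(jroot$all_children_smaller_length)
  # equality does not count as smaller (strict inequality)
  segdf$radius_mm <- c(5, 4, 4, 2, 3)
  j2 <- junctions(buildTree(segdf))
  expect_false(j2$all_children_smaller_radius[j2$parent_id == 2])
})

test_that("phantom decomposition partitions the mask exactly", {
  ph <- acceptancePhantom()
  tr <- acceptanceTree()
  s <- segments(tr)
  mask <- maskArray(makeNetworkMask(ph$volume, 50))
  expect_equal(sum(s$n_voxels), sum(mask))
  # r-V-l consistency for every segment
  expect_equal(s$radius_mm^2 * pi * s$length_mm, s$volume_mm3,
               tolerance = 1e-9)
})

test_that("Y-network extraction yields one arity-2 junction", {
  ph <- layoutAndVoxelize(treeSpec(K = 1, r0 = 4, l0 = 24), voxel_mm = 1)
  tr <- extractNetwork(ph$volume, 50)
  j <- junctions(tr)
  expect_equal(nrow(j), 1)
  expect_equal(j$arity, 2)
  expect_equal(nrow(segments(tr)), 3)
})
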