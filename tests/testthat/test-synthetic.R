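test_that("ideal tables follow the self-similar level formulas", {
  tab <- makeIdealTable(treeSpec(K = 3, r0 = 1, l0 = 2, a = 0.5, b = 1 / 3))
  expect_equal(nrow(tab), 15)  # 2^(K+1) - 1
  lvl <- tab$level
  expect_equal(sort(unique(round(tab$radius_mm, 5))),
               sort(round(c(1, 2^-0.5, 0.5, 2^-1.5), 5)))
  expect_equal(tab$radius_mm, 1 * 2^(-0.5 * lvl))
  expect_equal(tab$length_mm, 2 * 2^(-lvl / 3))
  expect_equal(tab$n_downstream_tips, as.integer(2^(3 - lvl)))
  # parents sit one level up
  par <- match(tab$parent_id, tab$segment_id)
  expect_true(all(lvl[par[-1]] == lvl[-1] - 1))
  # determinism under jitter
  s1 <- makeIdealTable(treeSpec(K = 3, noise_sd = 0.1, seed = 5))
  s2 <- makeIdealTable(treeSpec(K = 3, noise_sd = 0.1, seed = 5))
  expect_identical(s1, s2)
  s3 <- makeIdealTable(treeSpec(K = 3, noise_sd = 0.1, seed = 6))
  expect_false(identical(s1$radius_mm, s3$radius_mm))
})

test_that("asymmetric specs apply distinct child radius ratios", {
  tab <- makeIdealTable(treeSpec(K = 2, r0 = 1, asymmetry = c(0.8, 0.5)))
  lvl1 <- tab$radius_mm[tab$level == 1]
  expect_setequal(round(lvl1, 9), c(0.8, 0.5))
  lvl2 <- sort(unique(round(tab$radius_mm[tab$level == 2], 9)))
  expect_equal(lvl2, sort(unique(round(c(0.64, 0.4, 0.4, 0.25), 9))))
})

test_that("a single voxelized cylinder matches its analytic volume", {
  ph <- layoutAndVoxelize(treeSpec(K = 0, r0 = 3, l0 = 20), voxel_mm = 1)
  count <- sum(intensities(ph$volume) > 50)
  expect_lt(abs(count - pi * 9 * 20) / (pi * 9 * 20), 0.10)
  expect_equal(nrow(ph$truth), 1)
  expect_equal(ph$truth$radius_mm, 3)
})

test_that("the K=1 phantom is connected and yields two tips downstream", {
  ph <- layoutAndVoxelize(treeSpec(K = 1, r0 = 4, l0 = 24), voxel_mm = 1)
  g <- intensities(ph$volume) > 50
  m <- largestComponent(g, 26)
  expect_equal(sum(maskArray(m)), sum(g))  # single connected component
  tr <- extractNetwork(ph$volume, 50)
  expect_equal(sum(segments(tr)$n_downstream_tips == 1), 2)
  # two-level image: mask equals the rasterized tubes exactly at t = 50
  expect_identical(maskArray(m), g)
})

test_that("phantom truth satisfies the generating power laws", {
  ph <- acceptancePhantom()
  truth <- ph$truth
  lvl <- round(log2(truth$n_downstream_tips[1] / truth$n_downstream_tips))
  expect_equal(truth$radius_mm, 12 * 2^(-0.5 * lvl), tolerance = 1e-12)
  expect_equal(truth$length_mm, 40 * 2^(-lvl / 3), tolerance = 1e-12)
  expect_equal(nrow(ph$axes), nrow(truth))
  # children start where the parent ends
  par <- match(truth$parent_id, truth$segment_id)
  for (i in which(!is.na(par)))
    expect_equal(unname(ph$axes[i, 1:3]), unname(ph$axes[par[i], 4:6]))
})

test_that("overlapping layouts are rejected with advice", {
  expect_error(layoutAndVoxelize(treeSpec(K = 6, r0 = 8, l0 = 12),
                                 voxel_mm = 1), "overlap")
  expect_error(layoutAndVoxelize(treeSpec(K = 1, r0 = 1, l0 = 10),
                                 voxel_mm = 1), "resolvable")
})

test_that("perturbTable is the identity at sigma 0 and symmetric in logs", {
  tab <- makeIdealTable(treeSpec(K = 10))
  expect_identical(perturbTable(tab, 0, 0, seed = 1), tab)
  pert <- perturbTable(tab, sigma_r = 0.2, sigma_l = 0.1, seed = 2)
  expect_identical(pert$parent_id, tab$parent_id)
  lr <- log(pert$radius_mm / tab$radius_mm)
  expect_equal(mean(lr), 0, tolerance = 3 * 0.2 / sqrt(nrow(tab)))
  expect_equal(sd(lr), 0.2, tolerance = 0.02)
  # volumes stay consistent with r and l
  expect_equal(pert$volume_mm3, pi * pert$radius_mm^2 * pert$length_mm)
  # determinism
  expect_identical(pert, perturbTable(tab, 0.2, 0.1, seed = 2))
})
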