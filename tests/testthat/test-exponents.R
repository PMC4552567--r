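test_that("conservation solver matches closed forms and the bisection oracle", {
  expect_equal(solveConservationExponent(2, c(1, 1)), 1, tolerance = 1e-9)
  expect_equal(solveConservationExponent(1, c(2^-0.5, 2^-0.5)), 0.5,
               tolerance = 1e-9)
  # frozen value from the bisection oracle on f(x) = .9^(1/x)+.8^(1/x)-1
  expect_equal(solveConservationExponent(1, c(0.9, 0.8)), 0.2260197,
               tolerance = 1e-6)
  expect_true(is.na(solveConservationExponent(1, c(1.1, 0.5))))
  expect_true(is.na(solveConservationExponent(1, c(1.0, 0.5))))  # strict
  expect_error(solveConservationExponent(-1, c(0.5, 0.5)), "positive")
  expect_error(solveConservationExponent(1, c(0.5, -0.5)), "positive")
  expect_error(solveConservationExponent(1, 0.5), "children")
})

test_that("solver residuals stay within 1e-5 and roots agree with bisection", {
  set.seed(42)
  for (i in 1:200) {
    nch <- sample(2:3, 1)
    parent <- runif(1, 0.5, 10)
    children <- parent * runif(nch, 0.05, 0.999)
    x <- solveConservationExponent(parent, children)
    expect_false(is.na(x))
    expect_lte(abs(sum((children / parent)^(1 / x)) - 1), 1e-5)
    expect_equal(x, bisectConservation(parent, children), tolerance = 1e-6)
  }
})

test_that("conservation estimate averages defined junctions only", {
  j <- data.frame(parent_id = 1:3, arity = 2,
                  r_parent = c(1, 1, 1), l_parent = c(1, 1, 1))
  # exponents 0.4 and 0.6 by construction; third junction undefined
  j$r_children <- list(rep(2^-0.4, 2), rep(2^-0.6, 2), c(1.2, 0.4))
  j$l_children <- list(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))
  e <- conservationEstimate(j, "radius")
  expect_equal(e@n, 2L)
  expect_equal(e@value, 0.5, tolerance = 1e-6)
  expect_equal(e@sigma, sd(c(0.4, 0.6)), tolerance = 1e-6)
  expect_equal(e@ciHigh - e@value, 1.96 * e@sigma / sqrt(2), tolerance = 1e-6)
  # fewer than 2 defined junctions is an error
  expect_error(conservationEstimate(j[3, ], "radius"), "insufficient")
})

test_that("ratio estimates convert scale factors to exponents", {
  pairs <- data.frame(subject_id = "s", parent_id = 1,
                      segment_id = 1:4,
                      beta = c(0.5, 0.5, 2^-0.5, 2^-0.5),
                      gamma = c(1, 1, 1, 1))
  e <- ratioEstimate(pairs, "radius")
  expect_equal(e@value, mean(c(1, 1, 0.5, 0.5)))
  expect_equal(e@n, 4L)
  eb <- ratioEstimate(pairs, "length")
  expect_equal(eb@value, 0)  # children as long as parents
  pairs$beta[1] <- -0.1
  expect_error(ratioEstimate(pairs, "radius"), "positive")
})

test_that("scaleFactorPairs uses dichotomous junctions with quality filters", {
  tab <- makeIdealTable(treeSpec(K = 2, r0 = 4, l0 = 10, a = 0.5, b = 1 / 3))
  p <- scaleFactorPairs(tab)
  expect_equal(nrow(p), 6)  # 3 junctions x 2 children
  expect_equal(unique(round(p$beta, 6)), round(2^-0.5, 6))
  # a non-well-segmented leaf drops its own pair only
  tab2 <- tab
  leaf <- max(tab2$segment_id)
  tab2$well_segmented[tab2$segment_id == leaf] <- FALSE
  expect_equal(nrow(scaleFactorPairs(tab2)), 5)
  # a trichotomous junction contributes no pairs
  tab3 <- rbind(tab, within(tab[tab$segment_id == 2, ],
                            segment_id <- 99L))
  tab3$parent_id[tab3$segment_id == 99] <- 1L
  expect_equal(nrow(scaleFactorPairs(tab3)), 4)
})

test_that("SMA fit matches closed forms, involution and sign symmetry", {
  f <- smaFit(0:4, 2 * (0:4) + 1)
  expect_equal(f@slope, 2)
  expect_equal(f@intercept, 1)
  expect_equal(f@rSquared, 1)
  expect_equal(f@ciLow, f@ciHigh, tolerance = 1e-6)
  # frozen closed form: slope = sd(y)/sd(x) = sqrt(7/3)
  f2 <- smaFit(c(0, 1, 2), c(0, 2, 3))
  expect_equal(f2@slope, sqrt(7 / 3), tolerance = 1e-9)
  expect_equal(f2@intercept, 5 / 3 - sqrt(7 / 3), tolerance = 1e-9)
  # y -> -y negates the slope, leaves r^2
  f3 <- smaFit(c(0, 1, 2), -c(0, 2, 3))
  expect_equal(f3@slope, -f2@slope)
  expect_equal(f3@rSquared, f2@rSquared)
  # involution and scale equivariance over random data
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(30); y <- 0.6 * x + rnorm(30, sd = 0.4)
    a <- smaFit(x, y); b <- smaFit(y, x)
    expect_equal(a@slope * b@slope, 1, tolerance = 1e-9)
    expect_equal(smaFit(x, 3.5 * y)@slope, 3.5 * a@slope, tolerance = 1e-9)
  }
  expect_error(smaFit(rep(1, 5), rnorm(5)), "variance")
  expect_error(smaFit(1:2, 2:3), "3 points")
})

test_that("distribution estimator recovers the ideal-tree exponent", {
  tab <- expectedIdealTable()
  vals <- rep(tab$radius_mm, 1)
  e <- distributionEstimate(vals, "radius")
  expect_equal(e@value, 0.5, tolerance = 0.05)
  expect_gte(e@n, 30)
  expect_true(is.finite(e@rSquared))
  # scaling all values leaves the exponent unchanged
  e2 <- distributionEstimate(vals * 3.7, "radius")
  expect_equal(e2@value, e@value, tolerance = 1e-9)
  expect_error(distributionEstimate(rep(2, 100), "radius"), "identical")
  expect_error(distributionEstimate(runif(20), "radius", n_bins = 5,
                                    n_discard = 4), "exceed")
})

test_that("regression estimator reads exact power laws off the table", {
  nd <- c(1, 1, 2, 4, 8, 16, 32)
  tab <- data.frame(subject_id = "s", segment_id = seq_along(nd),
                    parent_id = NA, length_mm = nd^(1 / 3),
                    radius_mm = nd^0.41, n_downstream_tips = nd,
                    well_segmented = TRUE, in_loop = FALSE)
  e <- regressionEstimate(tab, "radius")
  expect_equal(e@value, 0.41, tolerance = 1e-9)
  expect_equal(e@rSquared, 1, tolerance = 1e-12)
  eb <- regressionEstimate(tab, "length")
  expect_equal(eb@value, 1 / 3, tolerance = 1e-9)
  # permuting rows changes nothing
  e2 <- regressionEstimate(tab[sample(nrow(tab)), ], "radius")
  expect_equal(e2@value, e@value)
  tab$n_downstream_tips <- 4
  expect_error(regressionEstimate(tab, "radius"), "degenerate|same")
})

test_that("Welch comparison matches the closed form and is symmetric", {
  mk <- function(v, sigma, n) new("ExponentEstimate", method = "ratio",
                                  dimension = "radius", value = v,
                                  ciLow = NA_real_, ciHigh = NA_real_,
                                  n = as.integer(n), sigma = sigma,
                                  rSquared = NA_real_)
  e1 <- mk(0, 0.1 * sqrt(50), 50)   # SE = 0.1
  e2 <- mk(1, 0.1 * sqrt(50), 50)
  w <- welchCompare(e1, e2)
  expect_equal(w$t, -1 / sqrt(0.02), tolerance = 1e-9)  # about -7.07
  expect_equal(w$df, 98, tolerance = 1e-6)
  w2 <- welchCompare(e2, e1)
  expect_equal(w2$p, w$p)
  expect_equal(w2$t, -w$t)
  expect_equal(welchCompare(e1, e1)$p, 1)
})

test_that("ratio and conservation agree exactly on symmetric junctions", {
  set.seed(99)
  for (i in 1:25) {
    a <- runif(1, 0.2, 2)
    parent <- runif(1, 1, 10)
    child <- parent * 2^-a
    x <- solveConservationExponent(parent, c(child, child))
    expect_equal(x, -log2(child / parent), tolerance = 1e-9)
  }
})

test_that("estimator means are unbiased under lognormal jitter", {
  tab <- makeIdealTable(treeSpec(K = 12, r0 = 10, l0 = 10, a = 0.5,
                                 b = 1 / 3))
  pert <- perturbTable(tab, sigma_r = 0.1, sigma_l = 0, seed = 4)
  e <- ratioEstimate(pert, "radius")
  expect_gt(e@n, 4000)
  expect_equal(e@value, 0.5, tolerance = 0.02)
})
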