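#' Specification of a synthetic self-similar vessel tree
#'
#' Defines the ground-truth branching geometry used by both generator
#' levels: the per-level dimensions follow \code{r_k = r0 * n^(-a k)} and
#' \code{l_k = l0 * n^(-b k)} for branching level k = 0..K, i.e. scale
#' factors \code{beta = n^-a}, \code{gamma = n^-b} per junction. Optional
#' multiplicative lognormal jitter emulates biological variation around
#' strict self-similarity.
#'
#' @param n branching factor (>= 2; the voxelized layout supports n = 2).
#' @param K number of branching generations (levels 0..K).
#' @param r0,l0 root radius and length in mm.
#' @param a,b radius and length scaling exponents.
#' @param asymmetry optional numeric(2) of distinct child radius ratios
#'   (beta1, beta2) replacing the symmetric \code{n^-a}; lengths stay
#'   symmetric.
#' @param noise_sd standard deviation of lognormal jitter applied
#'   multiplicatively to every radius and length (0 = strict
#'   self-similarity).
#' @param seed RNG seed making the jitter reproducible.
#' @return list of validated parameters (class \code{treeSpec}).
#' @export
treeSpec <- function(n = 2L, K = 4L, r0 = 12, l0 = 40, a = 0.5, b = 1 / 3,
                     asymmetry = NULL, noise_sd = 0, seed = 1L) {
  n <- as.integer(n); K <- as.integer(K)
  stopifnot(n >= 2L, K >= 0L, r0 > 0, l0 > 0, a > 0, b > 0, noise_sd >= 0)
  if (!is.null(asymmetry)) {
    stopifnot(length(asymmetry) == 2L, all(asymmetry > 0),
              asymmetry[1] != asymmetry[2])
  }
  structure(list(n = n, K = K, r0 = r0, l0 = l0, a = a, b = b,
                 asymmetry = asymmetry, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "treeSpec")
}

#' Ideal self-similar segment table
#'
#' Generates the segment table of a full n-ary tree with \code{n^k}
#' segments at level k: radii \code{r0 * n^(-a k)}, lengths
#' \code{l0 * n^(-b k)} (times jitter when \code{noise_sd > 0}), downstream
#' tip counts \code{n^(K-k)}, all segments well-segmented. This is the
#' ground truth on which all four exponent estimators provably coincide.
#'
#' @param spec a \code{\link{treeSpec}}.
#' @return segment table data.frame.
#' @examples
#' tab <- makeIdealTable(treeSpec(K = 3, r0 = 1))
#' unique(signif(tab$radius_mm, 5))   # 1, 0.70711, 0.5, 0.35355
#' @export
makeIdealTable <- function(spec) {
  stopifnot(inherits(spec, "treeSpec"))
  n <- spec$n; K <- spec$K
  total <- sum(n^(0:K))
  level <- integer(total)
  parent <- rep(NA_integer_, total)
  id <- seq_len(total)
  # breadth-first ids: level k occupies (n^k - 1)/(n - 1) + 1 .. + n^k
  offs <- cumsum(c(0, n^(0:K)))
  for (k in seq_len(K)) {
    idx <- (offs[k + 1] + 1):(offs[k + 2])
    level[idx] <- k
    parent[idx] <- offs[k] + ((seq_along(idx) - 1L) %/% n) + 1L
  }
  if (is.null(spec$asymmetry)) {
    radius <- spec$r0 * spec$n^(-spec$a * level)
  } else {
    radius <- numeric(total)
    radius[1] <- spec$r0
    childPos <- integer(total)
    for (k in seq_len(K)) {
      idx <- (offs[k + 1] + 1):(offs[k + 2])
      pos <- ((seq_along(idx) - 1L) %% n) + 1L
      ratio <- ifelse(pos == 1L, spec$asymmetry[1], spec$asymmetry[2])
      radius[idx] <- radius[parent[idx]] * ratio
    }
  }
  len <- spec$l0 * spec$n^(-spec$b * level)
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    radius <- radius * exp(stats::rnorm(total, 0, spec$noise_sd))
    len <- len * exp(stats::rnorm(total, 0, spec$noise_sd))
  }
  data.frame(subject_id = "ideal", segment_id = id, parent_id = parent,
             length_mm = len, volume_mm3 = pi * radius^2 * len,
             radius_mm = radius,
             n_downstream_tips = as.integer(n^(K - level)),
             well_segmented = TRUE, in_loop = FALSE, level = level)
}

rotateInPlane <- function(d, u, theta) {
  # rotate d towards u by theta (both unit, orthogonal)
  cos(theta) * d + sin(theta) * u
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# minimum distance between two 3D line segments (p1-p2, q1-q2)
segmentDistance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  EPS <- 1e-12
  if (a <= EPS && e <= EPS) return(sqrt(sum(r * r)))
  if (a <= EPS) {
    t <- min(1, max(0, f / e))
    return(sqrt(sum((p1 - (q1 + t * d2))^2)))
  }
  cc <- sum(d1 * r)
  if (e <= EPS) {
    s <- min(1, max(0, -cc / a))
    return(sqrt(sum((p1 + s * d1 - q1)^2)))
  }
  b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > EPS) min(1, max(0, (b * f - cc * e) / denom)) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- min(1, max(0, -cc / a)) }
  else if (t > 1) { t <- 1; s <- min(1, max(0, (b - cc) / a)) }
  sqrt(sum((p1 + s * d1 - (q1 + t * d2))^2))
}

#' Voxelized tube-tree phantom with ground truth
#'
#' Lays the tree of \code{\link{treeSpec}} out as straight tubes in 3D —
#' children leave the parent tip at \code{+/- half_angle} within branching
#' planes that rotate 90 degrees each generation (an H-tree-like space
#' filling arrangement) — verifies that no two non-adjacent tubes overlap,
#' and rasterizes the capsules (cylinders with spherical caps) onto a voxel
#' grid: lumen voxels get \code{intensity}, the rest \code{background}.
#'
#' @param spec a \code{\link{treeSpec}} with n = 2; \code{r0} must be at
#'   least 2 voxels so the smallest tubes stay resolvable.
#' @param voxel_mm isotropic voxel size (mm).
#' @param intensity,background two-level image intensities.
#' @param half_angle branching half-angle in degrees (default 40).
#' @param supersample if TRUE, 3x3x3 subvoxel sampling produces
#'   partial-volume intensities at the lumen boundary (MRI-like softness);
#'   default FALSE for exact two-level images.
#' @return list with \code{volume} (a \linkS4class{VoxelVolume}),
#'   \code{truth} (the exact generating segment table) and \code{axes}
#'   (per-segment axis endpoints in mm, columns x0..z1).
#' @export
layoutAndVoxelize <- function(spec, voxel_mm = 1, intensity = 100,
                              background = 0, half_angle = 40,
                              supersample = FALSE) {
  stopifnot(inherits(spec, "treeSpec"))
  if (spec$n != 2L)
    stop("the voxelized layout supports dichotomous branching (n = 2)")
  if (spec$r0 < 2 * voxel_mm)
    stop("root radius must be at least 2 voxels to be resolvable")
  truth <- makeIdealTable(spec)
  nseg <- nrow(truth)
  theta <- half_angle * pi / 180
  start <- matrix(NA_real_, nseg, 3)
  end <- matrix(NA_real_, nseg, 3)
  dirs <- matrix(NA_real_, nseg, 3)
  us <- matrix(NA_real_, nseg, 3)
  start[1, ] <- c(0, 0, 0)
  dirs[1, ] <- c(0, 0, 1)
  us[1, ] <- c(1, 0, 0)
  end[1, ] <- start[1, ] + truth$length_mm[1] * dirs[1, ]
  for (i in seq_len(nseg)[-1]) {
    p <- truth$parent_id[i]
    sib <- which(truth$parent_id == p)
    sgn <- if (match(i, sib) == 1L) 1 else -1
    d <- rotateInPlane(dirs[p, ], us[p, ], sgn * theta)
    d <- d / sqrt(sum(d^2))
    start[i, ] <- end[p, ]
    end[i, ] <- start[i, ] + truth$length_mm[i] * d
    dirs[i, ] <- d
    u <- cross3(dirs[p, ], us[p, ])
    us[i, ] <- u / sqrt(sum(u^2))
  }
  # overlap check between non-adjacent tubes (junction balls exempt)
  adjacent <- function(i, j) {
    pi_ <- truth$parent_id[i]; pj <- truth$parent_id[j]
    (!is.na(pi_) && pi_ == j) || (!is.na(pj) && pj == i) ||
      (!is.na(pi_) && !is.na(pj) && pi_ == pj)
  }
  for (i in seq_len(nseg - 1)) {
    for (j in (i + 1):nseg) {
      if (adjacent(i, j)) next
      dd <- segmentDistance(start[i, ], end[i, ], start[j, ], end[j, ])
      if (dd <= truth$radius_mm[i] + truth$radius_mm[j] + voxel_mm)
        stop("layout produced overlapping tubes (segments ", i, " and ", j,
             "); reduce K or the branching half-angle")
    }
  }
  pad <- max(truth$radius_mm) + 2 * voxel_mm
  lo <- pmin(apply(start, 2, min), apply(end, 2, min)) - pad
  hi <- pmax(apply(start, 2, max), apply(end, 2, max)) + pad
  dims <- as.integer(ceiling((hi - lo) / voxel_mm)) + 1L
  arr <- array(background, dims)
  sub <- if (supersample) {
    g <- (seq_len(3) - 2) / 3 * voxel_mm
    as.matrix(expand.grid(g, g, g))
  } else matrix(0, 1, 3)
  hasChildren <- truth$segment_id %in% truth$parent_id
  for (i in seq_len(nseg)) {
    r <- truth$radius_mm[i]
    # round caps only where tubes meet (junction balls); terminal ends —
    # the root inlet and the leaf tips — are cut flat so a lone tube is a
    # true cylinder
    roundStart <- !is.na(truth$parent_id[i])
    roundEnd <- hasChildren[i]
    blo <- pmax(1L, as.integer(floor((pmin(start[i, ], end[i, ]) - r -
                                        voxel_mm - lo) / voxel_mm)) + 1L)
    bhi <- pmin(dims, as.integer(ceiling((pmax(start[i, ], end[i, ]) + r +
                                            voxel_mm - lo) / voxel_mm)) + 1L)
    gx <- blo[1]:bhi[1]; gy <- blo[2]:bhi[2]; gz <- blo[3]:bhi[3]
    ctr <- expand.grid(x = lo[1] + (gx - 1) * voxel_mm,
                       y = lo[2] + (gy - 1) * voxel_mm,
                       z = lo[3] + (gz - 1) * voxel_mm)
    frac <- 0
    for (ss in seq_len(nrow(sub))) {
      px <- ctr$x + sub[ss, 1]; py <- ctr$y + sub[ss, 2]
      pz <- ctr$z + sub[ss, 3]
      dx <- end[i, 1] - start[i, 1]; dy <- end[i, 2] - start[i, 2]
      dz <- end[i, 3] - start[i, 3]
      L2 <- dx^2 + dy^2 + dz^2
      t <- ((px - start[i, 1]) * dx + (py - start[i, 2]) * dy +
              (pz - start[i, 3]) * dz) / L2
      tc <- pmin(1, pmax(0, t))
      qx <- start[i, 1] + tc * dx; qy <- start[i, 2] + tc * dy
      qz <- start[i, 3] + tc * dz
      d2 <- (px - qx)^2 + (py - qy)^2 + (pz - qz)^2
      inside <- d2 <= r^2 & (t >= 0 | roundStart) & (t <= 1 | roundEnd)
      frac <- frac + inside
    }
    frac <- frac / nrow(sub)
    sel <- which(frac > 0)
    if (length(sel)) {
      coords <- as.matrix(expand.grid(gx, gy, gz))[sel, , drop = FALSE]
      idx <- vox2idx(coords, dims)
      val <- background + frac[sel] * (intensity - background)
      arr[idx] <- pmax(arr[idx], val)
    }
  }
  axes <- cbind(start, end)
  colnames(axes) <- c("x0", "y0", "z0", "x1", "y1", "z1")
  truth$level <- NULL
  list(volume = voxelVolume(arr, spacing = rep(voxel_mm, 3), origin = lo),
       truth = truth, axes = axes)
}

#' Perturb a segment table with multiplicative lognormal noise
#'
#' Multiplies every radius and length by independent lognormal(0, sigma)
#' factors (volumes are recomputed so r = sqrt(V / (pi l)) keeps holding);
#' topology is untouched. Useful for bias/variance studies of the exponent
#' estimators.
#'
#' @param tab segment table.
#' @param sigma_r,sigma_l lognormal standard deviations (log scale).
#' @param seed RNG seed.
#' @return perturbed copy of \code{tab}.
#' @export
perturbTable <- function(tab, sigma_r = 0, sigma_l = 0, seed = 1L) {
  stopifnot(sigma_r >= 0, sigma_l >= 0)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- nrow(tab)
  if (sigma_r > 0) tab$radius_mm <- tab$radius_mm * exp(stats::rnorm(n, 0, sigma_r))
  if (sigma_l > 0) tab$length_mm <- tab$length_mm * exp(stats::rnorm(n, 0, sigma_l))
  if (!is.null(tab$volume_mm3))
    tab$volume_mm3 <- pi * tab$radius_mm^2 * tab$length_mm
  tab
}
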