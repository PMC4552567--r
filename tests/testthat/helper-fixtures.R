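# Shared fixtures and independent oracles. Heavy phantoms are built once
# per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# the acceptance phantom: symmetric binary tree, 4 generations, leaf radii
# 3 voxels (r0 = 12 * 2^-2), two-level intensities 0/100
acceptancePhantom <- function() {
  cachedFixture("phantomK4", function() {
    layoutAndVoxelize(treeSpec(K = 4, r0 = 12, l0 = 40, a = 0.5, b = 1 / 3),
                      voxel_mm = 1, intensity = 100, background = 0)
  })
}

acceptanceTree <- function() {
  cachedFixture("treeK4", function() {
    extractNetwork(acceptancePhantom()$volume, threshold = 50)
  })
}

# supersampled variant: partial-volume boundary intensities
softPhantom <- function() {
  cachedFixture("phantomK4soft", function() {
    layoutAndVoxelize(treeSpec(K = 4, r0 = 12, l0 = 40, a = 0.5, b = 1 / 3),
                      voxel_mm = 1, intensity = 100, background = 0,
                      supersample = TRUE)
  })
}

# solid axis-aligned tube mask in a small volume, intensities 0/100
tubeVolume <- function(radius = 3, len = 20, pad = 3, axis = 3) {
  n_ax <- len + 2 * pad
  n_tr <- 2 * (radius + pad) + 1
  dims <- rep(n_tr, 3)
  dims[axis] <- n_ax
  arr <- array(0, dims)
  ctr <- (n_tr + 1) / 2
  coords <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                  seq_len(dims[3])))
  tr <- setdiff(1:3, axis)
  lat2 <- (coords[, tr[1]] - ctr)^2 + (coords[, tr[2]] - ctr)^2
  inside <- lat2 <= radius^2 & coords[, axis] > pad &
    coords[, axis] <= pad + len
  arr[coords[inside, , drop = FALSE]] <- 100
  voxelVolume(arr)
}

ballVolume <- function(radius = 5, pad = 2) {
  n <- 2 * (radius + pad) + 1
  arr <- array(0, c(n, n, n))
  ctr <- radius + pad + 1
  coords <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  inside <- rowSums((coords - ctr)^2) <= radius^2
  arr[coords[inside, , drop = FALSE]] <- 100
  voxelVolume(arr)
}

# independent bisection oracle for the conservation law
bisectConservation <- function(parent, children, lo = 1e-6, hi = 50,
                               tol = 1e-12) {
  f <- function(x) sum((children / parent)^(1 / x)) - 1
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

# brute-force geodesic distances on a small mask (BFS over 26-neighbours
# with Euclidean step weights), independent of the compiled path
bruteGeodesic <- function(mask, from) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  wts <- sqrt(rowSums(offs^2))
  dist <- array(Inf, d)
  dist[from[1], from[2], from[3]] <- 0
  active <- matrix(from, 1)
  while (nrow(active)) {
    nxt <- list()
    for (i in seq_len(nrow(active))) {
      v <- active[i, ]
      dv <- dist[v[1], v[2], v[3]]
      for (k in seq_len(nrow(offs))) {
        u <- v + offs[k, ]
        if (any(u < 1) || any(u > d)) next
        if (!mask[u[1], u[2], u[3]]) next
        nd <- dv + wts[k]
        if (nd < dist[u[1], u[2], u[3]] - 1e-12) {
          dist[u[1], u[2], u[3]] <- nd
          nxt[[length(nxt) + 1L]] <- u
        }
      }
    }
    active <- if (length(nxt)) unique(do.call(rbind, nxt)) else
      matrix(integer(0), 0, 3)
  }
  dist
}

# brute-force Euclidean distance transform on a small mask
bruteEDT <- function(mask) {
  d <- dim(mask)
  coords <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  bg <- coords[!mask[coords], , drop = FALSE]
  out <- array(0, d)
  fg <- coords[mask[coords], , drop = FALSE]
  for (i in seq_len(nrow(fg))) {
    v <- fg[i, ]
    out[v[1], v[2], v[3]] <-
      sqrt(min(colSums((t(bg) - v)^2)))
  }
  out
}

expectedIdealTable <- function() {
  makeIdealTable(treeSpec(K = 10, r0 = 10, l0 = 10, a = 0.5, b = 1 / 3))
}
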