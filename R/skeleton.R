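#' Root voxel of a network mask
#'
#' The deepest interior point of the mask: the voxel maximizing the exact
#' Euclidean distance transform (physical units). For vascular masks this is
#' a point on the axis of the widest vessel, which anchors tree traversal at
#' the aorta. Ties are broken lexicographically by (x, y, z).
#'
#' @param m a \linkS4class{NetworkMask}.
#' @return integer(3), 1-based voxel coordinates.
#' @export
findRoot <- function(m) {
  stopifnot(is(m, "NetworkMask"))
  d <- dim(m@mask)
  dt <- .edt_cpp(as.logical(m@mask), d, m@spacing)
  mx <- max(dt)
  cand <- idx2vox(which(dt >= mx - 1e-12), d)
  as.integer(cand[lexOrder(cand)[1], ])
}

# distance transform of a mask, as a vector parallel to the linearized array
maskEDT <- function(m) .edt_cpp(as.logical(m@mask), dim(m@mask), m@spacing)

#' Detect network endpoints (vessel tips)
#'
#' Tips are where vessels become too small to follow: local maxima of the
#' geodesic (within-mask) distance from the root. A voxel is kept only if it
#' is the geodesic-farthest voxel within its own geodesic neighbourhood of
#' radius \code{min_separation} voxel-widths; the root's own neighbourhood
#' contributes no endpoint. The suppression radius should exceed the local
#' vessel radius, otherwise bulges on the wall of wide junctions can masquerade
#' as tips — see \code{\link{extractNetwork}}, which scales it automatically.
#'
#' @param m a \linkS4class{NetworkMask}.
#' @param root integer(3) root voxel (see \code{\link{findRoot}}).
#' @param min_separation suppression radius in voxel-widths (default 3).
#' @return integer matrix (k x 3) of tip voxels, lexicographically ordered;
#'   may be empty for a ball-like mask.
#' @export
detectEndpoints <- function(m, root, min_separation = 3) {
  stopifnot(is(m, "NetworkMask"))
  d <- dim(m@mask)
  rootIdx <- vox2idx(matrix(as.integer(root), 1), d)
  if (!m@mask[root[1], root[2], root[3]])
    stop("root voxel is not inside the mask")
  gd <- .geodesic_cpp(as.logical(m@mask), d, m@spacing, rootIdx - 1L)
  w <- mean(m@spacing)
  sep_mm <- min_separation * w
  # the exclusion zone around the root covers sqrt(2) x the suppression
  # radius: on a flat inlet face the geodesic maxima sit on the rim, up to
  # sqrt(2) x the vessel depth away from the root voxel
  ep0 <- .detect_endpoints_cpp(as.logical(m@mask), d, m@spacing, gd,
                               sep_mm, sqrt(2) * sep_mm)
  if (length(ep0) == 0L)
    return(matrix(integer(0), 0, 3))
  vox <- idx2vox(ep0 + 1L, d)
  # centre each tip: the geodesic-farthest voxel of a blunt vessel end sits
  # on the rim, so snap to the most interior voxel (max EDT; gdist, then
  # lexicographic tie-breaks) among its immediate neighbours
  dt <- maskEDT(m)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(vox))) {
    nbr <- sweep(offs, 2, vox[i, ], "+")
    ok <- nbr[, 1] >= 1 & nbr[, 2] >= 1 & nbr[, 3] >= 1 &
      nbr[, 1] <= d[1] & nbr[, 2] <= d[2] & nbr[, 3] <= d[3]
    nbr <- nbr[ok, , drop = FALSE]
    idx <- vox2idx(nbr, d)
    inMask <- m@mask[idx]
    nbr <- nbr[inMask, , drop = FALSE]
    idx <- idx[inMask]
    sc <- order(-dt[idx], -gd[idx], nbr[, 1], nbr[, 2], nbr[, 3])[1]
    vox[i, ] <- nbr[sc, ]
  }
  vox <- unique(vox)
  vox[lexOrder(vox), , drop = FALSE]
}

#' Skeletonize a mask by endpoint-preserving erosion
#'
#' Successively removes voxels until no more are removable without
#' disconnecting the endpoints: boundary voxels are peeled in increasing
#' distance-transform order (lexicographic tie-break), a voxel being removable
#' when its remaining 26-neighbours stay locally connected (simple-point
#' test) and it is not a protected endpoint. The survivors form a one-voxel
#' wide centerline lying within about one voxel-width of the true axis for
#' tubular shapes.
#'
#' @param m a \linkS4class{NetworkMask}.
#' @param endpoints integer matrix (k x 3) of protected tip voxels, all
#'   inside the mask and mutually connected within it.
#' @param root optional integer(3) root voxel, protected alongside the
#'   endpoints; the pipeline passes \code{\link{findRoot}} so the skeleton
#'   always reaches the deepest point of the widest vessel, which anchors
#'   the tree even when the root lies beyond the last detected tip.
#' @return A \linkS4class{VesselSkeleton}.
#' @export
skeletonize <- function(m, endpoints, root = NULL) {
  stopifnot(is(m, "NetworkMask"))
  d <- dim(m@mask)
  if (is.null(dim(endpoints))) endpoints <- matrix(endpoints, ncol = 3)
  if (!is.null(root))
    endpoints <- unique(rbind(endpoints, matrix(as.integer(root), 1)))
  epIdx <- if (nrow(endpoints)) vox2idx(endpoints, d) else integer(0)
  if (length(epIdx) && !all(m@mask[epIdx]))
    stop("endpoints must lie inside the mask")
  if (length(epIdx) > 1L) {
    labels <- .cc_label_cpp(as.logical(m@mask), d, 26L)
    if (length(unique(labels[epIdx])) != 1L)
      stop("endpoints are not mutually connected within the mask")
  }
  dt <- maskEDT(m)
  skel <- .skeletonize_cpp(as.logical(m@mask), d, dt, epIdx - 1L)
  skelArr <- array(skel, d)
  sidx <- which(skel)
  if (length(epIdx) > 1L) {
    sl <- .cc_label_cpp(skel, d, 26L)
    if (length(unique(sl[epIdx])) != 1L)
      stop("internal error: endpoints disconnected after erosion")
  }
  counts <- .count_neighbors_cpp(skel, d)[sidx]
  labels <- ifelse(counts == 0L, "isolated",
                   ifelse(counts == 1L, "endpoint",
                          ifelse(counts == 2L, "regular", "branch")))
  vox <- idx2vox(sidx, d)
  # root of the skeleton: its deepest voxel (max mask EDT), lex tie-break
  dts <- dt[sidx]
  cand <- which(dts >= max(dts) - 1e-12)
  rootRow <- cand[lexOrder(vox[cand, , drop = FALSE])[1]]
  new("VesselSkeleton", voxels = vox, labels = labels,
      root = as.integer(vox[rootRow, ]), dims = as.integer(d),
      spacing = m@spacing, origin = m@origin)
}

#' Export skeleton voxels as a TSV point list
#'
#' Debug export: one row per skeleton voxel with 0-based grid coordinates
#' (x, y, z) and its classification label, suitable for point-cloud
#' viewers.
#'
#' @param s a \linkS4class{VesselSkeleton}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSkeletonPoints <- function(s, path) {
  stopifnot(is(s, "VesselSkeleton"))
  df <- data.frame(x = s@voxels[, 1] - 1L, y = s@voxels[, 2] - 1L,
                   z = s@voxels[, 3] - 1L, label = s@labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a skeleton into centerline paths
#'
#' Labels every skeleton voxel (endpoint: one 26-neighbour; regular: two;
#' branch: three or more) and returns the maximal centerline paths whose
#' interior voxels are regular. Paths run from one critical voxel (endpoint
#' or branch) to the next; branch voxels are shared path ends. Pure cycles
#' with no critical voxel are returned as closed paths.
#'
#' @param s a \linkS4class{VesselSkeleton}.
#' @return list of integer matrices, each an ordered (n x 3) voxel path.
#' @export
classifyAndSplit <- function(s) {
  stopifnot(is(s, "VesselSkeleton"))
  vox <- s@voxels
  n <- nrow(vox)
  if (n == 0L) return(list())
  d <- s@dims
  lookup <- integer(prod(d))
  sidx <- vox2idx(vox, d)
  lookup[sidx] <- seq_len(n)
  # neighbour row ids, n x 26
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nb <- matrix(NA_integer_, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    q <- sweep(vox, 2, offs[k, ], "+")
    ok <- q[, 1] >= 1L & q[, 2] >= 1L & q[, 3] >= 1L &
      q[, 1] <= d[1] & q[, 2] <= d[2] & q[, 3] <= d[3]
    hit <- rep(0L, n)
    hit[ok] <- lookup[vox2idx(q[ok, , drop = FALSE], d)]
    nb[, k] <- ifelse(hit > 0L, hit, NA_integer_)
  }
  degree <- rowSums(!is.na(nb))
  nbList <- lapply(seq_len(n), function(i) sort(nb[i, !is.na(nb[i, ])]))
  critical <- which(degree != 2L)
  visited <- rep(FALSE, n)  # regular voxels consumed by a path
  paths <- list()
  trace <- function(start, second) {
    p <- c(start, second)
    prev <- start; cur <- second
    while (degree[cur] == 2L && !(cur %in% critical)) {
      nxt <- setdiff(nbList[[cur]], prev)
      if (length(nxt) == 0L) break          # dead end (shouldn't happen)
      # corner shortcut: both neighbours can sit adjacent to each other;
      # degree==2 guarantees exactly one remaining choice
      prev <- cur; cur <- nxt[1]
      p <- c(p, cur)
      if (cur == start) break               # closed cycle
    }
    p
  }
  for (c0 in critical) {
    for (u in nbList[[c0]]) {
      if (degree[u] != 2L) {
        if (u > c0) paths[[length(paths) + 1L]] <- c(c0, u)
      } else if (!visited[u]) {
        p <- trace(c0, u)
        interior <- p[-c(1, length(p))]
        last <- p[length(p)]
        if (degree[last] == 2L) interior <- c(interior, last)
        visited[interior] <- TRUE
        # avoid emitting the same critical-to-critical path twice
        if (degree[last] != 2L && last < c0 && visited[p[2]] &&
            length(paths) > 0L) {
          dup <- any(vapply(paths, function(q)
            identical(q, rev(p)) || identical(q, p), logical(1)))
          if (dup) next
        }
        paths[[length(paths) + 1L]] <- p
      }
    }
  }
  # pure cycles: untouched regular voxels
  for (i in seq_len(n)) {
    if (degree[i] == 2L && !visited[i] && !(i %in% critical)) {
      p <- trace(i, nbList[[i]][1])
      visited[p] <- TRUE
      paths[[length(paths) + 1L]] <- p
    }
  }
  # single isolated voxels form their own degenerate path
  for (c0 in critical)
    if (degree[c0] == 0L) paths[[length(paths) + 1L]] <- c0
  lapply(paths, function(p) vox[p, , drop = FALSE])
}
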