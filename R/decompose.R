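lexLess <- function(a, b) {
  if (a[1] != b[1]) return(a[1] < b[1])
  if (a[2] != b[2]) return(a[2] < b[2])
  a[3] < b[3]
}

# orient each path so its lexicographically smaller end comes first, then
# order paths by (first, last) end voxel — a deterministic segment numbering
canonicalizePaths <- function(paths) {
  oriented <- lapply(paths, function(p) {
    if (nrow(p) > 1L && lexLess(p[nrow(p), ], p[1, ]))
      p[rev(seq_len(nrow(p))), , drop = FALSE] else p
  })
  keys <- t(vapply(oriented, function(p) c(p[1, ], p[nrow(p), ]),
                   numeric(6)))
  oriented[do.call(order, as.data.frame(keys))]
}

#' Attribute mask voxels to vessel segments
#'
#' Every mask voxel is assigned to the segment whose centerline is closest
#' to it (physical Euclidean distance to the nearest centerline voxel).
#' Centerline voxels shared between paths, and distance ties, go to the
#' lower segment id.
#'
#' @param m a \linkS4class{NetworkMask}.
#' @param paths list of centerline paths (ordered n x 3 voxel matrices), as
#'   returned by \code{\link{classifyAndSplit}}; list position = segment id.
#' @return list with \code{maskVox} (v x 3 voxel coords), \code{segment}
#'   (integer segment id per mask voxel) and \code{dist_mm} (distance to the
#'   assigned centerline).
#' @export
assignVoxels <- function(m, paths) {
  stopifnot(is(m, "NetworkMask"), length(paths) > 0L)
  d <- dim(m@mask)
  skelSeg <- integer(0)
  skelIdx <- integer(0)
  for (i in seq_along(paths)) {
    idx <- vox2idx(paths[[i]], d)
    new <- !(idx %in% skelIdx)
    skelIdx <- c(skelIdx, idx[new])
    skelSeg <- c(skelSeg, rep(i, sum(new)))   # first (lowest) id wins
  }
  maskIdx <- which(as.logical(m@mask))
  maskVox <- idx2vox(maskIdx, d)
  res <- .assign_nearest_cpp(maskVox - 1L, idx2vox(skelIdx, d) - 1L,
                             skelSeg, m@spacing)
  list(maskVox = maskVox, segment = res$segment, dist_mm = res$dist_mm)
}

#' Measure one vessel segment
#'
#' Length is the sum of physical Euclidean steps between consecutive
#' centerline voxels (no quantization correction: jagged centerlines
#' overestimate length, and the radius \code{r = sqrt(V / (pi l))}
#' correspondingly underestimates, which cancels in scaling ratios).
#' Volume is voxel count times voxel volume.
#'
#' @param voxels voxel set of the segment: an (n x 3) matrix or a voxel count.
#' @param path ordered centerline (k x 3) voxel matrix.
#' @param spacing numeric(3) voxel size in mm.
#' @return list with \code{length_mm}, \code{volume_mm3}, \code{radius_mm}.
#' @export
measureSegment <- function(voxels, path, spacing) {
  nvox <- if (is.matrix(voxels)) nrow(voxels) else as.integer(voxels)
  if (nvox < 1L || is.null(path) || nrow(path) < 1L)
    stop("segment must have at least one voxel and a non-empty path")
  if (nrow(path) == 1L) {
    l <- mean(spacing)  # degenerate single-voxel centerline
  } else {
    steps <- diff(path) * rep(spacing, each = nrow(path) - 1L)
    l <- sum(sqrt(rowSums(steps^2)))
  }
  V <- nvox * prod(spacing)
  list(length_mm = l, volume_mm3 = V, radius_mm = sqrt(V / (pi * l)))
}

#' Segment quality filter
#'
#' A segment is well-segmented when at most 20% of its voxels lie farther
#' than (r + 1) voxel-widths from its centerline and it comprises at least 4
#' voxels. Distances are voxel-centre to nearest centerline voxel-centre in
#' voxel-widths, with the measured radius converted to voxel-widths.
#'
#' @param far_fraction fraction of voxels beyond (r + 1) voxel-widths.
#' @param n_voxels segment voxel count.
#' @param far_cutoff,min_voxels filter parameters (defaults 0.20 and 4).
#' @return logical vector.
#' @export
qualityFilter <- function(far_fraction, n_voxels, far_cutoff = 0.20,
                          min_voxels = 4L) {
  far_fraction <= far_cutoff & n_voxels >= min_voxels
}

#' Build the rooted vessel tree
#'
#' Roots the segment graph at the segment of greatest radius (assumed
#' aortic), orients all other segments away from it by breadth-first
#' traversal, flags segments lying on cycles (reticulation) as
#' \code{in_loop}, and counts downstream tips (a tip counts itself:
#' \code{n_downstream_tips = 1}).
#'
#' @param segdf data.frame with one row per segment: \code{segment_id},
#'   measurement columns, and end-node labels \code{node_a}, \code{node_b}
#'   (shared skeleton branch points).
#' @param subject_id label stored on the output table.
#' @return A \linkS4class{VesselTree}.
#' @export
buildTree <- function(segdf, subject_id = "subject1") {
  stopifnot(all(c("segment_id", "radius_mm", "node_a", "node_b") %in%
                  names(segdf)))
  segdf <- segdf[order(segdf$segment_id), , drop = FALSE]
  n <- nrow(segdf)
  nodes <- unique(c(segdf$node_a, segdf$node_b))
  g <- igraph::graph_from_data_frame(
    data.frame(from = segdf$node_a, to = segdf$node_b,
               segment_id = segdf$segment_id),
    directed = FALSE, vertices = data.frame(name = nodes))
  if (igraph::components(g)$no != 1L)
    stop("segment graph has multiple connected components")
  # segments on cycles = non-bridge edges (self-loops and multi-edges
  # included); these are flagged and excluded from junction records
  bridgeIds <- segdf$segment_id[as.integer(igraph::bridges(g))]
  segdf$in_loop <- !(segdf$segment_id %in% bridgeIds)

  rootRow <- which(segdf$radius_mm >= max(segdf$radius_mm) - 1e-12)[1]
  rootId <- segdf$segment_id[rootRow]

  incident <- split(rep(seq_len(n), 2L), c(segdf$node_a, segdf$node_b))
  parent <- rep(NA_integer_, n)
  attachNode <- rep(NA_character_, n)
  visited <- rep(FALSE, n)
  visited[rootRow] <- TRUE
  queue <- rootRow
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (node in c(segdf$node_a[cur], segdf$node_b[cur])) {
      for (j in sort(incident[[node]])) {
        if (!visited[j]) {
          visited[j] <- TRUE
          parent[j] <- segdf$segment_id[cur]
          attachNode[j] <- node
          queue <- c(queue, j)
        }
      }
    }
  }
  segdf$parent_id <- parent
  segdf$attach_node <- attachNode
  # downstream tips: leaves count themselves
  children <- split(seq_len(n), factor(parent, levels = segdf$segment_id))
  nd <- rep(NA_integer_, n)
  # iterative post-order to avoid deep recursion on long chains
  order_ <- integer(0)
  stack <- rootRow
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_ <- c(cur, order_)
    kids <- children[[as.character(segdf$segment_id[cur])]]
    if (length(kids)) stack <- c(stack, kids)
  }
  for (i in order_) nd[i] <- 0L
  for (i in order_) {
    kids <- children[[as.character(segdf$segment_id[i])]]
    nd[i] <- if (length(kids)) sum(nd[kids]) else 1L
  }
  segdf$n_downstream_tips <- nd
  segdf$subject_id <- subject_id
  tree <- new("VesselTree", segments = segdf, rootId = as.integer(rootId),
              junctions = data.frame())
  tree@junctions <- extractJunctions(tree)
  tree
}

#' Extract branching-junction records
#'
#' One record per branching junction: a well-segmented, non-loop parent with
#' at least two well-segmented, non-loop children attached at the same
#' skeleton node. Children of a parent attached at different nodes (possible
#' for the root segment) form separate junctions. The smaller-than-parent
#' flags use strict inequality.
#'
#' @param t a \linkS4class{VesselTree}.
#' @return data.frame with columns \code{parent_id}, \code{arity},
#'   \code{r_parent}, \code{l_parent}, list-columns \code{r_children},
#'   \code{l_children}, and the two all-children-smaller flags.
#' @export
extractJunctions <- function(t) {
  s <- t@segments
  empty <- data.frame(parent_id = integer(0), arity = integer(0),
                      r_parent = numeric(0), l_parent = numeric(0),
                      all_children_smaller_radius = logical(0),
                      all_children_smaller_length = logical(0))
  empty$r_children <- list()
  empty$l_children <- list()
  if (!"well_segmented" %in% names(s)) s$well_segmented <- TRUE
  if (!"in_loop" %in% names(s)) s$in_loop <- FALSE
  eligible <- s$well_segmented & !s$in_loop
  kids <- s[!is.na(s$parent_id) & eligible, , drop = FALSE]
  if (!nrow(kids)) return(empty)
  grpKey <- if ("attach_node" %in% names(s))
    paste(kids$parent_id, kids$attach_node) else as.character(kids$parent_id)
  out <- list()
  for (key in unique(grpKey)) {
    ch <- kids[grpKey == key, , drop = FALSE]
    pid <- ch$parent_id[1]
    prow <- s[s$segment_id == pid, , drop = FALSE]
    if (!nrow(prow) || !prow$well_segmented || prow$in_loop) next
    if (nrow(ch) < 2L) next
    rec <- data.frame(parent_id = pid, arity = nrow(ch),
                      r_parent = prow$radius_mm, l_parent = prow$length_mm,
                      all_children_smaller_radius =
                        all(ch$radius_mm < prow$radius_mm),
                      all_children_smaller_length =
                        all(ch$length_mm < prow$length_mm))
    rec$r_children <- list(ch$radius_mm)
    rec$l_children <- list(ch$length_mm)
    out[[length(out) + 1L]] <- rec
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$parent_id), , drop = FALSE]
}

# Decompose a network mask into a measured vessel tree.
decomposeMask <- function(m, min_separation = NULL, subject_id = "subject1",
                          far_cutoff = 0.20, min_voxels = 4L,
                          junction_merge_factor = 1.5, verbose = FALSE) {
  d <- dim(m@mask)
  w <- mean(m@spacing)
  root <- findRoot(m)
  if (is.null(min_separation)) {
    depth <- max(maskEDT(m)) / w
    min_separation <- max(3, ceiling(depth) + 2)
  }
  eps <- detectEndpoints(m, root, min_separation)
  if (verbose)
    message(sprintf("root (%d,%d,%d); %d endpoints (min_separation %.1f)",
                    root[1], root[2], root[3], nrow(eps), min_separation))
  skel <- skeletonize(m, eps, root = root)
  paths <- canonicalizePaths(classifyAndSplit(skel))
  if (!length(paths)) stop("skeletonization produced no centerline paths")

  # junction clusters: connected groups of branch voxels collapse to one node
  branchVox <- skel@voxels[skel@labels == "branch", , drop = FALSE]
  clusterOf <- integer(0)
  if (nrow(branchVox)) {
    bArr <- array(FALSE, d)
    bArr[branchVox] <- TRUE
    bl <- .cc_label_cpp(as.logical(bArr), d, 26L)
    clusterOf <- bl  # lookup by linear index
  }
  nodeKey <- function(vox) {
    idx <- vox2idx(matrix(vox, 1), d)
    if (length(clusterOf) && clusterOf[idx] > 0L)
      paste0("J", clusterOf[idx]) else paste0("V", idx)
  }
  ends <- t(vapply(paths, function(p)
    c(nodeKey(p[1, ]), nodeKey(p[nrow(p), ])), character(2)))

  # Junction-plumbing contraction: a skeleton path that runs from one
  # branch node to another in less than junction_merge_factor x the local
  # vessel depth lies inside a single junction ball (two centerlines meeting
  # a wide trunk rarely fuse at one voxel), so both ends are the same
  # anatomical junction. Such paths are folded into the junction node
  # rather than reported as vessel segments.
  dt <- maskEDT(m)
  plen <- vapply(paths, function(p) {
    if (nrow(p) < 2L) return(0)
    sum(sqrt(rowSums((diff(p) * rep(m@spacing, each = nrow(p) - 1L))^2)))
  }, numeric(1))
  endDepth <- vapply(paths, function(p)
    max(dt[vox2idx(p[c(1L, nrow(p)), , drop = FALSE], d)]), numeric(1))
  keys <- unique(as.vector(ends))
  uf <- stats::setNames(seq_along(keys), keys)
  findUF <- function(i) { while (uf[i] != i) i <- uf[i]; i }
  bothJ <- grepl("^J", ends[, 1]) & grepl("^J", ends[, 2])
  plumbing <- bothJ & plen <= junction_merge_factor * endDepth
  for (i in which(plumbing)) {
    ra <- findUF(match(ends[i, 1], keys))
    rb <- findUF(match(ends[i, 2], keys))
    if (ra != rb) uf[max(ra, rb)] <- min(ra, rb)
  }
  resolve <- function(k) keys[findUF(match(k, keys))]
  resolved <- vapply(as.vector(ends), resolve, character(1))
  endsAll <- ends
  ends <- matrix(resolved, ncol = 2)
  keep <- !plumbing
  if (!any(keep)) keep <- which.max(plen)  # degenerate blob: keep something

  # Each junction node is represented by a single junction point: the
  # deepest voxel (max EDT) among its member voxels — the branch-voxel
  # cluster plus any contracted plumbing paths. Incident centerlines are
  # measured from that point: the portion of a path wandering inside the
  # junction ball (closer to the junction point than the local depth) is
  # replaced by a straight step to the point, so parent length reaches the
  # junction and child lengths do not double-count the ball interior.
  members <- list()
  addMember <- function(key, vox) {
    members[[key]] <<- rbind(members[[key]], vox)
  }
  if (nrow(branchVox)) {
    bkeys0 <- paste0("J", clusterOf[vox2idx(branchVox, d)])
    known <- bkeys0 %in% keys
    bkeys <- bkeys0
    bkeys[known] <- vapply(bkeys0[known], resolve, character(1))
    for (k in unique(bkeys)) addMember(k, branchVox[bkeys == k, , drop = FALSE])
  }
  for (i in which(plumbing)) addMember(ends[i, 1], paths[[i]])
  jpoint <- lapply(members, function(vx) {
    vals <- dt[vox2idx(vx, d)]
    cand <- which(vals >= max(vals) - 1e-12)
    vx[cand[lexOrder(vx[cand, , drop = FALSE])[1]], ]
  })
  trimToJunction <- function(p, key, side) {
    jp <- jpoint[[key]]
    if (is.null(jp)) return(p)
    ballR <- dt[vox2idx(matrix(jp, 1), d)]
    if (side == "end") p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    dists <- sqrt(colSums((t(p) - jp)^2 * m@spacing^2))
    maxDrop <- nrow(p) - max(1L, floor(nrow(p) / 2))
    nDrop <- 0L
    while (nDrop < maxDrop && dists[nDrop + 1L] < ballR) nDrop <- nDrop + 1L
    if (nDrop > 0L) p <- p[-seq_len(nDrop), , drop = FALSE]
    p <- rbind(as.integer(jp), p)
    if (side == "end") p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    p
  }

  paths <- paths[keep]
  ends <- ends[keep, , drop = FALSE]
  if (!length(paths)) stop("no vessel segments survive path classification")

  assign <- assignVoxels(m, paths)
  nseg <- length(paths)
  meas <- vector("list", nseg)
  # the root voxel is an interior point (one vessel-depth in from the
  # inlet face); a segment terminating there is extended by that depth so
  # its length spans the territory its voxels actually cover
  rootKey <- paste0("V", vox2idx(matrix(as.integer(root), 1), d))
  rootExt <- dt[vox2idx(matrix(as.integer(root), 1), d)]
  for (i in seq_len(nseg)) {
    nvox <- sum(assign$segment == i)
    p <- paths[[i]]
    if (grepl("^J", ends[i, 1])) p <- trimToJunction(p, ends[i, 1], "start")
    if (grepl("^J", ends[i, 2])) p <- trimToJunction(p, ends[i, 2], "end")
    extra <- if (rootKey %in% ends[i, ]) rootExt else 0
    mm <- measureSegment(max(nvox, 1L), p, m@spacing)
    mm$length_mm <- mm$length_mm + extra
    mm$radius_mm <- sqrt(max(nvox, 1L) * prod(m@spacing) /
                           (pi * mm$length_mm))
    distVox <- assign$dist_mm[assign$segment == i] / w
    rVox <- mm$radius_mm / w
    farFrac <- if (nvox) mean(distVox > rVox + 1) else 1
    meas[[i]] <- data.frame(segment_id = i, length_mm = mm$length_mm,
                            volume_mm3 = nvox * prod(m@spacing),
                            radius_mm = sqrt(nvox * prod(m@spacing) /
                                               (pi * mm$length_mm)),
                            n_voxels = nvox, far_fraction = farFrac,
                            node_a = ends[i, 1], node_b = ends[i, 2])
  }
  segdf <- do.call(rbind, meas)
  segdf$centerline <- paths
  # a segment can end up with zero assigned voxels if a neighbour's
  # centerline shadows it completely; treat as a failed segment
  segdf$well_segmented <- qualityFilter(segdf$far_fraction, segdf$n_voxels,
                                        far_cutoff, min_voxels) &
    segdf$n_voxels > 0L
  tree <- buildTree(segdf, subject_id = subject_id)
  tree
}

#' Extract a measured vessel tree from a volume
#'
#' The full measurement pipeline: threshold the volume, keep the largest
#' connected component (the network mask), find the root and the vessel
#' tips, skeletonize by endpoint-preserving erosion, split the skeleton into
#' centerline paths, attribute every mask voxel to its nearest centerline,
#' measure each segment (length, volume, radius), apply the quality filter
#' and build the rooted tree.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param threshold intensity threshold (strict \code{>}).
#' @param connectivity mask connectivity, default 26.
#' @param min_separation endpoint suppression radius in voxel-widths;
#'   \code{NULL} (default) scales it with the deepest vessel radius
#'   (\code{max(3, ceil(max EDT) + 2)}), which prevents wall bulges of wide
#'   junctions from being mistaken for tips.
#' @param subject_id label recorded in the segment table.
#' @param far_cutoff,min_voxels quality-filter parameters (defaults 0.20, 4).
#' @param junction_merge_factor skeleton paths between two branch nodes
#'   shorter than this multiple of the local vessel depth are treated as
#'   plumbing inside one junction ball and contracted into a single
#'   junction node (default 1.5).
#' @param verbose print progress.
#' @return A \linkS4class{VesselTree}.
#' @examples
#' ph <- layoutAndVoxelize(treeSpec(K = 1, r0 = 4, l0 = 24), voxel_mm = 1)
#' tr <- extractNetwork(ph$volume, threshold = 50)
#' segments(tr)[, c("segment_id", "radius_mm", "n_downstream_tips")]
#' @export
extractNetwork <- function(v, threshold, connectivity = 26,
                           min_separation = NULL, subject_id = "subject1",
                           far_cutoff = 0.20, min_voxels = 4L,
                           junction_merge_factor = 1.5, verbose = FALSE) {
  m <- makeNetworkMask(v, threshold, connectivity)
  decomposeMask(m, min_separation = min_separation, subject_id = subject_id,
                far_cutoff = far_cutoff, min_voxels = min_voxels,
                junction_merge_factor = junction_merge_factor,
                verbose = verbose)
}
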