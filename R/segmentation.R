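#' Threshold a volume
#'
#' Marks every voxel whose intensity strictly exceeds \code{t}.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param t finite intensity threshold.
#' @return 3D logical array.
#' @export
thresholdVoxels <- function(v, t) {
  stopifnot(is(v, "VoxelVolume"))
  if (!is.finite(t)) stop("threshold must be finite")
  v@intensities > t
}

#' Largest connected component of a boolean grid
#'
#' Keeps exactly the voxels of the largest connected component under the
#' requested neighbourhood order. Size ties are broken in favour of the
#' component containing the lexicographically smallest voxel (by x, then y,
#' then z).
#'
#' @param g 3D logical array with at least one \code{TRUE} voxel.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param spacing,origin,threshold geometry and provenance stored on the
#'   returned mask.
#' @return A \linkS4class{NetworkMask}.
#' @export
largestComponent <- function(g, connectivity = 26,
                             spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             threshold = NA_real_) {
  if (length(dim(g)) != 3L) stop("grid must be 3D")
  if (!any(g))
    stop("empty mask: no voxels above threshold")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  labels <- .cc_label_cpp(as.logical(g), dim(g), connectivity)
  sizes <- tabulate(labels)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component whose seed voxel is lexicographically smallest
    seeds <- vapply(best, function(lb) {
      vox <- idx2vox(which(labels == lb), dim(g))
      vox <- vox[lexOrder(vox)[1], , drop = FALSE]
      vox2idx(vox, dim(g))
    }, integer(1))
    ordvox <- idx2vox(seeds, dim(g))
    best <- best[lexOrder(ordvox)[1]]
  }
  keep <- array(labels == best, dim(g))
  new("NetworkMask", mask = keep, spacing = as.numeric(spacing),
      origin = as.numeric(origin), threshold = as.numeric(threshold),
      connectivity = connectivity)
}

#' Build the vessel-lumen network mask
#'
#' The network mask is the largest 26-connected group of voxels whose
#' intensity strictly exceeds the threshold. An empty result signals that the
#' threshold is too high.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param t intensity threshold (strict \code{>}).
#' @param connectivity neighbourhood order, default 26.
#' @return A \linkS4class{NetworkMask}.
#' @seealso \code{\link{suggestThreshold}} for an automatic starting value.
#' @export
makeNetworkMask <- function(v, t, connectivity = 26) {
  g <- thresholdVoxels(v, t)
  if (!any(g))
    stop("empty mask: no voxels exceed threshold ", t,
         " (threshold too high)")
  largestComponent(g, connectivity = connectivity, spacing = v@spacing,
                   origin = v@origin, threshold = t)
}

#' Suggest an intensity threshold (Otsu)
#'
#' Convenience only: Otsu's criterion on the intensity histogram. Threshold
#' choice for real angiograms is a judgement call (the reference procedure is
#' a manual binary search against visual vessel identification); treat this
#' value as a starting point, not a substitute for inspection.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param nbins histogram resolution.
#' @return A single intensity value.
#' @export
suggestThreshold <- function(v, nbins = 256) {
  x <- as.numeric(v@intensities)
  rg <- range(x)
  if (rg[1] == rg[2]) return(rg[1])
  h <- hist(x, breaks = seq(rg[1], rg[2], length.out = nbins + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  sigma2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- -Inf
  mids[which.max(sigma2)]
}
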