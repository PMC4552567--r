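# Internal voxel-grid helpers. Linear indices are 1-based and column-major
# (R array order); voxel coordinates are 1-based (i, j, k) triples.

vox2idx <- function(vox, dims) {
  (vox[, 1] - 1L) + dims[1] * (vox[, 2] - 1L) +
    dims[1] * dims[2] * (vox[, 3] - 1L) + 1L
}

idx2vox <- function(idx, dims) {
  idx0 <- idx - 1L
  cbind(idx0 %% dims[1],
        (idx0 %/% dims[1]) %% dims[2],
        idx0 %/% (dims[1] * dims[2])) + 1L
}

# order voxel rows lexicographically by (x, y, z)
lexOrder <- function(vox) order(vox[, 1], vox[, 2], vox[, 3])

#' Construct a VoxelVolume
#'
#' @param intensities 3D numeric array.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) physical coordinate of the first voxel centre (mm).
#' @return A \linkS4class{VoxelVolume}.
#' @export
voxelVolume <- function(intensities, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  if (is.null(dim(intensities)) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array, got dimensionality ",
         length(dim(intensities)))
  new("VoxelVolume", intensities = intensities,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

# derive a reproducible 32-bit substream seed from a base seed and a tag
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}
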