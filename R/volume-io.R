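#' Read a 3D tomographic volume
#'
#' Reads NIfTI (\code{.nii}, \code{.nii.gz}), NRRD (\code{.nrrd}) and
#' multi-page TIFF volumes. Voxel spacing is taken from the file header; a
#' TIFF stack carries no spacing metadata, so unit spacing is assumed and a
#' warning is emitted.
#'
#' @param path path to the volume file.
#' @return A \linkS4class{VoxelVolume}.
#' @examples
#' v <- voxelVolume(array(runif(8^3), c(8, 8, 8)), spacing = c(0.8, 0.8, 0.9))
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(v, f)
#' spacing(readVolume(f))
#' @seealso \code{\link{writeVolume}}, \code{\link{downsample2x2x2}}
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("volume file does not exist: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    im <- RNifti::readNifti(path)
    arr <- array(as.numeric(im), dim = dim(im))
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- arr[, , , 1L, drop = TRUE]
    if (length(dim(arr)) != 3L)
      stop("volume in ", path, " is ", length(dim(arr)),
           "-dimensional, expected 3D")
    xf <- RNifti::xform(im)
    sp <- if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0)
      sqrt(colSums(xf[1:3, 1:3]^2)) else RNifti::pixdim(im)[1:3]
    sp[sp == 0] <- 1
    org <- as.numeric(xf[1:3, 4])
    # our convention keeps axes aligned with positive spacing
    voxelVolume(arr, spacing = abs(sp), origin = org)
  } else if (grepl("\\.nrrd$", lower)) {
    nr <- readNrrd(path)
    sp <- nr$spacing
    if (is.null(sp)) {
      warning("NRRD file ", path, " carries no spacing; assuming 1 mm voxels")
      sp <- c(1, 1, 1)
    }
    voxelVolume(nr$data, spacing = sp, origin = nr$origin)
  } else if (grepl("\\.tiff?$", lower)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop("TIFF file ", path, " holds a single 2D page, expected a 3D stack")
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("TIFF pages in ", path, " are not greyscale 2D planes")
    d <- dim(pages[[1]])
    arr <- array(NA_real_, c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    warning("TIFF stack ", path,
            " carries no voxel spacing; assuming 1 mm isotropic voxels")
    voxelVolume(arr, spacing = c(1, 1, 1))
  } else {
    stop("unsupported volume format: ", path,
         " (supported: .nii, .nii.gz, .nrrd, .tif/.tiff)")
  }
}

#' Write a 3D volume
#'
#' Writes NIfTI (\code{.nii}, \code{.nii.gz}) or NRRD (\code{.nrrd});
#' spacing and origin go into the header so that \code{readVolume} recovers
#' them exactly.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param path output path; the extension selects the format.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "VoxelVolume"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    im <- RNifti::asNifti(v@intensities)
    im <- RNifti::`pixdim<-`(im, v@spacing)
    m <- diag(4)
    m[1, 1] <- v@spacing[1]; m[2, 2] <- v@spacing[2]; m[3, 3] <- v@spacing[3]
    m[1:3, 4] <- v@origin
    attr(m, "code") <- 2L
    im <- RNifti::`sform<-`(im, m)
    RNifti::writeNifti(im, path)
  } else if (grepl("\\.nrrd$", lower)) {
    writeNrrd(v@intensities, path, spacing = v@spacing, origin = v@origin)
  } else {
    stop("unsupported volume output format: ", path,
         " (supported: .nii, .nii.gz, .nrrd)")
  }
  invisible(path)
}

#' Average 2x2x2 voxel blocks
#'
#' Reduces a volume by averaging each 2x2x2 cube of adjacent voxels into a
#' single voxel, the standard pre-processing step that trades resolution for
#' noise suppression on contrast-enhanced angiograms. Output dimensions are
#' \code{floor(dim/2)}; trailing odd slices are cropped before averaging so
#' that every output voxel is an exact 8-voxel arithmetic mean. Spacing is
#' doubled and the origin moves to the centre of the first block.
#'
#' @param v a \linkS4class{VoxelVolume} with all dimensions >= 2.
#' @return The downsampled \linkS4class{VoxelVolume}.
#' @export
downsample2x2x2 <- function(v) {
  stopifnot(is(v, "VoxelVolume"))
  d <- dim(v@intensities)
  if (any(d < 2L))
    stop("all dimensions must be >= 2 to average 2x2x2 blocks; got ",
         paste(d, collapse = " x "))
  nd <- d %/% 2L
  a <- v@intensities[seq_len(2L * nd[1]), seq_len(2L * nd[2]),
                     seq_len(2L * nd[3]), drop = FALSE]
  # sum the 8 corners of every block
  out <- array(0, nd)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    out <- out + a[seq(1L + ox, by = 2L, length.out = nd[1]),
                   seq(1L + oy, by = 2L, length.out = nd[2]),
                   seq(1L + oz, by = 2L, length.out = nd[3]), drop = FALSE]
  }
  voxelVolume(out / 8, spacing = v@spacing * 2,
              origin = v@origin + v@spacing / 2)
}
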