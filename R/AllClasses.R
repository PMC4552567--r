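#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib angioscale, .registration = TRUE
NULL

#' VoxelVolume: a 3D scalar intensity grid with physical geometry
#'
#' Container for a tomographic image volume. Voxel indices are 1-based in R;
#' the physical position of the centre of voxel (i, j, k) is
#' \code{origin + (c(i, j, k) - 1) * spacing} (voxel-centre convention).
#'
#' @slot intensities 3D numeric array of non-negative, finite intensities.
#' @slot spacing numeric(3), per-axis physical voxel size in mm (> 0).
#' @slot origin numeric(3), physical coordinate (mm) of the first voxel centre.
#' @export
setClass("VoxelVolume",
  representation(intensities = "array", spacing = "numeric",
                 origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VoxelVolume", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 3L)
    return("intensities must be a 3D array")
  if (any(d < 1L))
    return("all three dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three finite positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite values (mm)")
  if (any(!is.finite(object@intensities)))
    return("intensities must be finite")
  TRUE
})

#' NetworkMask: the binary vessel-lumen mask
#'
#' The largest connected component of voxels whose intensity strictly exceeds
#' the threshold, aligned to the originating \linkS4class{VoxelVolume}.
#'
#' @slot mask 3D logical array.
#' @slot spacing,origin geometry inherited from the source volume.
#' @slot threshold intensity threshold used (strict \code{>}).
#' @slot connectivity neighbourhood order used (6, 18 or 26).
#' @export
setClass("NetworkMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric",
                 threshold = "numeric", connectivity = "integer"))

setValidity("NetworkMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  if (!any(object@mask)) return("mask must be non-empty")
  TRUE
})

#' VesselSkeleton: classified one-voxel-wide centerline voxels
#'
#' @slot voxels integer matrix (n x 3) of 1-based voxel indices, a subset of
#'   the mask.
#' @slot labels character vector parallel to \code{voxels}: one of
#'   \code{"endpoint"} (exactly 1 skeleton 26-neighbour), \code{"regular"}
#'   (exactly 2) or \code{"branch"} (3 or more).
#' @slot root integer(3), the root voxel (deepest interior point of the mask).
#' @slot dims,spacing,origin grid geometry of the source mask.
#' @export
setClass("VesselSkeleton",
  representation(voxels = "matrix", labels = "character", root = "integer",
                 dims = "integer", spacing = "numeric", origin = "numeric"))

setValidity("VesselSkeleton", function(object) {
  if (ncol(object@voxels) != 3L) return("voxels must be an n x 3 matrix")
  if (length(object@labels) != nrow(object@voxels))
    return("labels must parallel voxels")
  if (!all(object@labels %in% c("endpoint", "regular", "branch", "isolated")))
    return("unknown voxel label")
  TRUE
})

#' VesselTree: measured vessel segments with rooted topology
#'
#' @slot segments a segment table (see \code{\link{readSegmentTable}} for the
#'   schema): one row per vessel segment with id, parent, length, volume,
#'   radius, quality flags and downstream-tip counts.
#' @slot rootId id of the root segment (greatest radius).
#' @slot junctions data.frame of branching-junction records: parent and child
#'   dimensions plus the strict smaller-than-parent flags (see
#'   \code{\link{extractJunctions}}).
#' @export
setClass("VesselTree",
  representation(segments = "data.frame", rootId = "integer",
                 junctions = "data.frame"))

#' ExponentEstimate: a method-tagged vascular scaling exponent
#'
#' One row of the exponent summary: the scaling exponent a (radius) or b
#' (length) measured by one of the four estimators, with its 95% CI and the
#' dispersion (node-level methods) or fit correlation (network-level methods).
#'
#' @slot method one of \code{"conservation"}, \code{"ratio"},
#'   \code{"distribution"}, \code{"regression"}.
#' @slot dimension \code{"radius"} or \code{"length"}.
#' @slot value the exponent estimate (dimensionless).
#' @slot ciLow,ciHigh bounds of the 95% confidence interval.
#' @slot n number of observations used.
#' @slot sigma per-observation standard deviation (node-level methods; NA
#'   otherwise).
#' @slot rSquared fit correlation squared (network-level methods; NA
#'   otherwise).
#' @export
setClass("ExponentEstimate",
  representation(method = "character", dimension = "character",
                 value = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 n = "integer", sigma = "numeric", rSquared = "numeric"))

setValidity("ExponentEstimate", function(object) {
  if (!object@method %in% c("conservation", "ratio", "distribution",
                            "regression"))
    return("unknown method")
  if (!object@dimension %in% c("radius", "length"))
    return("dimension must be 'radius' or 'length'")
  if (object@n < 2L) return("N must be >= 2")
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    return("ciLow > ciHigh")
  if (is.finite(object@sigma) && is.finite(object@rSquared))
    return("exactly one of sigma / rSquared may be populated")
  TRUE
})

#' SMAFit: a standard major axis regression fit
#'
#' @slot slope,intercept fitted line; |slope| = sd(y)/sd(x), signed by the
#'   Pearson correlation.
#' @slot rSquared squared correlation.
#' @slot ciLow,ciHigh 95% confidence bounds on the slope.
#' @slot n number of points.
#' @export
setClass("SMAFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 n = "integer"))
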