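#' @rdname VoxelVolume-class
#' @param object,x a \linkS4class{VoxelVolume} (or other angioscale object).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname VoxelVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname VoxelVolume-class
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname NetworkMask-class
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname NetworkMask-class
#' @export
setGeneric("maskThreshold", function(x) standardGeneric("maskThreshold"))

#' @rdname VesselSkeleton-class
#' @export
setGeneric("skeletonVoxels", function(x) standardGeneric("skeletonVoxels"))

#' @rdname VesselSkeleton-class
#' @export
setGeneric("voxelLabels", function(x) standardGeneric("voxelLabels"))

#' @rdname VesselTree-class
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname VesselTree-class
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' @rdname VesselTree-class
#' @export
setGeneric("rootId", function(x) standardGeneric("rootId"))

setMethod("intensities", "VoxelVolume", function(x) x@intensities)
setMethod("spacing", "VoxelVolume", function(x) x@spacing)
setMethod("voxelOrigin", "VoxelVolume", function(x) x@origin)
setMethod("spacing", "NetworkMask", function(x) x@spacing)
setMethod("voxelOrigin", "NetworkMask", function(x) x@origin)
setMethod("maskArray", "NetworkMask", function(x) x@mask)
setMethod("maskThreshold", "NetworkMask", function(x) x@threshold)
setMethod("spacing", "VesselSkeleton", function(x) x@spacing)
setMethod("skeletonVoxels", "VesselSkeleton", function(x) x@voxels)
setMethod("voxelLabels", "VesselSkeleton", function(x) x@labels)
setMethod("segments", "VesselTree", function(x) x@segments)
setMethod("junctions", "VesselTree", function(x) x@junctions)
setMethod("rootId", "VesselTree", function(x) x@rootId)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@intensities)
  cat("VoxelVolume:", paste(d, collapse = " x "), "voxels\n")
  cat("  spacing (mm):", paste(signif(object@spacing, 6), collapse = " x "),
      "\n")
  cat("  intensity range:",
      paste(signif(range(object@intensities), 6), collapse = " .. "), "\n")
})

setMethod("show", "NetworkMask", function(object) {
  cat("NetworkMask:", sum(object@mask), "of",
      length(object@mask), "voxels\n")
  cat("  threshold:", signif(object@threshold, 6),
      " connectivity:", object@connectivity, "\n")
})

setMethod("show", "VesselSkeleton", function(object) {
  tab <- table(factor(object@labels,
                      c("endpoint", "regular", "branch", "isolated")))
  cat("VesselSkeleton:", nrow(object@voxels), "voxels (",
      tab[["endpoint"]], "endpoints,", tab[["branch"]], "branch voxels )\n")
})

setMethod("show", "VesselTree", function(object) {
  s <- object@segments
  cat("VesselTree:", nrow(s), "segments,", nrow(object@junctions),
      "junction records\n")
  cat("  root segment:", object@rootId,
      " well-segmented:", sum(s$well_segmented),
      " tips:", sum(s$n_downstream_tips == 1L & !s$in_loop), "\n")
})

setMethod("show", "ExponentEstimate", function(object) {
  ex <- if (object@dimension == "radius") "a" else "b"
  cat(sprintf("%s-based %s = %.4f  95%% CI [%.4f, %.4f]  N = %d",
              object@method, ex, object@value, object@ciLow, object@ciHigh,
              object@n))
  if (is.finite(object@sigma)) cat(sprintf("  sigma = %.4f", object@sigma))
  if (is.finite(object@rSquared)) cat(sprintf("  R^2 = %.4f", object@rSquared))
  cat("\n")
})

setMethod("show", "SMAFit", function(object) {
  cat(sprintf("SMA fit: slope %.6g [%.6g, %.6g], intercept %.6g, R^2 %.4f, n = %d\n",
              object@slope, object@ciLow, object@ciHigh, object@intercept,
              object@rSquared, object@n))
})
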