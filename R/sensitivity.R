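#' Add Gaussian image noise
#'
#' Adds independent Gaussian noise with standard deviation
#' \code{sigma_fraction * max(intensities)} to every voxel, clipping at zero
#' (magnitude images are non-negative). Deterministic given the seed.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param sigma_fraction noise sd as a fraction of the maximum intensity
#'   (the baseline used in sweeps is 0.0047, i.e. 0.47%).
#' @param seed RNG seed.
#' @return noisy \linkS4class{VoxelVolume}.
#' @export
addGaussianNoise <- function(v, sigma_fraction, seed = 1L) {
  stopifnot(is(v, "VoxelVolume"), sigma_fraction >= 0)
  if (sigma_fraction == 0) return(v)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sd <- sigma_fraction * max(v@intensities)
  noisy <- v@intensities + array(stats::rnorm(length(v@intensities), 0, sd),
                                 dim(v@intensities))
  noisy[noisy < 0] <- 0
  voxelVolume(noisy, spacing = v@spacing, origin = v@origin)
}

# number of well-segmented vessels at a threshold ("visible" segments;
# fragments that fail the quality filter do not count)
countSegments <- function(v, threshold, ...) {
  tryCatch(sum(segments(extractNetwork(v, threshold, ...))$well_segmented),
           error = function(e) 0L)
}

#' Maximum usable threshold
#'
#' The largest intensity threshold at which extraction still yields at
#' least \code{min_segments} vessel segments, located by bisection over the
#' sorted unique foreground intensities (those above \code{t_min}). This is
#' the upper anchor of the normalized threshold sweep.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param t_min the minimum (baseline) threshold; extraction must succeed
#'   there with at least \code{min_segments} segments.
#' @param min_segments minimum visible segment count (default 30).
#' @param ... passed to \code{\link{extractNetwork}}.
#' @return intensity threshold.
#' @export
maxThreshold <- function(v, t_min, min_segments = 30, ...) {
  base <- countSegments(v, t_min, ...)
  if (base < min_segments)
    stop("sweep impossible: only ", base, " segments at the minimum ",
         "threshold, need ", min_segments)
  u <- sort(unique(as.numeric(v@intensities)))
  u <- u[u > t_min & u < max(u)]
  cand <- c(t_min, u)
  lo <- 1L                 # known to satisfy
  hi <- length(cand) + 1L  # conceptual failure point
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (countSegments(v, cand[mid], ...) >= min_segments) lo <- mid
    else hi <- mid
  }
  cand[lo]
}

sweepEstimates <- function(tree) {
  tab <- tryCatch(scalingExponentTable(tree), error = function(e) NULL)
  if (is.null(tab))
    tab <- data.frame(method = rep(c("conservation", "ratio", "distribution",
                                     "regression"), 2),
                      dimension = rep(c("radius", "length"), each = 4),
                      N = NA_integer_, value = NA_real_, ci95_low = NA_real_,
                      ci95_high = NA_real_, sigma = NA_real_,
                      r_squared = NA_real_)
  tab
}

#' Threshold sensitivity sweep
#'
#' Runs the full extraction and all four exponent estimators for both
#' dimensions at each normalized threshold \code{s = 0, step, ..., 1}, where
#' \code{s = 0} maps to \code{t_min} (the baseline analysis) and
#' \code{s = 1} to \code{\link{maxThreshold}}. Extraction failures at a
#' step are recorded as NA rows rather than aborting the sweep.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param t_min baseline threshold.
#' @param step normalized increment (default 0.05).
#' @param min_segments passed to \code{\link{maxThreshold}}.
#' @param ... passed to \code{\link{extractNetwork}}.
#' @return long-format data.frame: \code{s}, \code{threshold},
#'   \code{n_segments}, then one row per (method, dimension) estimate.
#' @export
thresholdSweep <- function(v, t_min, step = 0.05, min_segments = 30, ...) {
  t_max <- maxThreshold(v, t_min, min_segments = min_segments, ...)
  svals <- seq(0, 1, by = step)
  out <- list()
  for (s in svals) {
    t <- t_min + s * (t_max - t_min)
    tree <- tryCatch(extractNetwork(v, t, ...), error = function(e) NULL)
    est <- if (is.null(tree)) sweepEstimates(NULL) else sweepEstimates(tree)
    est$s <- s
    est$threshold <- t
    est$n_segments <- if (is.null(tree)) 0L else nrow(segments(tree))
    est$n_well <- if (is.null(tree)) 0L else
      sum(segments(tree)$well_segmented)
    out[[length(out) + 1L]] <- est
  }
  res <- do.call(rbind, out)
  res[, c("s", "threshold", "n_segments", "n_well", "method", "dimension",
          "N", "value", "ci95_low", "ci95_high", "sigma", "r_squared")]
}

#' Image-noise sensitivity sweep
#'
#' Adds Gaussian noise at multiples of the baseline rate (0.47% of the
#' maximum intensity), re-runs extraction and all estimators at each
#' multiple, and reports the estimates and segment counts. Each step uses a
#' seed derived from \code{seed} and the multiple, so individual steps are
#' independently reproducible.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param threshold extraction threshold applied to the noisy volumes.
#' @param baseline baseline noise fraction (default 0.0047).
#' @param multiples noise multiples to evaluate (default 1:10; 0 is allowed
#'   and reproduces the clean run).
#' @param seed sweep-level RNG seed.
#' @param ... passed to \code{\link{extractNetwork}}.
#' @return long-format data.frame keyed by \code{noise_multiple}.
#' @export
noiseSweep <- function(v, threshold, baseline = 0.0047, multiples = 1:10,
                       seed = 1L, ...) {
  out <- list()
  for (mult in multiples) {
    nv <- if (mult == 0) v else
      addGaussianNoise(v, baseline * mult,
                       seed = deriveSeed(seed, paste0("noise", mult)))
    tree <- tryCatch(extractNetwork(nv, threshold, ...),
                     error = function(e) NULL)
    est <- sweepEstimates(tree)
    est$noise_multiple <- mult
    est$sigma_fraction <- baseline * mult
    est$n_segments <- if (is.null(tree)) 0L else nrow(segments(tree))
    est$n_well <- if (is.null(tree)) 0L else
      sum(segments(tree)$well_segmented)
    out[[length(out) + 1L]] <- est
  }
  res <- do.call(rbind, out)
  res[, c("noise_multiple", "sigma_fraction", "n_segments", "n_well",
          "method", "dimension", "N", "value", "ci95_low", "ci95_high",
          "sigma", "r_squared")]
}
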