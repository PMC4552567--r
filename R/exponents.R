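# The four vascular scaling-exponent estimators. Throughout, the radius
# exponent is a and the length exponent is b: across a branching junction
# the generalized conservation law parent^(1/a) = sum(children^(1/a)) holds,
# for symmetric dichotomous trees the child/parent scale factors are
# beta = 2^-a (radius) and gamma = 2^-b (length), the size distribution of
# an idealized tree follows N = (r/r0)^(-1/a), and any segment's dimensions
# relate to its downstream tip count as r ~ Nd^a, l ~ Nd^b.

#' Solve the conservation law at one junction
#'
#' Finds the exponent x > 0 with \code{sum((child/parent)^(1/x)) = 1}, the
#' generalized Murray's-law exponent of a single branching junction. When
#' every child is strictly smaller than the parent the solution exists and
#' is unique (the power sum is monotone in x) and is found by Newton's
#' method, safeguarded by bisection, iterated to convergence — far inside
#' the required residual tolerance. If any child equals or exceeds the
#' parent the exponent is undefined and \code{NA} is returned.
#'
#' @param parent parent dimension (mm), > 0.
#' @param children numeric vector of at least 2 child dimensions, all > 0.
#' @param tol maximum permitted residual |sum - 1| (default 1e-5).
#' @return The exponent, or \code{NA_real_} when undefined.
#' @examples
#' solveConservationExponent(2, c(1, 1))          # 1
#' solveConservationExponent(1, c(2^-0.5, 2^-0.5)) # 0.5
#' @export
solveConservationExponent <- function(parent, children, tol = 1e-5) {
  if (!is.finite(parent) || parent <= 0 || any(!is.finite(children)) ||
      any(children <= 0))
    stop("parent and children dimensions must be positive")
  if (length(children) < 2L)
    stop("a junction needs at least 2 children")
  q <- children / parent
  if (any(q >= 1)) return(NA_real_)   # undefined: child not smaller
  f <- function(x) sum(q^(1 / x)) - 1
  lo <- 1e-3
  hi <- 10
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(lo) > 0) lo <- 1e-8
  x <- 0.5
  if (x <= lo || x >= hi) x <- (lo + hi) / 2
  for (iter in 1:200) {
    fx <- f(x)
    if (fx > 0) hi <- x else lo <- x
    fp <- -sum(q^(1 / x) * log(q)) / x^2
    step <- fx / fp
    xn <- x - step
    if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- (lo + hi) / 2
    if (abs(xn - x) < 1e-13 * max(1, abs(x))) { x <- xn; break }
    x <- xn
  }
  if (abs(f(x)) > tol)
    stop("conservation solver failed to reach residual ", tol)
  x
}

# junction records derived from a segment table: eligible (well-segmented,
# non-loop) children grouped under their eligible parent
junctionsFromTable <- function(tab) {
  tab <- validateSegmentTable(tab)
  if (!"well_segmented" %in% names(tab)) tab$well_segmented <- TRUE
  if (!"in_loop" %in% names(tab)) tab$in_loop <- FALSE
  eligible <- tab$well_segmented & !tab$in_loop
  out <- list()
  for (sub in unique(tab$subject_id)) {
    rows <- tab[tab$subject_id == sub, , drop = FALSE]
    el <- eligible[tab$subject_id == sub]
    kids <- rows[!is.na(rows$parent_id) & el, , drop = FALSE]
    if (!nrow(kids)) next
    for (pid in unique(kids$parent_id)) {
      prow <- rows[rows$segment_id == pid, , drop = FALSE]
      if (!nrow(prow) || !prow$well_segmented[1] || prow$in_loop[1]) next
      ch <- kids[kids$parent_id == pid, , drop = FALSE]
      if (nrow(ch) < 2L) next
      rec <- data.frame(parent_id = pid, arity = nrow(ch),
                        r_parent = prow$radius_mm[1],
                        l_parent = prow$length_mm[1],
                        all_children_smaller_radius =
                          all(ch$radius_mm < prow$radius_mm[1]),
                        all_children_smaller_length =
                          all(ch$length_mm < prow$length_mm[1]))
      rec$r_children <- list(ch$radius_mm)
      rec$l_children <- list(ch$length_mm)
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out))
    return(extractJunctions(new("VesselTree", segments = tab,
                                rootId = NA_integer_,
                                junctions = data.frame())))
  do.call(rbind, out)
}

asJunctionFrame <- function(x) {
  if (is(x, "VesselTree")) return(x@junctions)
  if (is.data.frame(x) && all(c("r_parent", "r_children") %in% names(x)))
    return(x)
  if (is.data.frame(x)) return(junctionsFromTable(x))
  stop("expected a VesselTree, a junction frame or a segment table")
}

#' Conservation-based scaling exponent
#'
#' Solves the conservation law at every branching junction and averages the
#' defined per-junction exponents. A junction's exponent is defined only
#' when all children are strictly smaller than the parent in the chosen
#' dimension. The 95% CI is 1.96 standard errors on the mean.
#'
#' @param junctions a \linkS4class{VesselTree}, a junction record frame
#'   (\code{\link{extractJunctions}}) or a segment table.
#' @param dimension \code{"radius"} or \code{"length"}.
#' @param tol solver residual tolerance.
#' @return An \linkS4class{ExponentEstimate} (slot \code{sigma} holds the
#'   between-junction standard deviation).
#' @export
conservationEstimate <- function(junctions, dimension = c("radius", "length"),
                                 tol = 1e-5) {
  dimension <- match.arg(dimension)
  j <- asJunctionFrame(junctions)
  if (!nrow(j)) stop("insufficient data: no junction records")
  pcol <- if (dimension == "radius") "r_parent" else "l_parent"
  ccol <- if (dimension == "radius") "r_children" else "l_children"
  vals <- vapply(seq_len(nrow(j)), function(i)
    solveConservationExponent(j[[pcol]][i], j[[ccol]][[i]], tol = tol),
    numeric(1))
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  if (n < 2L)
    stop("insufficient data: fewer than 2 junctions with a defined exponent")
  m <- mean(vals)
  s <- stats::sd(vals)
  hw <- 1.96 * s / sqrt(n)
  new("ExponentEstimate", method = "conservation", dimension = dimension,
      value = m, ciLow = m - hw, ciHigh = m + hw, n = as.integer(n),
      sigma = s, rSquared = NA_real_)
}

#' Child/parent scale-factor pairs
#'
#' Computes the scale factors beta = r_child / r_parent and gamma =
#' l_child / l_parent for every parent-child pair at a dichotomous junction
#' (exactly two non-loop children) in which both segments are
#' well-segmented.
#'
#' @param tab a segment table or \linkS4class{VesselTree}.
#' @return data.frame with columns \code{subject_id}, \code{parent_id},
#'   \code{segment_id}, \code{beta}, \code{gamma}.
#' @export
scaleFactorPairs <- function(tab) {
  if (is(tab, "VesselTree")) tab <- tab@segments
  tab <- validateSegmentTable(tab)
  if (!"well_segmented" %in% names(tab)) tab$well_segmented <- TRUE
  if (!"in_loop" %in% names(tab)) tab$in_loop <- FALSE
  out <- list()
  for (sub in unique(tab$subject_id)) {
    rows <- tab[tab$subject_id == sub, , drop = FALSE]
    kids <- rows[!is.na(rows$parent_id) & !rows$in_loop, , drop = FALSE]
    if (!nrow(kids)) next
    nChild <- table(kids$parent_id)
    for (pid in names(nChild)[nChild == 2L]) {
      prow <- rows[as.character(rows$segment_id) == pid, , drop = FALSE]
      if (!nrow(prow) || !prow$well_segmented[1] || prow$in_loop[1]) next
      ch <- kids[as.character(kids$parent_id) == pid &
                   kids$well_segmented, , drop = FALSE]
      if (!nrow(ch)) next
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sub, parent_id = prow$segment_id[1],
        segment_id = ch$segment_id,
        beta = ch$radius_mm / prow$radius_mm[1],
        gamma = ch$length_mm / prow$length_mm[1])
    }
  }
  if (!length(out))
    return(data.frame(subject_id = character(0), parent_id = integer(0),
                      segment_id = integer(0), beta = numeric(0),
                      gamma = numeric(0)))
  do.call(rbind, out)
}

#' Ratio-based scaling exponent
#'
#' Per-pair exponents \code{-log2(beta)} (radius) or \code{-log2(gamma)}
#' (length) averaged over all dichotomous parent-child pairs; for a
#' symmetric self-similar tree these equal the conservation solution
#' exactly. The 95% CI is 1.96 standard errors on the mean.
#'
#' @param pairs output of \code{\link{scaleFactorPairs}} (or a segment
#'   table / \linkS4class{VesselTree}, converted automatically).
#' @param dimension \code{"radius"} or \code{"length"}.
#' @return An \linkS4class{ExponentEstimate}.
#' @export
ratioEstimate <- function(pairs, dimension = c("radius", "length")) {
  dimension <- match.arg(dimension)
  if (is(pairs, "VesselTree") ||
      (is.data.frame(pairs) && !"beta" %in% names(pairs)))
    pairs <- scaleFactorPairs(pairs)
  ratio <- if (dimension == "radius") pairs$beta else pairs$gamma
  if (length(ratio) < 2L)
    stop("insufficient data: fewer than 2 parent-child pairs")
  if (any(ratio <= 0)) stop("scale factors must be positive")
  vals <- -log2(ratio)
  m <- mean(vals)
  s <- stats::sd(vals)
  hw <- 1.96 * s / sqrt(length(vals))
  new("ExponentEstimate", method = "ratio", dimension = dimension,
      value = m, ciLow = m - hw, ciHigh = m + hw,
      n = as.integer(length(vals)), sigma = s, rSquared = NA_real_)
}

# one distribution fit at a fixed binning configuration; returns the
# exponent plus the central-fit bookkeeping
distributionFitOnce <- function(values, n_bins, n_discard) {
  lv <- log(values)
  rg <- range(lv)
  if (diff(rg) == 0)
    stop("degenerate fit: all values identical")
  breaks <- seq(rg[1], rg[2], length.out = n_bins + 1)
  bin <- findInterval(lv, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  keepBins <- setdiff(seq_len(n_bins), seq_len(n_discard))
  counts <- tabulate(bin, nbins = n_bins)
  nonEmpty <- intersect(keepBins, which(counts > 0))
  if (length(nonEmpty) < 3L)
    stop("insufficient bins: fewer than 3 retained non-empty bins")
  relFreq <- counts[nonEmpty] / length(values)
  xMean <- vapply(nonEmpty, function(bk) mean(values[bin == bk]), numeric(1))
  fit <- smaFit(log(xMean), log(relFreq))
  list(exponent = -1 / fit@slope, fit = fit,
       nRetained = sum(counts[nonEmpty]))
}

#' Distribution-based scaling exponent
#'
#' For an idealized self-similar network the vessel-size distribution is a
#' power law with exponent -1/a (radius) or -1/b (length). The estimator
#' bins log-transformed sizes (default 20 bins), discards the initial bins
#' where censoring near the resolution limit makes small-vessel counts
#' unreliable (default 5 for radius, 7 for length), drops empty bins, and
#' SMA-fits the log relative frequency per bin against the log mean size in
#' the bin; the exponent is -1/slope. The 95% CI is the middle-95% range of
#' exponents over all alternative binnings with \code{n_bins} and
#' \code{n_discard} varied by up to +/-3 (discard floored at 0).
#'
#' @param values vessel radii or lengths (mm); at least 30 must survive the
#'   discarded bins.
#' @param dimension \code{"radius"} or \code{"length"} (sets the default
#'   \code{n_discard}).
#' @param n_bins number of equal-width log bins (default 20).
#' @param n_discard initial bins discarded; default 5 (radius) or 7 (length).
#' @param resample_range maximum perturbation of both binning parameters
#'   when resampling the CI (default 3).
#' @return An \linkS4class{ExponentEstimate} (slot \code{rSquared} from the
#'   central fit).
#' @export
distributionEstimate <- function(values, dimension = c("radius", "length"),
                                 n_bins = 20, n_discard = NULL,
                                 resample_range = 3) {
  dimension <- match.arg(dimension)
  if (is.null(n_discard))
    n_discard <- if (dimension == "radius") 5L else 7L
  if (n_bins <= n_discard + 2)
    stop("n_bins must exceed n_discard + 2")
  values <- values[is.finite(values) & values > 0]
  central <- distributionFitOnce(values, n_bins, n_discard)
  if (central$nRetained < 30L)
    stop("insufficient data: fewer than 30 values survive the discarded bins")
  alt <- c()
  for (nb in (n_bins - resample_range):(n_bins + resample_range)) {
    for (dsc in max(0, n_discard - resample_range):(n_discard +
                                                    resample_range)) {
      if (nb <= dsc + 2) next
      e <- tryCatch(distributionFitOnce(values, nb, dsc)$exponent,
                    error = function(e) NA_real_)
      alt <- c(alt, e)
    }
  }
  alt <- alt[is.finite(alt)]
  ci <- if (length(alt) >= 2)
    stats::quantile(alt, c(0.025, 0.975), names = FALSE)
  else rep(central$exponent, 2)
  new("ExponentEstimate", method = "distribution", dimension = dimension,
      value = central$exponent, ciLow = ci[1], ciHigh = ci[2],
      n = as.integer(central$nRetained), sigma = NA_real_,
      rSquared = central$fit@rSquared)
}

#' Regression-based scaling exponent
#'
#' SMA regression of log vessel dimension against the log number of
#' downstream tips over all well-segmented segments: for self-similar
#' networks r ~ Nd^a and l ~ Nd^b, so the slope estimates the exponent.
#'
#' @param tab a segment table or \linkS4class{VesselTree} with
#'   \code{n_downstream_tips}.
#' @param dimension \code{"radius"} or \code{"length"}.
#' @return An \linkS4class{ExponentEstimate} (CI and R^2 from the SMA fit).
#' @export
regressionEstimate <- function(tab, dimension = c("radius", "length")) {
  dimension <- match.arg(dimension)
  if (is(tab, "VesselTree")) tab <- tab@segments
  tab <- validateSegmentTable(tab)
  if (!"well_segmented" %in% names(tab)) tab$well_segmented <- TRUE
  if (is.null(tab$n_downstream_tips))
    stop("segment table lacks n_downstream_tips")
  use <- tab[tab$well_segmented & tab$n_downstream_tips >= 1L, , drop = FALSE]
  if (nrow(use) < 3L)
    stop("insufficient data: fewer than 3 well-segmented segments")
  x <- log(use$n_downstream_tips)
  if (stats::sd(x) == 0)
    stop("degenerate fit: all segments have the same number of tips")
  y <- log(if (dimension == "radius") use$radius_mm else use$length_mm)
  fit <- smaFit(x, y)
  new("ExponentEstimate", method = "regression", dimension = dimension,
      value = fit@slope, ciLow = fit@ciLow, ciHigh = fit@ciHigh,
      n = as.integer(nrow(use)), sigma = NA_real_, rSquared = fit@rSquared)
}

#' Welch's t-test between two exponent estimates
#'
#' Compares two estimates from their means and standard errors (taken from
#' \code{sigma/sqrt(N)} for node-level estimates, or from the CI half-width
#' divided by 1.96 otherwise) using the Welch-Satterthwaite approximation.
#'
#' @param e1,e2 \linkS4class{ExponentEstimate} objects.
#' @return list with \code{t}, \code{df} and the two-sided \code{p}.
#' @export
welchCompare <- function(e1, e2) {
  se <- function(e) {
    if (is.finite(e@sigma)) return(e@sigma / sqrt(e@n))
    hw <- (e@ciHigh - e@ciLow) / 2
    if (!is.finite(hw)) stop("estimate carries no standard error")
    hw / 1.96
  }
  s1 <- se(e1); s2 <- se(e2)
  t <- (e1@value - e2@value) / sqrt(s1^2 + s2^2)
  df <- (s1^2 + s2^2)^2 / (s1^4 / (e1@n - 1) + s2^4 / (e2@n - 1))
  p <- if (t == 0) 1 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' All eight scaling-exponent estimates
#'
#' Runs the four estimators for both dimensions on a segment table or
#' \linkS4class{VesselTree} and returns the summary in one data.frame
#' (method, dimension, N, value, 95% CI bounds, sigma, R^2). Estimators
#' that cannot run on the data (e.g. too few junctions) produce NA rows
#' rather than aborting the others.
#'
#' @param x segment table or \linkS4class{VesselTree}.
#' @param n_bins,resample_range distribution-fit configuration.
#' @param warn report estimator failures as warnings.
#' @return data.frame with 8 rows.
#' @export
scalingExponentTable <- function(x, n_bins = 20, resample_range = 3,
                                 warn = FALSE) {
  tab <- if (is(x, "VesselTree")) x@segments else validateSegmentTable(x)
  if (!"well_segmented" %in% names(tab)) tab$well_segmented <- TRUE
  junc <- if (is(x, "VesselTree")) x@junctions else NULL
  ws <- tab[tab$well_segmented, , drop = FALSE]
  rows <- list()
  for (dimension in c("radius", "length")) {
    ests <- list(
      conservation = function() conservationEstimate(
        if (is.null(junc)) tab else junc, dimension),
      ratio = function() ratioEstimate(x, dimension),
      distribution = function() distributionEstimate(
        if (dimension == "radius") ws$radius_mm else ws$length_mm,
        dimension, n_bins = n_bins, resample_range = resample_range),
      regression = function() regressionEstimate(tab, dimension))
    for (method in names(ests)) {
      e <- tryCatch(ests[[method]](), error = function(err) {
        if (warn) warning(method, "-based ", dimension, " estimate failed: ",
                          conditionMessage(err), call. = FALSE)
        NULL
      })
      rows[[length(rows) + 1L]] <- if (is.null(e))
        data.frame(method = method, dimension = dimension, N = NA_integer_,
                   value = NA_real_, ci95_low = NA_real_,
                   ci95_high = NA_real_, sigma = NA_real_,
                   r_squared = NA_real_)
      else
        data.frame(method = e@method, dimension = e@dimension, N = e@n,
                   value = e@value, ci95_low = e@ciLow, ci95_high = e@ciHigh,
                   sigma = e@sigma, r_squared = e@rSquared)
    }
  }
  do.call(rbind, rows)
}
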