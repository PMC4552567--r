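#' Standard major axis regression
#'
#' Symmetric line fitting for the case where both variables carry comparable
#' error, as is true of log-transformed vessel dimensions: the slope is
#' \code{sign(cor(x, y)) * sd(y) / sd(x)}, so the fit of y on x and of x on
#' y are exact inverses. The 95% CI on the slope is the closed form
#' \code{slope * (sqrt(B + 1) +/- sqrt(B))} with
#' \code{B = (1 - r^2) * t(0.975, n - 2)^2 / (n - 2)}.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with positive
#'   standard deviation.
#' @return An \linkS4class{SMAFit}.
#' @examples
#' f <- smaFit(0:4, 2 * (0:4) + 1)
#' c(f@slope, f@intercept, f@rSquared)   # 2, 1, 1
#' @export
smaFit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("SMA fit needs at least 3 points")
  sdx <- stats::sd(x)
  sdy <- stats::sd(y)
  if (sdx == 0 || sdy == 0)
    stop("degenerate SMA fit: zero variance in ",
         if (sdx == 0) "x" else "y")
  r <- stats::cor(x, y)
  if (r == 0)
    stop("SMA slope sign is undefined at zero correlation")
  slope <- sign(r) * sdy / sdx
  intercept <- mean(y) - slope * mean(x)
  B <- (1 - r^2) * stats::qt(0.975, n - 2)^2 / (n - 2)
  ci <- sort(slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  new("SMAFit", slope = slope, intercept = intercept, rSquared = r^2,
      ciLow = ci[1], ciHigh = ci[2], n = as.integer(n))
}
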