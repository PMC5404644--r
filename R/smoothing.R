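#' Smoothing weight between two grid points
#'
#' The influence of grid point `xj` (carrying neighbor covariance `sigma_j`)
#' on grid point `xi` in the covariance-smoothing pass:
#' `w = det(sigma_j)^(-1/2) * exp(-q/2)` with `q` the squared Mahalanobis
#' distance of `xi` from `xj` under `sigma_j`, truncated to 0 beyond the
#' cutoff radius. Grid points with large ellipsoids (low density) or far
#' from `xi` therefore contribute little, making the smoothing local. The
#' same weights average both the precision matrices and the effective-k
#' values.
#'
#' @param xi,xj numeric vectors of length d (d = 1 or 2).
#' @param sigma_j covariance at `xj`: a positive scalar (d = 1) or 2x2
#'   positive-definite matrix.
#' @param cutoff Mahalanobis truncation radius (default 4).
#' @return a nonnegative scalar weight.
#' @examples
#' smoothing_weight(0, 1, 1)   # exp(-1/2)
#' @export
smoothing_weight <- function(xi, xj, sigma_j, cutoff = 4) {
  xi <- as.numeric(xi)
  xj <- as.numeric(xj)
  stopifnot(length(xi) == length(xj), length(xi) %in% 1:2)
  S <- if (length(xi) == 1L) matrix(as.numeric(sigma_j), 1, 1)
       else as.matrix(sigma_j)
  dt <- det(S)
  if (dt <= 0) stop("sigma_j must be positive definite")
  dev <- xi - xj
  q <- drop(crossprod(dev, solve(S, dev)))
  if (q > cutoff^2) return(0)
  dt^(-1 / 2) * exp(-q / 2)
}
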