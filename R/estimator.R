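#' Rescale a sample to unit per-axis variance
#'
#' Divides each coordinate axis by its sample standard deviation. The
#' estimator always works in these rescaled coordinates: without the
#' rescaling, Euclidean neighbor queries would behave as if distances were
#' measured with ellipsoids rather than spheres. Per-axis scaling (rather
#' than sphering) preserves the correlations, so the covariance matrix of
#' the rescaled sample is its correlation matrix.
#'
#' @param x numeric matrix (or vector for d = 1) of observations, one per row.
#' @return an object of class `"scaled_points"`: list with `coords` (M x d
#'   rescaled matrix), `scales` (the per-axis standard deviations),
#'   `sigma_P` (covariance of the rescaled sample), `M`, `d`.
#' @export
rescale_points <- function(x) {
  x <- as_point_matrix(x)
  M <- nrow(x)
  d <- ncol(x)
  if (M < 2L) stop("at least two observations are required")
  scales <- apply(x, 2, sd)
  if (any(scales <= 0))
    stop("degenerate data: an axis has zero variance")
  z <- sweep(x, 2, scales, "/")
  structure(list(coords = z, scales = scales, sigma_P = cov(z), M = M, d = d),
            class = "scaled_points")
}

#' Smoothing-level constant H0
#'
#' The sample-size- and dimension-dependent constant that sets the overall
#' smoothing level: `0.028 * M^(4/5)` for d = 1 and `0.162 * M^(2/5)` for
#' d = 2 (the bivariate coefficient is close to the square root of the
#' univariate one, `sqrt(0.028) = 0.167`). These power laws were calibrated
#' once, by a visual criterion, and are not data-dependent; `h0_scale` lets
#' the user vary the coefficient, with discretion, within about a factor 2.
#'
#' @param M sample size.
#' @param d dimension, 1 or 2.
#' @param h0_scale positive multiplier on the coefficient (default 1).
#' @return the constant H0.
#' @export
h0_constant <- function(M, d, h0_scale = 1) {
  stopifnot(is.numeric(M), length(M) == 1L, M >= 1,
            is.numeric(h0_scale), length(h0_scale) == 1L, h0_scale > 0)
  if (identical(as.integer(d), 1L)) h0_scale * 0.028 * M^(4 / 5)
  else if (identical(as.integer(d), 2L)) h0_scale * 0.162 * M^(2 / 5)
  else stop("only dimensions 1 and 2 are supported")
}

#' Balance constant C2
#'
#' The threshold of the balance rule `V_k(x) * k >= C2` that stops the
#' neighbor search at each grid point: `C2 = H0 * sqrt(det(Sigma_P))`, with
#' `Sigma_P` the covariance (= correlation) matrix of the rescaled sample.
#' For d = 1 it equals H0 exactly, since the rescaled variance is 1.
#'
#' @param scaled a [rescale_points()] result.
#' @param h0_scale passed to [h0_constant()].
#' @return the constant C2.
#' @export
balance_constant <- function(scaled, h0_scale = 1) {
  stopifnot(inherits(scaled, "scaled_points"))
  dt <- det(as.matrix(scaled$sigma_P))
  if (dt <= 0)
    stop("degenerate data: sample covariance is singular (collinear data)")
  h0_constant(scaled$M, scaled$d, h0_scale) * sqrt(dt)
}

#' Neighbor-set statistics
#'
#' Mean, population covariance (divisor k, describing the realized point
#' cloud) and ellipsoid volume `V = sqrt(det(Sigma))` of a set of points,
#' as accumulated for the k nearest neighbors of a probe.
#'
#' @param x the neighbor subset: numeric matrix (or vector for d = 1).
#' @return list with `k`, `mean`, `cov` (d x d matrix), `volume`.
#' @export
neighbor_stats <- function(x) {
  x <- as_point_matrix(x)
  k <- nrow(x)
  mu <- colMeans(x)
  dev <- sweep(x, 2, mu)
  S <- crossprod(dev) / k
  list(k = k, mean = mu, cov = S, volume = sqrt(max(det(S), 0)))
}

#' Balanced adaptive density estimate
#'
#' Fits the balanced adaptive density estimator to a 1-D or 2-D sample.
#' The sample is rescaled to unit per-axis variance; on a regular grid
#' covering it, each grid point consumes nearest neighbors one at a time
#' until the balance rule `V_k(x) * k >= C2` first holds (capped at k = M),
#' where `V_k` is the volume of the neighbor covariance ellipsoid and `C2`
#' is the [balance_constant()]. The raw density is `k_e(x) / (M * V_k(x))`
#' with effective count `k_e(x) = k * exp(-Mahalanobis^2 / 2)` measured from
#' the neighbor mean, which enforces light exponential tails. Optionally a
#' smoothing pass replaces per-point precision matrices and effective counts
#' by Gaussian-weighted grid averages. The field is normalized to integrate
#' to 1 (Riemann sum on its own grid) and mapped back to original units.
#'
#' @param x sample: numeric vector, matrix or data frame (one observation
#'   per row, 1 or 2 columns).
#' @param grid_size grid points per axis (default 100).
#' @param margin grid extension beyond the data range, as a fraction of the
#'   range per axis (default 0.15).
#' @param h0_scale multiplier on the smoothing constant, sane range about
#'   \[0.5, 2\] (default 1).
#' @param smooth apply the covariance-smoothing pass (default `TRUE`).
#' @param k_min smallest neighbor count considered (default `d + 1`, the
#'   least that can give a nonsingular covariance).
#' @param cutoff Mahalanobis-distance truncation radius of the smoothing
#'   weights (default 4).
#' @param jitter nonnegative ridge added to near-singular neighbor
#'   covariances before inversion, in rescaled units (default 1e-10).
#' @return an object of class `"bade"`; see Details.
#' @details The returned object contains, in original units, `grid` (list of
#'   axis coordinate vectors), `estimate` (density values: a vector for
#'   d = 1, a `grid_size x grid_size` matrix for d = 2, axis 1 along rows),
#'   and `raw` (the unsmoothed field, normalized the same way). Per grid
#'   point diagnostics in rescaled coordinates: `k`, `ke`, `V`, `mu`, `cov`,
#'   and, when smoothed, `prec` (smoothed precision entries) and `ke_smooth`.
#'   Constants: `C2`, `H0`, `C` (normalization applied in rescaled
#'   coordinates), `scales`, `sigma_P`. Methods: `print`, `summary`, `plot`,
#'   `predict` (interpolates the density at new points), `simulate` (draws
#'   from the fitted field).
#' @examples
#' set.seed(1)
#' fit <- bade(rnorm(500), grid_size = 80)
#' fit
#' predict(fit, 0)
#' @export
bade <- function(x, grid_size = 100, margin = 0.15, h0_scale = 1,
                 smooth = TRUE, k_min = NULL, cutoff = 4, jitter = 1e-10) {
  cl <- match.call()
  sp <- rescale_points(x)
  d <- sp$d
  M <- sp$M
  if (is.null(k_min)) k_min <- d + 1L
  k_min <- as.integer(k_min)
  stopifnot(grid_size >= 2, margin >= 0, h0_scale > 0, k_min >= 1L,
            cutoff > 0, jitter >= 0)

  H0 <- h0_constant(M, d, h0_scale)
  C2 <- balance_constant(sp, h0_scale)

  axes_s <- lapply(seq_len(d), function(a) {
    r <- range(sp$coords[, a])
    w <- r[2] - r[1]
    seq(r[1] - margin * w, r[2] + margin * w, length.out = grid_size)
  })

  core <- cpp_bade_grid(sp$coords, axes_s, C2, k_min, jitter)

  if (smooth) {
    sm <- cpp_smooth_field(axes_s, core$cov, core$ke, cutoff, jitter)
    values_s <- sm$value
  } else {
    sm <- NULL
    values_s <- core$raw
  }

  dxs <- vapply(axes_s, function(a) a[2] - a[1], 0)
  cellv_s <- prod(dxs)
  C <- 1 / (cellv_s * sum(values_s))
  values_s <- C * values_s
  raw_s <- core$raw / (cellv_s * sum(core$raw))

  # back-transform: axes pick up the original units, the density the
  # reciprocal Jacobian; renormalize against float error
  axes <- Map(function(a, s) a * s, axes_s, as.list(sp$scales))
  jac <- prod(sp$scales)
  values <- values_s / jac
  raw <- raw_s / jac
  cellv <- cellv_s * jac
  values <- values / (cellv * sum(values))
  raw <- raw / (cellv * sum(raw))

  shape <- function(v) if (d == 2L) matrix(v, length(axes[[1]])) else v
  structure(list(
    estimate = shape(values), raw = shape(raw), grid = axes,
    grid_scaled = axes_s, cell_volume = cellv,
    k = core$k, ke = core$ke, V = core$V, mu = core$mu, cov = core$cov,
    ke_smooth = if (smooth) sm$ke else NULL,
    prec = if (smooth) sm$prec else NULL,
    C = C, C2 = C2, H0 = H0, scales = sp$scales, sigma_P = sp$sigma_P,
    scaled = sp, M = M, d = d,
    config = list(grid_size = grid_size, margin = margin,
                  h0_scale = h0_scale, smooth = smooth, k_min = k_min,
                  cutoff = cutoff, jitter = jitter),
    call = cl), class = "bade")
}

#' @export
print.bade <- function(x, ...) {
  cat(sprintf("Balanced adaptive density estimate (%d-D)\n", x$d))
  cat(sprintf("  sample size M = %d, grid %s (%d points)\n", x$M,
              paste(lengths(x$grid), collapse = " x "),
              prod(lengths(x$grid))))
  cat(sprintf("  balance constant C2 = %.4g, smoothing %s\n", x$C2,
              if (x$config$smooth) "on" else "off"))
  cat(sprintf("  selected k: mean %.1f, range [%d, %d]\n", mean(x$k),
              min(x$k), max(x$k)))
  cat(sprintf("  integral on grid = %.8f\n",
              x$cell_volume * sum(x$estimate)))
  invisible(x)
}

#' @export
summary.bade <- function(object, ...) {
  s <- list(
    d = object$d, M = object$M, grid = lengths(object$grid),
    C2 = object$C2, H0 = object$H0, smooth = object$config$smooth,
    k = quantile(object$k, c(0, .25, .5, .75, 1)),
    ke = quantile(object$ke, c(0, .25, .5, .75, 1)),
    peak = max(object$estimate),
    integral = object$cell_volume * sum(object$estimate))
  class(s) <- "summary.bade"
  s
}

#' @export
print.summary.bade <- function(x, ...) {
  cat(sprintf("Balanced adaptive density estimate (%d-D), M = %d\n", x$d, x$M))
  cat(sprintf("  grid: %s; C2 = %.4g; H0 = %.4g; smoothing %s\n",
              paste(x$grid, collapse = " x "), x$C2, x$H0,
              if (x$smooth) "on" else "off"))
  cat("  selected k quantiles:\n")
  print(round(x$k, 1))
  cat("  effective k quantiles:\n")
  print(round(x$ke, 2))
  cat(sprintf("  peak density %.5g; grid integral %.8f\n", x$peak, x$integral))
  invisible(x)
}

#' Interpolate a fitted density at new points
#'
#' Linear (d = 1) or bilinear (d = 2) interpolation of the fitted field;
#' points outside the grid get density 0.
#'
#' @param object a [bade()] fit.
#' @param newdata numeric vector or matrix of evaluation points.
#' @param ... unused.
#' @return numeric vector of density values.
#' @export
predict.bade <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata) || is.data.frame(newdata)) as.matrix(newdata)
       else if (object$d == 1L) matrix(as.numeric(newdata), ncol = 1)
       else matrix(as.numeric(newdata), ncol = 2)
  if (ncol(x) != object$d) stop("newdata dimension does not match fit")
  g1 <- object$grid[[1]]
  if (object$d == 1L) {
    out <- stats::approx(g1, as.vector(object$estimate), xout = x[, 1],
                         yleft = 0, yright = 0)$y
    return(out)
  }
  g2 <- object$grid[[2]]
  v <- object$estimate
  out <- numeric(nrow(x))
  i1 <- findInterval(x[, 1], g1)
  i2 <- findInterval(x[, 2], g2)
  ok <- i1 >= 1L & i1 < length(g1) & i2 >= 1L & i2 < length(g2)
  # points exactly on the upper edge still count as inside
  on1 <- x[, 1] == g1[length(g1)]
  on2 <- x[, 2] == g2[length(g2)]
  i1[on1] <- length(g1) - 1L
  i2[on2] <- length(g2) - 1L
  ok <- ok | (on1 & i2 >= 1L & (i2 < length(g2) | on2)) |
             (on2 & i1 >= 1L & (i1 < length(g1) | on1))
  w <- which(ok)
  if (length(w)) {
    j1 <- i1[w]; j2 <- i2[w]
    t1 <- (x[w, 1] - g1[j1]) / (g1[j1 + 1L] - g1[j1])
    t2 <- (x[w, 2] - g2[j2]) / (g2[j2 + 1L] - g2[j2])
    out[w] <- (1 - t1) * (1 - t2) * v[cbind(j1, j2)] +
      t1 * (1 - t2) * v[cbind(j1 + 1L, j2)] +
      (1 - t1) * t2 * v[cbind(j1, j2 + 1L)] +
      t1 * t2 * v[cbind(j1 + 1L, j2 + 1L)]
  }
  out
}

#' Draw observations from a fitted density field
#'
#' Samples grid cells proportionally to their density mass and jitters
#' uniformly within each cell.
#'
#' @param object a [bade()] fit.
#' @param nsim number of draws.
#' @param seed optional integer seed (self-contained stream).
#' @param ... unused.
#' @return an `nsim x d` numeric matrix.
#' @export
simulate.bade <- function(object, nsim = 1, seed = NULL, ...) {
  nsim <- as.integer(nsim)
  stopifnot(nsim >= 1L)
  with_seed(seed, {
    p <- as.vector(object$estimate)
    cell <- sample.int(length(p), nsim, replace = TRUE, prob = p / sum(p))
    g1 <- object$grid[[1]]
    dx <- vapply(object$grid, function(a) a[2] - a[1], 0)
    out <- matrix(0, nsim, object$d)
    i1 <- (cell - 1L) %% length(g1) + 1L
    out[, 1] <- g1[i1] + runif(nsim, -0.5, 0.5) * dx[1]
    if (object$d == 2L) {
      g2 <- object$grid[[2]]
      i2 <- (cell - 1L) %/% length(g1) + 1L
      out[, 2] <- g2[i2] + runif(nsim, -0.5, 0.5) * dx[2]
    }
    out
  })
}

#' Plot a fitted density
#'
#' d = 1: the density curve with a data rug. d = 2: a filled image with
#' contours and the sample overlaid.
#'
#' @param x a [bade()] fit.
#' @param points overlay the sample (default `TRUE`).
#' @param ... passed to the underlying base-graphics call.
#' @return the fit, invisibly.
#' @export
plot.bade <- function(x, points = TRUE, ...) {
  if (x$d == 1L) {
    graphics::plot(x$grid[[1]], as.vector(x$estimate), type = "l",
                   xlab = "x", ylab = "density", ...)
    if (points) graphics::rug(x$scaled$coords[, 1] * x$scales[1])
  } else {
    graphics::image(x$grid[[1]], x$grid[[2]], x$estimate,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "x", ylab = "y", ...)
    graphics::contour(x$grid[[1]], x$grid[[2]], x$estimate, add = TRUE,
                      drawlabels = FALSE)
    if (points)
      graphics::points(x$scaled$coords[, 1] * x$scales[1],
                       x$scaled$coords[, 2] * x$scales[2],
                       pch = 16, cex = 0.3)
  }
  invisible(x)
}
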