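#' Construct a Gaussian mixture
#'
#' Defines a finite mixture of 1-D or 2-D Gaussian components, used both as
#' a known test density and as a sampling distribution. Univariate
#' components are parameterized by their standard deviation `sd` (not the
#' variance); bivariate components by full 2x2 covariance matrices.
#'
#' @param weights positive component weights; must sum to 1 (within 1e-12,
#'   after which they are renormalized exactly).
#' @param means for `d = 1` a numeric vector of component means; for `d = 2`
#'   a list of length-2 vectors (or a matrix with one row per component).
#' @param sd univariate only: vector of component standard deviations.
#' @param cov bivariate only: list of symmetric positive-definite 2x2
#'   covariance matrices.
#' @return An object of class `"gaussian_mixture"` with fields `weights`,
#'   `means`, `sd` or `cov`, and dimension `d`.
#' @seealso [test_density()] for the six built-in validation densities,
#'   [dmixture()], [rmixture()].
#' @examples
#' m <- gaussian_mixture(c(2, 1) / 3, means = c(0, 0), sd = c(1, 0.1))
#' dmixture(0, m)
#' @export
gaussian_mixture <- function(weights, means, sd = NULL, cov = NULL) {
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1")
  weights <- weights / sum(weights)
  nc <- length(weights)
  if (is.null(sd) == is.null(cov))
    stop("supply exactly one of 'sd' (d = 1) or 'cov' (d = 2)")

  if (!is.null(sd)) {
    d <- 1L
    means <- as.numeric(means)
    sd <- as.numeric(sd)
    if (length(means) != nc || length(sd) != nc)
      stop("means and sd must have one entry per component")
    if (any(!is.finite(means)) || any(!is.finite(sd)) || any(sd <= 0))
      stop("component standard deviations must be positive and finite")
    out <- list(weights = weights, means = means, sd = sd, cov = NULL, d = d)
  } else {
    d <- 2L
    if (is.matrix(means)) means <- lapply(seq_len(nrow(means)), function(i) means[i, ])
    if (!is.list(means) || length(means) != nc ||
        any(vapply(means, length, 0L) != 2L))
      stop("for d = 2, means must be a list of length-2 vectors (one per component)")
    means <- lapply(means, as.numeric)
    if (!is.list(cov) || length(cov) != nc)
      stop("cov must be a list with one 2x2 matrix per component")
    cov <- lapply(cov, function(S) {
      S <- as.matrix(S)
      if (!all(dim(S) == c(2, 2)) || any(!is.finite(S)))
        stop("each covariance must be a finite 2x2 matrix")
      if (max(abs(S - t(S))) > 1e-12 * max(1, max(abs(S))))
        stop("covariance matrices must be symmetric")
      S <- (S + t(S)) / 2
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) stop("covariance matrices must be positive definite")
      S
    })
    out <- list(weights = weights, means = means, sd = NULL, cov = cov, d = d)
  }
  class(out) <- "gaussian_mixture"
  out
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d component(s), d = %d\n",
              length(x$weights), x$d))
  for (i in seq_along(x$weights)) {
    if (x$d == 1L)
      cat(sprintf("  w = %-8.5g mean = %-8.5g sd = %.5g\n",
                  x$weights[i], x$means[i], x$sd[i]))
    else
      cat(sprintf("  w = %-8.5g mean = (%g, %g)  cov = [%g %g; %g %g]\n",
                  x$weights[i], x$means[[i]][1], x$means[[i]][2],
                  x$cov[[i]][1, 1], x$cov[[i]][1, 2],
                  x$cov[[i]][2, 1], x$cov[[i]][2, 2]))
  }
  invisible(x)
}

#' Mixture density
#'
#' Evaluates the probability density function of a Gaussian mixture at a set
#' of points: the weighted sum of component normal densities.
#'
#' @param x evaluation points: a numeric vector (d = 1) or a matrix with `d`
#'   columns, one point per row.
#' @param mix a [gaussian_mixture()].
#' @return numeric vector of density values, one per point.
#' @export
dmixture <- function(x, mix) {
  stopifnot(inherits(mix, "gaussian_mixture"))
  if (mix$d == 1L) {
    if (is.matrix(x)) {
      if (ncol(x) != 1L) stop("dimension mismatch: mixture has d = 1")
      x <- x[, 1]
    }
    out <- numeric(length(x))
    for (i in seq_along(mix$weights))
      out <- out + mix$weights[i] * dnorm(x, mix$means[i], mix$sd[i])
    out
  } else {
    x <- if (is.matrix(x)) x else matrix(x, ncol = 2)
    if (ncol(x) != 2L) stop("dimension mismatch: mixture has d = 2")
    out <- numeric(nrow(x))
    for (i in seq_along(mix$weights))
      out <- out + mix$weights[i] *
        mclust::dmvnorm(x, mean = mix$means[[i]], sigma = mix$cov[[i]])
    out
  }
}

#' Sample from a Gaussian mixture
#'
#' Draws i.i.d. observations: a component index from the weight vector, then
#' a (multivariate) normal draw from that component. With a `seed` the call
#' is fully reproducible and leaves the caller's RNG stream untouched.
#'
#' @param n number of draws (at least 1).
#' @param mix a [gaussian_mixture()].
#' @param seed optional integer seed for a self-contained RNG stream.
#' @return an `n x d` numeric matrix, one draw per row.
#' @export
rmixture <- function(n, mix, seed = NULL) {
  stopifnot(inherits(mix, "gaussian_mixture"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1")
  with_seed(seed, {
    comp <- sample.int(length(mix$weights), n, replace = TRUE,
                       prob = mix$weights)
    if (mix$d == 1L) {
      matrix(rnorm(n, mean = mix$means[comp], sd = mix$sd[comp]), ncol = 1)
    } else {
      out <- matrix(0, n, 2)
      for (ci in seq_along(mix$weights)) {
        rows <- which(comp == ci)
        if (!length(rows)) next
        L <- chol(mix$cov[[ci]])
        z <- matrix(rnorm(2L * length(rows)), ncol = 2)
        out[rows, ] <- sweep(z %*% L, 2, mix$means[[ci]], "+")
      }
      out
    }
  })
}

#' Standard validation densities
#'
#' The six Gaussian-mixture test densities used by the validation study.
#' H3--H5 are univariate (kurtotic unimodal, asymmetric bimodal, symmetric
#' trimodal; the Hazelton / Marron--Wand suite), F2--F4 bivariate (bimodal,
#' trimodal, "dumbbell" unimodal; the Zougab / Wand--Jones suite).
#'
#' @param name one of `"H3"`, `"H4"`, `"H5"`, `"F2"`, `"F3"`, `"F4"`.
#' @return a [gaussian_mixture()].
#' @examples
#' test_density("H3")
#' @export
test_density <- function(name) {
  name <- match.arg(toupper(name), c("H3", "H4", "H5", "F2", "F3", "F4"))
  switch(name,
    H3 = gaussian_mixture(c(2 / 3, 1 / 3), means = c(0, 0), sd = c(1, 1 / 10)),
    H4 = gaussian_mixture(c(4 / 5, 1 / 5), means = c(0, 2), sd = c(1, 1 / 5)),
    H5 = gaussian_mixture(c(9 / 20, 9 / 20, 1 / 10),
                          means = c(-7 / 4, 7 / 4, 0), sd = c(1, 1, 1 / 5)),
    F2 = gaussian_mixture(c(1 / 2, 1 / 2),
                          means = list(c(1, 1), c(-1, -1)),
                          cov = list(matrix(c(1, 1 / 2, 1 / 2, 1), 2),
                                     matrix(c(1, -1 / 2, -1 / 2, 1), 2))),
    F3 = gaussian_mixture(c(3 / 7, 3 / 7, 1 / 7),
                          means = list(c(-1, 0), c(1, 2 / 3), c(1, -2 / 3)),
                          cov = list(
                            matrix(c(9 / 25, 63 / 250, 63 / 250, 49 / 100), 2),
                            diag(c(9 / 25, 9 / 25)),
                            diag(c(9 / 25, 9 / 25)))),
    F4 = gaussian_mixture(c(4 / 11, 3 / 11, 4 / 11),
                          means = list(c(-2, 2), c(0, 0), c(2, -2)),
                          cov = list(diag(2),
                                     matrix(c(0.8, -0.72, -0.72, 0.8), 2),
                                     diag(2))))
}
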