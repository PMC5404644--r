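# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: plain sorting, dense matrix algebra and
# closed forms only.

# Full-sequence retrieval from an incremental stream.
stream_all <- function(index, probe, n = index$M) {
  nn_next(nn_stream(index, probe), n)
}

# Bivariate normal pdf by the explicit closed form (no package code).
dnorm2_ref <- function(x, mu, S) {
  a <- S[1, 1]; b <- S[1, 2]; c <- S[2, 2]
  dt <- a * c - b * b
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  q <- (c * dx^2 - 2 * b * dx * dy + a * dy^2) / dt
  exp(-q / 2) / (2 * pi * sqrt(dt))
}

# Population covariance-ellipsoid volume of the first k naive neighbors of
# `probe` within the rescaled sample `z`.
naive_volume <- function(z, probe, k) {
  nb <- order(if (ncol(z) == 1L) abs(z[, 1] - probe[1])
              else sqrt((z[, 1] - probe[1])^2 + (z[, 2] - probe[2])^2),
              seq_len(nrow(z)))
  sub <- z[nb[seq_len(k)], , drop = FALSE]
  mu <- colMeans(sub)
  dev <- sweep(sub, 2, mu)
  S <- crossprod(dev) / k
  sqrt(max(det(S), 0))
}

# Brute-force balance search: smallest k in [k_min, M] with V_k * k >= C2,
# else M. Evaluates every k from scratch.
brute_optimal_k <- function(z, probe, C2, k_min) {
  M <- nrow(z)
  for (k in seq(k_min, M)) {
    if (naive_volume(z, probe, k) * k >= C2) return(k)
  }
  M
}

# Reference implementation of the covariance-smoothing pass: dense double
# loop over grid points, truncated Gaussian weights, returning unnormalized
# smoothed density values in grid (first-axis-fastest) order.
ref_smooth <- function(axes, cov_entries, ke, cutoff) {
  d <- length(axes)
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  G <- nrow(pts)
  prec <- vector("list", G)
  dets <- numeric(G)
  for (j in seq_len(G)) {
    S <- if (d == 1L) matrix(cov_entries[j, 1], 1, 1)
         else matrix(c(cov_entries[j, 1], cov_entries[j, 2],
                       cov_entries[j, 2], cov_entries[j, 3]), 2)
    prec[[j]] <- solve(S)
    dets[j] <- det(S)
  }
  den <- numeric(G)
  num_k <- numeric(G)
  num_p <- lapply(seq_len(G), function(i) matrix(0, d, d))
  for (j in seq_len(G)) {
    pj <- prec[[j]]
    wpre <- dets[j]^(-1 / 2)
    for (i in seq_len(G)) {
      dev <- pts[i, ] - pts[j, ]
      q <- drop(crossprod(dev, pj %*% dev))
      if (q > cutoff^2) next
      w <- wpre * exp(-q / 2)
      den[i] <- den[i] + w
      num_k[i] <- num_k[i] + w * ke[j]
      num_p[[i]] <- num_p[[i]] + w * pj
    }
  }
  vapply(seq_len(G), function(i) {
    P <- num_p[[i]] / den[i]
    (num_k[i] / den[i]) * sqrt(det(P))
  }, numeric(1))
}

# Random point sets, optionally tie-rich (points on a coarse half-integer
# lattice so many pairs are exactly equidistant from lattice probes).
rand_points <- function(M, d, ties = FALSE) {
  if (ties) matrix(sample(0:8, M * d, replace = TRUE) / 2, ncol = d)
  else matrix(rnorm(M * d), ncol = d)
}
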