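test_that("rescaling gives unit per-axis variance and keeps correlations", {
  z <- rescale_points(c(0, 2, 4))
  expect_equal(sd(z$coords[, 1]), 1, tolerance = 1e-12)
  expect_equal(z$scales[1], sd(c(0, 2, 4)))
  expect_equal(drop(z$sigma_P), 1, tolerance = 1e-12)

  # already unit-variance data is unchanged
  set.seed(2)
  u <- rnorm(50)
  u <- u / sd(u)
  expect_equal(rescale_points(u)$coords[, 1], u, tolerance = 1e-12)

  # correlation is invariant under per-axis scaling
  set.seed(3)
  a <- rnorm(400)
  x <- cbind(a, 0.9 * a + sqrt(1 - 0.81) * rnorm(400))
  z2 <- rescale_points(x)
  expect_equal(z2$sigma_P[1, 2], cor(x)[1, 2], tolerance = 1e-12)
  expect_equal(apply(z2$coords, 2, sd), c(1, 1), tolerance = 1e-12)

  expect_error(rescale_points(rep(1, 5)), "zero variance")
  expect_error(rescale_points(3), "at least two")
})

test_that("smoothing-level constant follows its power laws", {
  expect_identical(h0_constant(1, 1), 0.028)
  expect_identical(h0_constant(1, 2), 0.162)
  expect_equal(h0_constant(100, 1), 0.028 * 100^0.8, tolerance = 1e-15)
  expect_equal(h0_constant(100, 1), 1.1147001, tolerance = 1e-6)
  expect_equal(h0_constant(50, 2, h0_scale = 1.5),
               1.5 * 0.162 * 50^0.4, tolerance = 1e-15)
  expect_error(h0_constant(10, 3), "dimensions 1 and 2")
})

test_that("balance constant factors out the sample ellipsoid volume", {
  set.seed(4)
  z1 <- rescale_points(rnorm(200))
  expect_equal(balance_constant(z1), h0_constant(200, 1), tolerance = 1e-12)

  x <- cbind(rnorm(400), rnorm(400))
  z2 <- rescale_points(x)
  rho <- cor(x)[1, 2]
  expect_equal(balance_constant(z2),
               h0_constant(400, 2) * sqrt(1 - rho^2), tolerance = 1e-10)

  # perfectly collinear bivariate data is degenerate
  a <- rnorm(50)
  expect_error(balance_constant(rescale_points(cbind(a, 2 * a))),
               "singular")
})

test_that("neighbor statistics use the population covariance", {
  s <- neighbor_stats(c(-1, 0, 1))
  expect_equal(s$mean, 0)
  expect_equal(drop(s$cov), 2 / 3)
  expect_equal(s$volume, sqrt(2 / 3), tolerance = 1e-12)

  s0 <- neighbor_stats(rep(2.5, 4))
  expect_equal(drop(s0$cov), 0)
  expect_equal(s0$volume, 0)

  sq <- neighbor_stats(matrix(c(0, 1, 0, 1, 0, 0, 1, 1), ncol = 2))
  expect_equal(sq$mean, c(0.5, 0.5))
  expect_equal(sq$cov, diag(c(0.25, 0.25)))
  expect_equal(sq$volume, 0.25)
})

test_that("per-grid-point k matches the brute-force balance search", {
  set.seed(12)
  fit <- bade(runif(20, 0, 4), grid_size = 25, smooth = FALSE)
  z <- fit$scaled$coords
  probes <- fit$grid_scaled[[1]]
  for (g in seq_along(probes)) {
    expect_equal(fit$k[g],
                 brute_optimal_k(z, probes[g], fit$C2, fit$config$k_min))
  }

  # bivariate spot check on a smaller grid
  set.seed(13)
  fit2 <- bade(matrix(rnorm(120), ncol = 2), grid_size = 9, smooth = FALSE)
  pts <- as.matrix(expand.grid(fit2$grid_scaled))
  for (g in seq_len(nrow(pts))) {
    expect_equal(fit2$k[g],
                 brute_optimal_k(fit2$scaled$coords, pts[g, ], fit2$C2,
                                 fit2$config$k_min))
  }
})

test_that("effective k and raw density follow their defining formulas", {
  set.seed(21)
  fit <- bade(matrix(rnorm(300), ncol = 2), grid_size = 15, smooth = FALSE)
  pts <- as.matrix(expand.grid(fit$grid_scaled))
  for (g in seq_len(nrow(pts))) {
    S <- matrix(c(fit$cov[g, 1], fit$cov[g, 2],
                  fit$cov[g, 2], fit$cov[g, 3]), 2)
    dev <- pts[g, ] - fit$mu[g, ]
    q <- drop(crossprod(dev, solve(S, dev)))
    expect_equal(fit$ke[g], fit$k[g] * exp(-q / 2), tolerance = 1e-9)
    expect_equal(fit$V[g]^2, det(S), tolerance = 1e-9)
  }
  expect_true(all(fit$ke >= 0 & fit$ke <= fit$k))

  # unnormalized density is k_e / (M V): the normalized field is proportional
  keep <- fit$ke > 1e-12
  ratio <- as.vector(fit$raw)[keep] /
    (fit$ke[keep] / (fit$M * fit$V[keep]))
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("estimated fields are normalized, nonnegative and consistent", {
  set.seed(31)
  for (smooth in c(TRUE, FALSE)) {
    f1 <- bade(rnorm(400), grid_size = 80, smooth = smooth)
    expect_true(all(is.finite(f1$estimate)) && all(f1$estimate >= 0))
    expect_equal(f1$cell_volume * sum(f1$estimate), 1, tolerance = 1e-6)

    f2 <- bade(rmixture(300, test_density("F4"), seed = 8),
               grid_size = 40, smooth = smooth)
    expect_true(all(is.finite(f2$estimate)) && all(f2$estimate >= 0))
    expect_equal(f2$cell_volume * sum(f2$estimate), 1, tolerance = 1e-6)
  }

  # recovery of the standard normal near its mode
  x <- rmixture(2000, gaussian_mixture(1, 0, sd = 1), seed = 5)
  fr <- bade(x)
  expect_lt(abs(predict(fr, 0) - dnorm(0)) / dnorm(0), 0.15)
})

test_that("axis scaling is an exact equivariance of the estimator", {
  set.seed(41)
  x <- rnorm(250)
  f <- bade(x, grid_size = 50)
  f4 <- bade(4 * x, grid_size = 50)     # power of two: exact arithmetic
  expect_equal(f4$grid[[1]], 4 * f$grid[[1]], tolerance = 1e-14)
  expect_equal(as.vector(f4$estimate), as.vector(f$estimate) / 4,
               tolerance = 1e-12)

  y <- matrix(rnorm(300), ncol = 2)
  g <- bade(y, grid_size = 25)
  g2 <- bade(sweep(y, 2, c(4, 0.5), "*"), grid_size = 25)
  expect_equal(as.vector(g2$estimate), as.vector(g$estimate) / 2,
               tolerance = 1e-12)
})

test_that("light tails and balanced duality hold on the six test densities", {
  for (nm in c("H3", "H4", "H5", "F2", "F3", "F4")) {
    mix <- test_density(nm)
    fit <- bade(rmixture(1000, mix, seed = 17), margin = 0.3,
                grid_size = if (mix$d == 1L) 100 else 60)
    v <- fit$estimate
    edge <- if (mix$d == 1L) c(v[1], v[length(v)])
            else c(v[1, ], v[nrow(v), ], v[, 1], v[, ncol(v)])
    expect_lt(max(edge), 0.1 * max(v))
    # regions of many (effective) neighbors are regions of small ellipsoids
    expect_lt(cor(fit$ke, fit$V, method = "spearman"), 0)
  }
})

test_that("degenerate inputs raise degenerate-data errors", {
  expect_error(bade(rep(1, 10)), "zero variance")
  a <- rnorm(30)
  expect_error(bade(cbind(a, -0.5 * a)), "singular")
})
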