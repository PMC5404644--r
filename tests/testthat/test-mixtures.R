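test_that("mixture pdf matches closed-form normal values", {
  std <- gaussian_mixture(1, means = 0, sd = 1)
  expect_equal(dmixture(0, std), 1 / sqrt(2 * pi), tolerance = 1e-12)

  # kurtotic unimodal density at its spike
  h3 <- test_density("H3")
  expect_equal(dmixture(0, h3),
               (2 / 3) / sqrt(2 * pi) + (1 / 3) / (0.1 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(dmixture(0, h3), 1.595769, tolerance = 1e-6)

  # bivariate mixtures against the explicit closed form
  set.seed(7)
  x <- matrix(rnorm(40), ncol = 2)
  for (nm in c("F2", "F3", "F4")) {
    mix <- test_density(nm)
    ref <- rowSums(vapply(seq_along(mix$weights), function(i)
      mix$weights[i] * dnorm2_ref(x, mix$means[[i]], mix$cov[[i]]),
      numeric(nrow(x))))
    expect_equal(dmixture(x, mix), ref, tolerance = 1e-12)
  }
})

test_that("every standard density integrates to 1 on a wide fine grid", {
  for (nm in c("H3", "H4", "H5")) {
    mix <- test_density(nm)
    g <- seq(-8, 10, length.out = 20001)
    expect_equal(sum(dmixture(g, mix)) * (g[2] - g[1]), 1, tolerance = 1e-3)
  }
  for (nm in c("F2", "F3", "F4")) {
    mix <- test_density(nm)
    g <- seq(-8, 8, length.out = 401)
    pts <- as.matrix(expand.grid(g, g))
    expect_equal(sum(dmixture(pts, mix)) * (g[2] - g[1])^2, 1,
                 tolerance = 1e-3)
  }
})

test_that("standard densities carry the published parameters", {
  f4 <- test_density("F4")
  expect_equal(f4$weights, c(4, 3, 4) / 11)
  expect_equal(sum(f4$weights), 1)

  h4 <- test_density("H4")
  expect_equal(h4$weights, c(4 / 5, 1 / 5))
  expect_equal(h4$means, c(0, 2))
  expect_equal(h4$sd, c(1, 1 / 5))

  # symmetric trimodal: pdf even in x, exactly, on mirrored grid points
  h5 <- test_density("H5")
  g <- seq(0.017, 5, length.out = 211)
  expect_identical(dmixture(g, h5), dmixture(-g, h5))
  expect_length(h5$weights, 3)

  f2 <- test_density("F2")
  expect_equal(det(f2$cov[[1]]), 3 / 4, tolerance = 1e-12)
  expect_equal(det(f2$cov[[2]]), 3 / 4, tolerance = 1e-12)
})

test_that("sampler is seeded-deterministic and reproduces mixture moments", {
  h3 <- test_density("H3")
  a <- rmixture(5, h3, seed = 11)
  b <- rmixture(5, h3, seed = 11)
  expect_identical(a, b)
  expect_equal(dim(a), c(5L, 1L))

  f2 <- test_density("F2")
  a2 <- rmixture(7, f2, seed = 3)
  expect_identical(a2, rmixture(7, f2, seed = 3))
  expect_equal(dim(a2), c(7L, 2L))

  # law of large numbers: single standard normal component
  std <- gaussian_mixture(1, means = 0, sd = 1)
  x <- rmixture(1e5, std, seed = 1)[, 1]
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(var(x) - 1), 0.02)

  # categorical step: well-separated components make labels observable
  sep <- gaussian_mixture(c(4 / 5, 1 / 5), means = c(0, 100), sd = c(1, 1))
  y <- rmixture(1e5, sep, seed = 2)[, 1]
  expect_lt(abs(mean(y < 50) - 4 / 5), 0.01)

  # bivariate moments
  z <- rmixture(1e5, f2, seed = 4)
  expect_lt(max(abs(colMeans(z))), 0.03)        # mixture mean is (0, 0)
})

test_that("constructor and pdf reject invalid input", {
  expect_error(gaussian_mixture(c(0.5, 0.4), means = c(0, 1), sd = c(1, 1)),
               "sum to 1")
  expect_error(gaussian_mixture(c(-1, 2), means = c(0, 1), sd = c(1, 1)),
               "positive")
  expect_error(gaussian_mixture(1, means = 0, sd = -1), "positive")
  expect_error(gaussian_mixture(1, means = list(c(0, 0)),
                                cov = list(matrix(c(1, 2, 2, 1), 2))),
               "positive definite")
  expect_error(test_density("H9"))
  expect_error(rmixture(0, test_density("H3")), "at least 1")
  expect_error(dmixture(matrix(0, 1, 2), test_density("H3")),
               "dimension mismatch")
})
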