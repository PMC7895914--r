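test_that("beta signals match closed-form moments and densities", {
  expect_equal(mean(signal_beta(0.5, 0.5)), 0.5)
  expect_equal(mean(signal_beta(1, 5)), 1 / 6)
  flat <- signal_beta(1, 1)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(signal_density(flat, p), rep(1, length(p)))
  expect_error(signal_beta(0, 1), "positive")
  expect_error(signal_beta(2, -1), "positive")
})

test_that("uniform signals have the expected support and moments", {
  expect_equal(mean(signal_uniform()), 0.5)
  half <- signal_uniform(0, 0.5)
  expect_equal(mean(half), 0.25)
  expect_equal(support_max(half), 0.5)
  expect_equal(signal_density(half, c(0.25, 0.75)), c(2, 0))
  expect_error(signal_uniform(0.3, 0.3), "lo < hi")
  expect_error(signal_uniform(-0.1, 0.5), "lo < hi")
})

test_that("partial_mean matches closed forms and quadrature", {
  expect_equal(partial_mean(unif, 0), 0.5)
  expect_equal(partial_mean(unif, 0.5), 0.375)
  expect_equal(partial_mean(unif, 1), 0)
  # quadrature oracle across families and thresholds
  cases <- list(
    list(d = signal_beta(2, 8), f = function(p) dbeta(p, 2, 8)),
    list(d = signal_beta(0.5, 0.5), f = function(p) dbeta(p, 0.5, 0.5)),
    list(d = signal_beta(1, 5), f = function(p) dbeta(p, 1, 5)),
    list(d = signal_uniform(0.1, 0.7),
         f = function(p) dunif(p, 0.1, 0.7))
  )
  for (cs in cases) {
    for (a in c(0, 0.05, 0.3, 0.62, 0.9)) {
      expect_equal(partial_mean(cs$d, a), quad_pe(cs$f, a),
                   tolerance = 1e-8)
    }
  }
})

test_that("densities integrate to one and tail functions are monotone", {
  set.seed(11)
  for (d in random_beta_dists(10)) {
    total <- integrate(function(p) signal_density(d, p), 0, 1,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
    grid <- seq(0.01, 0.99, length.out = 50)
    expect_true(all(diff(signal_cdf(d, grid)) >= 0))
    pe <- partial_mean(d, grid)
    expect_true(all(diff(pe) <= 1e-12))
    expect_equal(partial_mean(d, 0), mean(d), tolerance = 1e-10)
    expect_equal(partial_mean(d, 1), 0)
  }
})

test_that("empirical smoothing recovers the generating distribution", {
  set.seed(21)
  x <- rbeta(1000, 2, 8)
  emp <- signal_empirical(x)
  expect_lt(abs(mean(emp) - 0.2), 0.02)
  total <- sum(diff(emp$grid) *
                 (head(emp$fg, -1) + tail(emp$fg, -1)) / 2)
  expect_equal(total, 1, tolerance = 1e-6)
  # floor constant keeps the support open on (0, 1)
  expect_gt(signal_density(emp, 0.999), 0)
  expect_error(signal_empirical(c(0.5, 1.2, 0.3, rep(0.4, 10))),
               "inside \\(0, 1\\)")
  expect_error(signal_empirical(runif(5)), "at least 10")
})

test_that("sampling is reproducible and matches the CDF", {
  d <- signal_beta(2, 8)
  s1 <- signal_sample(d, 100, seed = 5)
  s2 <- signal_sample(d, 100, seed = 5)
  expect_identical(s1, s2)
  s <- signal_sample(d, 1e5, seed = 17)
  ks <- max(abs(ecdf(s)(seq(0.001, 0.999, by = 0.001)) -
                signal_cdf(d, seq(0.001, 0.999, by = 0.001))))
  expect_lt(ks, 0.01)
  # empirical family samples from its own smoothed CDF
  emp <- signal_empirical(rbeta(500, 2, 8))
  se <- signal_sample(emp, 2e4, seed = 3)
  expect_equal(mean(se), mean(emp), tolerance = 0.01)
})
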