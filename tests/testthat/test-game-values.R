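test_that("single-dose symmetric values match hand calculations", {
  cfg <- game_config(1, unif, utility_params(0, 1, 2, alpha = 1))
  # treat everyone: value is U * E(p) / (1 - F(0)^2) = 0.5
  expect_equal(as.numeric(symmetric_value_table(0, cfg)), 0.5)
  # treat no one (boundary rule): the continuity limit k U / 2 = 0.5
  expect_equal(as.numeric(symmetric_value_table(1, cfg)), 0.5)
})

test_that("the continuous and dichotomous recursions agree on constant rules", {
  for (dist in list(unif, signal_beta(1, 5), signal_beta(0.5, 0.5))) {
    cfg <- game_config(12, dist)
    for (T in c(0.2, 0.5, 0.8) * dist$support_max) {
      vT <- symmetric_value_table(rep(T, 12), cfg)
      vd <- dichotomous_values(T, cfg, "both-high")
      expect_equal(as.numeric(vT), as.numeric(vd), tolerance = 1e-10)
    }
    v0 <- symmetric_value_table(rep(0, 12), cfg)
    va <- dichotomous_values(0.5 * dist$support_max, cfg, "both-all")
    expect_equal(as.numeric(v0), as.numeric(va), tolerance = 1e-10)
  }
})

test_that("treat-everyone values follow the two-dose-per-period recursion", {
  cfg <- game_config(4, unif, utility_params(0, 1, 2, alpha = 0.25))
  v <- dichotomous_values(0.5, cfg, "both-all")
  U <- cfg$params$U
  expect_equal(v[1], 1 * U * 0.5)
  expect_equal(v[2], 2 * U * 0.5)
  expect_equal(v[3], 3 * U * 0.5 + v[1])
  expect_equal(v[4], 4 * U * 0.5 + v[2])
})

test_that("deviation values reduce to the symmetric recursion at equality", {
  cfg <- game_config(6, signal_beta(2, 3))
  v <- symmetric_value_table(rep(0.3, 6), cfg)
  for (k in 2:6) {
    expect_equal(deviation_value(k, 0.3, 0.3, v, cfg), as.numeric(v)[k],
                 tolerance = 1e-12)
  }
})

test_that("deviating against a treat-everyone opponent has the closed form", {
  # k = 1, opponent threshold 0: value U * (1 - d^2) / 2 for the uniform
  cfg <- game_config(1, unif, utility_params(0, 1, 2, alpha = 1))
  dbar <- seq(0, 0.9, by = 0.1)
  got <- deviation_value(1, dbar, 0, numeric(1), cfg)
  expect_equal(got, (1 - dbar^2) / 2, tolerance = 1e-12)
  expect_true(all(diff(got) < 0))
  # both thresholds exhausting the support is undefined
  expect_error(deviation_value(1, 1, 1, numeric(1), cfg), "undefined")
})

test_that("the boundary rule is the limit of vanishing treatment", {
  cfg <- game_config(5, unif)
  eq <- solve_mpe(cfg)
  v <- as.numeric(eq$values)
  lim <- 5 * cfg$params$U / 2 + v[4]
  errs <- vapply(10^-(2:6), function(e) {
    vt <- symmetric_value_table(c(eq$thresholds[1:4], 1 - e), cfg)
    abs(as.numeric(vt)[5] - lim)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))     # monotone convergence
  expect_lt(errs[length(errs)], 1e-5)
})

test_that("the deviation-payoff index is strictly increasing", {
  expect_equal(deviation_index(unif, 0, 0), 0)
  expect_equal(deviation_index(unif, 0.5, 0.5), 0.75)
  set.seed(51)
  for (d in random_beta_dists(10)) {
    for (dd in c(0.2, 0.5, 0.7)) {
      grid <- seq(0.005, 0.995, length.out = 100)
      g <- deviation_index(d, dd, grid)
      expect_true(all(diff(g) > 0))
    }
  }
})

test_that("treat-high-only values increase in k when the policy is stable", {
  # bimodal scenario satisfies the stability condition at T = 0.5
  cfg <- game_config(30, signal_beta(0.5, 0.5))
  v <- dichotomous_values(0.5, cfg, "both-high")
  expect_true(all(diff(c(0, as.numeric(v))) > 0))
})
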