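test_that("coarsening the uniform signal gives closed-form posteriors", {
  cs <- coarsen(unif, 0.5)
  expect_equal(cs$q_H, 0.5)
  expect_equal(cs$p_H, 0.75)
  expect_equal(cs$p_L, 0.25)
  expect_error(coarsen(signal_uniform(0, 0.5), 0.7), "degenerate")
})

test_that("coarsened posteriors match the arcsine closed form and quadrature", {
  arc <- signal_beta(0.5, 0.5)
  cs <- coarsen(arc, 0.5)
  expect_equal(cs$p_H, 0.5 + 1 / pi, tolerance = 1e-10)
  expect_equal(cs$p_L, 0.5 - 1 / pi, tolerance = 1e-10)
  q <- quad_coarsen(function(p) dbeta(p, 2, 5), function(p) pbeta(p, 2, 5),
                    0.3)
  cs2 <- coarsen(signal_beta(2, 5), 0.3)
  expect_equal(cs2$p_H, q$p_H, tolerance = 1e-9)
  expect_equal(cs2$p_L, q$p_L, tolerance = 1e-9)
})

test_that("total expectation identity and posterior monotonicity hold", {
  set.seed(31)
  for (d in random_beta_dists(100)) {
    Ts <- seq(0.1, 0.9, by = 0.1)
    for (T in Ts) {
      cs <- coarsen(d, T)
      expect_equal(cs$q_H * cs$p_H + cs$q_L * cs$p_L, mean(d),
                   tolerance = 1e-8)
      expect_true(cs$p_L <= T + 1e-12 && T <= cs$p_H + 1e-12)
    }
  }
  # truncated-mean monotonicity on a fine grid
  for (d in random_beta_dists(5)) {
    prof <- threshold_profile(d)
    expect_true(all(diff(prof$p_H) >= -1e-10))
    expect_true(all(diff(prof$p_L) >= -1e-10))
  }
})

test_that("stability gap has the right sign pattern across scenarios", {
  # uniform: exact indifference at every threshold
  Ts <- seq(0.05, 0.95, by = 0.05)
  expect_equal(stability_gap(unif, Ts), rep(0, length(Ts)),
               tolerance = 1e-12)
  # bimodal (informative) scenario: strictly positive
  expect_equal(stability_gap(signal_beta(0.5, 0.5), 0.5), 2 / pi - 0.5,
               tolerance = 1e-10)
  # concentrated (uninformative) scenario: strictly negative
  q <- quad_coarsen(function(p) dbeta(p, 20, 20),
                    function(p) pbeta(p, 20, 20), 0.5)
  expect_equal(stability_gap(signal_beta(20, 20), 0.5), q$gap,
               tolerance = 1e-9)
  expect_lt(stability_gap(signal_beta(20, 20), 0.5), -0.37)
})

test_that("minimal stable threshold locates the infimum or reports none", {
  expect_lte(min_stable_threshold(signal_beta(0.5, 0.5)), 1e-3)
  expect_lte(min_stable_threshold(unif), 1e-3)
  expect_true(is.na(min_stable_threshold(signal_beta(20, 20))))
  # agreement with a dense brute-force scan
  set.seed(41)
  for (d in random_beta_dists(20)) {
    mt <- min_stable_threshold(d, tol = 1e-6)
    g <- seq(1e-4, 1 - 1e-4, by = 1e-4)
    ok <- stability_gap(d, g) >= -1e-6
    bf <- if (any(ok)) g[which(ok)[1]] else NA_real_
    if (is.na(mt)) {
      expect_true(is.na(bf))
    } else {
      expect_lt(abs(mt - bf), 2e-4)
    }
  }
})

test_that("threshold profiles carry the full diagnostic table", {
  prof <- threshold_profile(unif, c(0.25, 0.5, 0.75))
  expect_named(prof, c("T", "q_H", "p_H", "p_L", "h", "E_p", "gap",
                       "stable"))
  expect_equal(prof$h, rep(0.5, 3), tolerance = 1e-12)
  expect_true(all(prof$stable))
  # identity per row
  expect_equal(prof$q_H * prof$p_H + (1 - prof$q_H) * prof$p_L,
               rep(0.5, 3), tolerance = 1e-10)
  prof20 <- threshold_profile(signal_beta(20, 20))
  expect_equal(nrow(prof20), 999L)
  expect_false(any(prof20$stable))
})
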