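test_that("identical and constant samples carry no evidence (p = 1)", {
  x <- c(1.2, 3.4, -0.5, 2.2, 0.9)
  s <- surfdelta:::cpp_two_sample_stats(x, x)
  expect_equal(s[["ksD"]], 0)
  expect_equal(two_sample_p(x, x, "ks"), 1)
  const <- rep(2.5, 6)
  for (tst in c("t", "ks", "ad")) {
    expect_equal(as.numeric(two_sample_p(const, const, tst)), 1)
  }
  expect_error(two_sample_p(1, c(1, 2), "t"), "size >= 2")
})

test_that("t and KS agree with the reference implementations in stats", {
  set.seed(99)
  cases <- list(
    list(x = rnorm(15), y = rnorm(20, 0.8)),
    list(x = rexp(40), y = rexp(35)),
    list(x = rnorm(100, sd = 3), y = rnorm(60))
  )
  for (cs in cases) {
    tt <- t.test(cs$x, cs$y)
    expect_equal(two_sample_p(cs$x, cs$y, "t"), tt$p.value, tolerance = 1e-12)
    kk <- ks.test(cs$x, cs$y, exact = FALSE)
    expect_equal(two_sample_p(cs$x, cs$y, "ks"), kk$p.value, tolerance = 1e-10)
    # exchange symmetry
    for (tst in c("t", "ks", "ad")) {
      expect_equal(as.numeric(two_sample_p(cs$x, cs$y, tst)),
                   as.numeric(two_sample_p(cs$y, cs$x, tst)),
                   tolerance = 1e-12)
    }
  }
})

test_that("the standardized Anderson-Darling statistic matches an external reference", {
  # frozen from an independent implementation of the Scholz-Stephens
  # midrank k-sample statistic on this exact sample pair
  x <- c(1.1, 2.3, 0.5, 3.7, 1.9)
  y <- c(2.2, 4.1, 3.3, 5.0, 2.8)
  s <- surfdelta:::cpp_two_sample_stats(x, y)
  expect_equal(s[["T"]], 1.4882447581306262, tolerance = 1e-9)
})

test_that("asymptotic AD p-values track an exhaustive permutation oracle at n = 5", {
  x <- c(1.1, 2.3, 0.5, 3.7, 1.9)
  y <- c(2.2, 4.1, 3.3, 5.0, 2.8)
  t_obs <- surfdelta:::cpp_two_sample_stats(x, y)[["T"]]
  pool <- c(x, y)
  combs <- utils::combn(10, 5)
  t_perm <- apply(combs, 2, function(idx) {
    surfdelta:::cpp_two_sample_stats(pool[idx], pool[-idx])[["T"]]
  })
  p_perm <- mean(t_perm >= t_obs - 1e-12)
  expect_equal(p_perm, 28 / 252, tolerance = 1e-12)  # exhaustive, no MC error
  p_asym <- as.numeric(two_sample_p(x, y, "ad"))
  expect_lt(abs(p_asym - p_perm), 0.05)
})

test_that("AD p-values are extrapolated, not clipped, outside the table", {
  # strong separation: p far below the smallest tabulated level
  x <- rnorm(200, 0, 1)
  y <- rnorm(200, 5, 1)
  p <- two_sample_p(x, y, "ad")
  expect_lt(as.numeric(p), 1e-6)
  expect_gt(as.numeric(p), 0)
  expect_true(any(attr(p, "extrapolated")))
  # weak end: p above 0.25 rather than pinned at it
  p_hi <- two_sample_p(1:50, 1:50 + 0.001, "ad")
  expect_gt(as.numeric(p_hi), 0.3)
})

test_that("significance thresholding is strict, matching published table calls", {
  expect_true(is_significant(1.06e-7, 0.01))   # deeply significant row
  expect_false(is_significant(4.38e-1, 0.01))  # same row's t-test call
  expect_false(is_significant(8.7e-1, 0.01))
  expect_false(is_significant(0.01, 0.01))     # boundary: strict inequality
  expect_true(is_significant(0.0099999, 0.01))
})

test_that("resampled comparisons are seed-deterministic and symmetric", {
  pr <- sample_potential_pair(800, 0.5, seed = 17)
  cfg <- resampling_config(n_points = 50, n_iterations = 200, seed = 7)
  r1 <- resampled_comparison(pr$x, pr$y, cfg)
  r2 <- resampled_comparison(pr$x, pr$y, cfg)
  expect_identical(r1$per_iteration_p, r2$per_iteration_p)
  expect_identical(r1$p_AD, r2$p_AD)
  # median-p aggregation reproduces row medians of the iteration matrix
  expect_equal(r1$p_T, median(r1$per_iteration_p["t", ]))
  expect_equal(r1$p_AD, median(r1$per_iteration_p["ad", ]))
  expect_equal(r1$p_KS, median(r1$per_iteration_p["ks", ]))
  # swapping samples negates the shift exactly; aggregated p-values agree up
  # to resampling noise (the index draws are positional, so per-iteration
  # subsample pairs differ between the two orders)
  null_pr <- sample_potential_pair(800, 0, seed = 18)
  cfg_big <- resampling_config(n_points = 50, n_iterations = 1000, seed = 7)
  r_fw <- resampled_comparison(null_pr$x, null_pr$y, cfg_big)
  r_sw <- resampled_comparison(null_pr$y, null_pr$x, cfg_big)
  expect_equal(r_sw$median_shift, -r_fw$median_shift)
  for (f in c("p_T", "p_KS", "p_AD")) {
    # KS p-values are discrete at n_points = 50, so the aggregated medians
    # can land on different plateau steps between the two orders
    expect_lt(abs(r_sw[[f]] - r_fw[[f]]), 0.2)
    expect_equal(is_significant(r_sw[[f]]), is_significant(r_fw[[f]]))
  }
  # identical samples: shift is exactly zero
  r0 <- resampled_comparison(pr$x, pr$x, cfg)
  expect_identical(r0$median_shift, 0)
})

test_that("without-replacement draws respect sample-size limits", {
  pr <- sample_potential_pair(60, 0, seed = 2)
  cfg <- resampling_config(n_points = 100, n_iterations = 10, seed = 1,
                           with_replacement = FALSE)
  expect_error(resampled_comparison(pr$x, pr$y, cfg), "with_replacement")
  cfg2 <- resampling_config(n_points = 40, n_iterations = 50, seed = 1,
                            with_replacement = FALSE)
  r <- resampled_comparison(pr$x, pr$y, cfg2)
  expect_true(all(r$per_iteration_p >= 0 & r$per_iteration_p <= 1))
})

test_that("Fisher aggregation is available and flagged as anti-conservative", {
  pr <- sample_potential_pair(2000, 1.0, seed = 5)
  cfg <- resampling_config(n_iterations = 100, seed = 5, aggregation = "fisher")
  r <- resampled_comparison(pr$x, pr$y, cfg)
  expect_lt(r$p_AD, 1e-20)  # combination reaches extreme p-values
  expect_true(any(grepl("not independent|anti-conservative", r$notes)))
  r_med <- resampled_comparison(pr$x, pr$y,
                                resampling_config(n_iterations = 100, seed = 5))
  expect_gt(r_med$p_AD, 0)
  expect_lt(r_med$p_AD, 0.01)
})

test_that("aggregated p-values do not drift toward zero with more iterations", {
  pr <- sample_potential_pair(3000, 0, seed = 23)
  p100 <- resampled_comparison(pr$x, pr$y,
                               resampling_config(n_iterations = 100, seed = 3))
  p1000 <- resampled_comparison(pr$x, pr$y,
                                resampling_config(n_iterations = 1000, seed = 3))
  for (f in c("p_T", "p_KS", "p_AD")) {
    expect_gt(p1000[[f]], 0.1)
    expect_lt(abs(p1000[[f]] - p100[[f]]), 0.25)
  }
})
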