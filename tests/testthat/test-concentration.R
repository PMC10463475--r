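test_that("fractional ranks are weighted midpoints with mean one half", {
  expect_equal(fractional_rank(c(10, 20, 30, 40), rep(1, 4)),
               c(0.125, 0.375, 0.625, 0.875))
  expect_equal(fractional_rank(c(1, 2), c(1, 3)), c(0.125, 0.625))
  expect_equal(fractional_rank(5, 2), 0.5)
  # unsorted input is ranked by value, not position
  expect_equal(fractional_rank(c(40, 10, 30, 20), rep(1, 4)),
               c(0.875, 0.125, 0.625, 0.375))
})

test_that("tied scores share a midpoint rank and the mean stays 0.5", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    s <- sample(1:8, n, replace = TRUE)      # many ties
    w <- rlnorm(n, 0, 0.6)
    r <- fractional_rank(s, w)
    expect_equal(sum(w * r) / sum(w), 0.5, tolerance = 1e-10)
    for (v in unique(s)) expect_lt(diff(range(r[s == v])), 1e-14)
    expect_true(all(r > 0 & r < 1))
  }
})

test_that("the toy pro-rich instance gives CIX = 0.5 exactly", {
  r <- fractional_rank(1:4, rep(1, 4))
  ci <- concentration_index(c(0, 0, 1, 1), r, rep(1, 4))
  expect_equal(ci$cix, 0.5, tolerance = 1e-12)
  expect_equal(ci$mu, 0.5)
})

test_that("a constant outcome has zero concentration", {
  r <- fractional_rank(rnorm(10), rep(1, 10))
  expect_equal(concentration_index(rep(1, 10), r, rep(1, 10))$cix, 0,
               tolerance = 1e-12)
})

test_that("h = r reproduces the closed-form midpoint-rank variance", {
  for (n in c(5, 8, 20)) {
    r <- fractional_rank(seq_len(n), rep(1, n))
    expect_equal(concentration_index(r, r, rep(1, n))$cix,
                 (n^2 - 1) / (3 * n^2), tolerance = 1e-12)
  }
})

test_that("an all-zero outcome is rejected", {
  r <- fractional_rank(1:4, rep(1, 4))
  expect_error(concentration_index(rep(0, 4), r, rep(1, 4)), "undefined")
})

test_that("covariance formula agrees with the convenient-regression oracle", {
  set.seed(53)
  for (i in 1:120) {
    inst <- random_instance(sample(10:200, 1), binary = (i %% 2 == 0))
    if (sum(inst$h) == 0) inst$h[1] <- 1
    cix <- concentration_index(inst$h, fractional_rank(inst$score, inst$w),
                               inst$w)$cix
    expect_equal(cix, convenient_regression_cix(inst$h, inst$score, inst$w),
                 tolerance = 1e-8)
  }
})

test_that("the weighted covariance agrees with stats::cov.wt (ML convention)", {
  set.seed(59)
  for (i in 1:15) {
    inst <- random_instance(sample(10:120, 1))
    if (sum(inst$h) == 0) inst$h[1] <- 1
    r <- fractional_rank(inst$score, inst$w)
    mu <- sum(inst$w * inst$h) / sum(inst$w)
    ref <- stats::cov.wt(cbind(inst$h, r), wt = inst$w, method = "ML")$cov[1, 2]
    expect_equal(concentration_index(inst$h, r, inst$w)$cix, 2 * ref / mu,
                 tolerance = 1e-12)
  }
})

test_that("negating the wealth ordering negates the index exactly", {
  set.seed(54)
  for (i in 1:30) {
    inst <- random_instance(sample(10:100, 1))
    if (sum(inst$h) == 0) inst$h[1] <- 1
    c1 <- concentration_index(inst$h, fractional_rank(inst$score, inst$w), inst$w)$cix
    c2 <- concentration_index(inst$h, fractional_rank(-inst$score, inst$w), inst$w)$cix
    expect_lt(abs(c1 + c2), 1e-12)
  }
})

test_that("binary outcomes respect the |CIX| <= 1 - mu bound", {
  set.seed(55)
  for (i in 1:100) {
    inst <- random_instance(sample(5:150, 1))
    if (sum(inst$h) == 0) inst$h[1] <- 1
    ci <- concentration_index(inst$h, fractional_rank(inst$score, inst$w), inst$w)
    expect_lte(abs(ci$cix), 1 - ci$mu + 1e-12)
    expect_lte(abs(ci$cix), 1)
  }
})

test_that("the index is invariant to the scale of the weights", {
  set.seed(56)
  inst <- random_instance(80)
  r1 <- fractional_rank(inst$score, inst$w)
  r2 <- fractional_rank(inst$score, inst$w * 250)
  expect_equal(concentration_index(inst$h, r1, inst$w)$cix,
               concentration_index(inst$h, r2, inst$w * 250)$cix,
               tolerance = 1e-12)
})

test_that("concentration curve coordinates and verdicts match hand computation", {
  h <- c(0, 0, 1, 1)
  cc <- concentration_curve(h, 1:4, rep(1, 4))
  expect_equal(cc$points$pop_share, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(cc$points$outcome_share, c(0, 0, 0, 0.5, 1))
  expect_identical(cc$verdict, "pro-rich")

  # reversing the wealth order flips the verdict
  expect_identical(concentration_curve(h, 4:1, rep(1, 4))$verdict, "pro-poor")

  # constant outcome: the curve is the diagonal
  cc0 <- concentration_curve(rep(1, 4), 1:4, rep(1, 4))
  expect_equal(cc0$points$outcome_share, cc0$points$pop_share, tolerance = 1e-12)
  expect_identical(cc0$verdict, "equality")
})

test_that("curve endpoints and monotonicity hold on random instances", {
  set.seed(57)
  for (i in 1:25) {
    inst <- random_instance(sample(5:100, 1))
    if (sum(inst$h) == 0) inst$h[1] <- 1
    pts <- concentration_curve(inst$h, inst$score, inst$w)$points
    expect_equal(pts$pop_share[1], 0)
    expect_equal(pts$outcome_share[1], 0)
    expect_equal(pts$pop_share[nrow(pts)], 1, tolerance = 1e-12)
    expect_equal(pts$outcome_share[nrow(pts)], 1, tolerance = 1e-12)
    expect_true(all(diff(pts$pop_share) >= 0))
    expect_true(all(diff(pts$outcome_share) >= -1e-12))
  }
})

test_that("the Erreygers-corrected index equals 4 cov(h, r)", {
  set.seed(58)
  inst <- random_instance(60)
  if (sum(inst$h) == 0) inst$h[1] <- 1
  res <- concentration(inst$h, inst$score, inst$w, erreygers = TRUE)
  expect_equal(res$cix_erreygers, 2 * res$cix * res$mu, tolerance = 1e-12)
})
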