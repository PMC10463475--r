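# Published worked-example rows used to pin down the contribution arithmetic:
# elasticity and the dummy's concentration index must reproduce the absolute
# contribution at 4 decimal places.
worked_rows <- data.frame(
  label = c("wealth richer", "married", "islam", "working",
            "two births", "four or more births", "secondary/higher"),
  elasticity = c(0.0194, -0.1201, -0.0359, 0.1080, 0.0412, 0.3654, 0.0706),
  ck = c(0.3509, -0.0339, -0.1396, 0.0089, 0.1090, -0.1038, 0.4028),
  absolute = c(0.0068, 0.0041, 0.0050, 0.0010, 0.0045, -0.0379, 0.0284)
)

test_that("contribution arithmetic reproduces published worked-example rows at 4 dp", {
  for (i in seq_len(nrow(worked_rows))) {
    row <- worked_rows[i, ]
    # elasticity = beta*xbar/mu; feed it through with mu = xbar = 1 so that
    # beta carries the whole elasticity
    con <- contribution(beta = row$elasticity, xbar = 1, mu = 1, ck = row$ck)
    expect_equal(round(con$absolute, 4), row$absolute,
                 info = row$label)
  }
})

test_that("contribution handles zero effects, zero concentration and missing totals", {
  expect_equal(contribution(0, 0.4, 0.2, 0.9, total = 0.1)$absolute, 0)
  expect_equal(contribution(0.3, 0.4, 0.2, 0, total = 0.1)$absolute, 0)
  expect_true(is.na(contribution(0.3, 0.4, 0.2, 0.5, total = 0)$percentage))
  expect_true(is.na(contribution(0.3, 0.4, 0.2, 0.5)$percentage))
  expect_error(contribution(0.3, 0.4, 0, 0.5), "mu")
  con <- contribution(0.25, 0.4, 0.2, -0.3, total = 0.05)
  expect_equal(con$elasticity, 0.5)
  expect_equal(con$absolute, con$elasticity * -0.3)
  expect_equal(con$percentage, 100 * con$absolute / 0.05)
})

run_small_decomposition <- function(n, seed) {
  set.seed(seed)
  d <- data.frame(
    outcome = rbinom(n, 1, 0.4),
    g1 = factor(sample(c("a", "b", "c"), n, replace = TRUE), levels = c("a", "b", "c")),
    g2 = factor(sample(c("u", "v"), n, replace = TRUE), levels = c("u", "v")),
    weight = rlnorm(n, 0, 0.5),
    score = rnorm(n)
  )
  if (sum(d$outcome) == 0) d$outcome[1] <- 1
  X <- dummy_encode(d, c("g1", "g2"))
  fit <- fit_lpm(X, d$outcome, d$weight)
  r <- fractional_rank(d$score, d$weight)
  list(d = d, X = X, fit = fit, r = r,
       dec = decompose_cix(fit, r, X))
}

test_that("contributions plus residual reconstruct the outcome CIX exactly", {
  for (seed in c(61, 62, 63, 64, 65)) {
    res <- run_small_decomposition(sample(30:150, 1), seed)
    total <- attr(res$dec, "total_cix")
    expect_equal(sum(res$dec$absolute_contribution) + attr(res$dec, "residual"),
                 total, tolerance = 1e-10)
    expect_equal(sum(res$dec$percentage_contribution) + attr(res$dec, "residual_pct"),
                 100, tolerance = 1e-6)
    # total matches an independent recomputation from the raw data
    expect_equal(total, bf_cix(res$d$outcome, res$d$score, res$d$weight),
                 tolerance = 1e-10)
  }
})

test_that("each decomposition term matches its brute-force recomputation", {
  res <- run_small_decomposition(120, 66)
  w <- res$d$weight
  mu <- sum(w * res$d$outcome) / sum(w)
  for (i in seq_len(nrow(res$dec))) {
    tm <- paste0(res$dec$covariate[i], "=", res$dec$level[i])
    xk <- res$X[, tm]
    xbar <- sum(w * xk) / sum(w)
    ck <- 2 * bf_wcov(xk, res$r, w) / xbar
    expect_equal(res$dec$xbar[i], xbar, tolerance = 1e-12)
    expect_equal(res$dec$ck[i], ck, tolerance = 1e-10)
    expect_equal(res$dec$elasticity[i], res$dec$beta[i] * xbar / mu,
                 tolerance = 1e-12)
    expect_equal(res$dec$absolute_contribution[i],
                 res$dec$elasticity[i] * res$dec$ck[i], tolerance = 1e-14)
    expect_true(res$dec$xbar[i] >= 0 && res$dec$xbar[i] <= 1)
    expect_true(abs(res$dec$ck[i]) <= 1 + 1e-12)
  }
  # residual equals 2 cov(residuals, rank)/mu, the GC/mu term
  expect_equal(attr(res$dec, "residual"),
               2 * bf_wcov(res$fit$residuals, res$r, w) / mu,
               tolerance = 1e-10)
})

test_that("a rich-concentrated dummy with positive beta contributes positively", {
  n <- 4000
  set.seed(67)
  score <- rnorm(n)
  # dummy concentrated among the rich, outcome boosted by it
  x <- rbinom(n, 1, plogis(score))
  y <- rbinom(n, 1, plogis(-1 + 1.5 * x))
  if (sum(y) == 0) y[1] <- 1
  d <- data.frame(outcome = y,
                  g = factor(ifelse(x == 1, "yes", "no"), levels = c("no", "yes")),
                  weight = 1, score = score)
  X <- dummy_encode(d, "g")
  fit <- fit_lpm(X, d$outcome, d$weight)
  dec <- decompose_cix(fit, fractional_rank(score, d$weight), X)
  expect_gt(dec$ck[1], 0)
  expect_gt(dec$beta[1], 0)
  expect_gt(dec$absolute_contribution[1], 0)
})

test_that("decomposition is deterministic given the same references", {
  r1 <- run_small_decomposition(100, 68)$dec
  r2 <- run_small_decomposition(100, 68)$dec
  expect_identical(r1, r2)
})

test_that("wealth-only outcome puts the wealth block on top at scale", {
  cfg <- sim_config(50000, seed = 71,
                    outcome_coefficients = list(intercept = -1.65, ses_slope = 1,
                                                effects = numeric(0)))
  d <- simulate_survey(cfg)
  cfg_a <- analysis_config(wealth_mode = "assets", asset_columns = default_asset_cols)
  a <- suppressMessages(run_analysis(d, cfg_a))
  blocks <- block_contributions(a$decomposition)
  wealth_pct <- blocks$percentage_contribution[blocks$covariate == "wealth_quintile"]
  others <- blocks$percentage_contribution[blocks$covariate != "wealth_quintile"]
  expect_true(all(wealth_pct > others))
})
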