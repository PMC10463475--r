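# Small shared fixtures built in code.

# 2x2 outcome-by-group data with counts a,b in group 1 and c,d in group 0
# (a, c = outcome 1). Equal weights.
make_2x2 <- function(a, b, c, d) {
  data.frame(
    outcome = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    grp = factor(c(rep("exposed", a + b), rep("unexposed", c + d)),
                 levels = c("unexposed", "exposed")),
    weight = 1
  )
}

# brute-force weighted population covariance (oracle, independent of wcov)
bf_wcov <- function(x, y, w) {
  p <- w / sum(w)
  sum(p * (x - sum(p * x)) * (y - sum(p * y)))
}

# brute-force concentration index straight from the definition
bf_cix <- function(h, score, w) {
  r <- fractional_rank(score, w)
  2 * bf_wcov(h, r, w) / (sum(w * h) / sum(w))
}

# "convenient regression" formulation of the concentration index:
# weighted LS slope of 2*var_w(r)*(h/mu) on r equals CIX.
convenient_regression_cix <- function(h, score, w) {
  r <- fractional_rank(score, w)
  p <- w / sum(w)
  mu <- sum(p * h)
  vr <- sum(p * (r - sum(p * r))^2)
  z <- 2 * vr * h / mu
  unname(coef(lm(z ~ r, weights = w))[2])
}

# small random weighted instance for property tests
random_instance <- function(n, binary = TRUE) {
  list(h = if (binary) rbinom(n, 1, runif(1, 0.2, 0.8)) else runif(n),
       score = rnorm(n),
       w = rlnorm(n, 0, 0.5))
}

default_asset_cols <- sprintf("asset_%02d", 1:10)
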