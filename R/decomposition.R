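#' Elasticity and contribution of one regressor to the concentration index
#'
#' For a regressor with linear-model coefficient `beta`, weighted mean
#' `xbar`, own concentration index `ck` and outcome mean `mu`:
#' the elasticity is `beta * xbar / mu`, the absolute contribution is
#' `elasticity * ck`, and the percentage contribution is the absolute
#' contribution as a share of the total index.
#'
#' @param beta linear probability model coefficient.
#' @param xbar weighted mean of the regressor (for a dummy, its prevalence).
#' @param mu weighted mean of the outcome (> 0).
#' @param ck concentration index of the regressor w.r.t. the wealth rank.
#' @param total total concentration index of the outcome; if `NULL` or zero
#'   the percentage is `NA`.
#' @return list with `elasticity`, `absolute`, `percentage`.
#' @examples
#' contribution(beta = 0.1, xbar = 0.4, mu = 0.2, ck = 0.35, total = 0.1)
#' @export
contribution <- function(beta, xbar, mu, ck, total = NULL) {
  if (mu <= 0) stop("mu must be positive")
  elasticity <- beta * xbar / mu
  absolute <- elasticity * ck
  percentage <- if (!is.null(total) && total != 0) 100 * absolute / total
  else NA_real_
  list(elasticity = elasticity, absolute = absolute, percentage = percentage)
}

#' Decompose the concentration index into covariate contributions
#'
#' Regression-based decomposition of the outcome's concentration index:
#' under the linear probability model `y = a0 + sum_k beta_k x_k + e`,
#'
#' `CIX = sum_k (beta_k * xbar_k / mu) * C_k + GC/mu`
#'
#' where `C_k = 2 cov(x_k, r) / xbar_k` is the dummy's own concentration
#' index computed with the same wealth rank `r` and the same weighted
#' population covariance as the outcome index, and the residual term
#' `GC/mu` is the part of the inequality the regressors do not explain.
#' With the uncorrected weighted covariance the identity is exact, so the
#' residual is obtained by subtraction.
#'
#' @param fit an [fit_lpm()] object (fitted on the same complete-case rows).
#' @param rank fractional wealth ranks from [fractional_rank()].
#' @param design the dummy design matrix the model was fitted on.
#' @return an object of class `decomposition_table`: a `data.frame` with one
#'   row per dummy (`covariate`, `level`, `beta`, `xbar`, `ck`, `elasticity`,
#'   `absolute_contribution`, `percentage_contribution`) and attributes
#'   `total_cix`, `residual` (GC/mu) and `residual_pct`.
#' @export
decompose_cix <- function(fit, rank, design) {
  stopifnot(inherits(fit, "lpm_fit"))
  w <- fit$weights
  if (length(rank) != length(fit$y)) stop("rank and fit sizes differ")
  mu <- fit$mu
  if (mu <= 0) stop("weighted mean of the outcome is zero; index undefined")
  total <- 2 * wcov(fit$y, rank, w) / mu

  keep <- fit$xbar > 0
  if (any(!keep)) {
    warning("empty dummy column(s) dropped: ",
            paste(names(fit$xbar)[!keep], collapse = ", "))
  }
  terms <- names(fit$beta)[keep]
  rows <- lapply(terms, function(tm) {
    xk <- design[, tm]
    xbar <- fit$xbar[[tm]]
    ck <- 2 * wcov(xk, rank, w) / xbar
    con <- contribution(fit$beta[[tm]], xbar, mu, ck, total = total)
    data.frame(term = tm, beta = fit$beta[[tm]], xbar = xbar, ck = ck,
               elasticity = con$elasticity,
               absolute_contribution = con$absolute,
               percentage_contribution = con$percentage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  split_terms <- strsplit(out$term, "=", fixed = TRUE)
  out$covariate <- vapply(split_terms, `[`, character(1), 1)
  out$level <- vapply(split_terms, `[`, character(1), 2)
  out <- out[, c("covariate", "level", "beta", "xbar", "ck", "elasticity",
                 "absolute_contribution", "percentage_contribution")]
  rownames(out) <- NULL
  attr(out, "total_cix") <- total
  attr(out, "residual") <- total - sum(out$absolute_contribution)
  attr(out, "residual_pct") <- 100 * attr(out, "residual") / total
  attr(out, "references") <- attr(design, "references")
  class(out) <- c("decomposition_table", "data.frame")
  out
}

#' @export
print.decomposition_table <- function(x, digits = 4, ...) {
  cat("Decomposition of the concentration index\n")
  cat(sprintf("  total CIX: %.*f   residual (GC/mu): %.*f (%.2f%%)\n",
              digits, attr(x, "total_cix"),
              digits, attr(x, "residual"), attr(x, "residual_pct")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summed contributions by covariate block
#'
#' Aggregates a decomposition table to one row per covariate: the summed
#' absolute and percentage contribution of all its dummies.
#'
#' @param x a `decomposition_table`.
#' @return a `data.frame` with `covariate`, `absolute_contribution`,
#'   `percentage_contribution`, ordered as in `x`.
#' @export
block_contributions <- function(x) {
  stopifnot(inherits(x, "decomposition_table"))
  covs <- unique(x$covariate)
  out <- data.frame(
    covariate = covs,
    absolute_contribution = vapply(covs, function(cv) {
      sum(x$absolute_contribution[x$covariate == cv])
    }, numeric(1)),
    percentage_contribution = vapply(covs, function(cv) {
      sum(x$percentage_contribution[x$covariate == cv])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
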