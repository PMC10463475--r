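#' Dummy-code categorical covariates against declared reference levels
#'
#' Builds the 0/1 design matrix used by both the logistic models and the
#' decomposition regression: one column per non-reference level, covariates
#' in the given order and levels in declared order. Column names are
#' `"covariate=level"`; the per-column covariate and level are attached as
#' attributes for downstream grouping.
#'
#' @param data complete-case survey data frame.
#' @param covariates character vector of covariate column names.
#' @param references named character vector, covariate -> reference level;
#'   covariates not named default to their first declared level.
#' @return numeric matrix with attributes `covariate`, `level` and
#'   `references`.
#' @export
dummy_encode <- function(data, covariates, references = NULL) {
  cols <- list()
  col_cov <- character(0)
  col_lev <- character(0)
  refs <- character(0)
  for (cv in covariates) {
    x <- as.character(data[[cv]])
    lv <- covariate_levels(data[[cv]], cv)
    ref <- if (!is.null(references) && cv %in% names(references)) {
      references[[cv]]
    } else lv[1]
    if (!ref %in% lv) {
      stop("reference '", ref, "' is not a declared level of '", cv, "'")
    }
    refs[cv] <- ref
    for (l in setdiff(lv, ref)) {
      cols[[paste0(cv, "=", l)]] <- as.numeric(x == l)
      col_cov <- c(col_cov, cv)
      col_lev <- c(col_lev, l)
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "covariate") <- col_cov
  attr(X, "level") <- col_lev
  attr(X, "references") <- refs
  X
}

logistic_block <- function(X, y, w_norm, model_label) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(
    .y ~ ., family = stats::binomial(), data = df, weights = w_norm,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  if (!fit$converged) {
    stop("logistic regression did not converge in ", fit$iter, " iterations")
  }
  co <- stats::coef(fit)[-1]
  if (any(abs(co) > 15)) {
    stop("apparent complete separation in column '",
         names(co)[which.max(abs(co))], "'")
  }
  sm <- summary(fit)$coefficients
  se <- sm[-1, "Std. Error"]
  p <- sm[-1, "Pr(>|z|)"]
  data.frame(term = colnames(X),
             odds_ratio = exp(co),
             ci_low = exp(co - 1.96 * se),
             ci_high = exp(co + 1.96 * se),
             p_value = p,
             reference = FALSE,
             model = model_label,
             stringsAsFactors = FALSE)
}

ref_rows <- function(design, model_label) {
  refs <- attr(design, "references")
  data.frame(term = paste0(names(refs), "=", unname(refs)),
             odds_ratio = 1, ci_low = NA_real_, ci_high = NA_real_,
             p_value = NA_real_, reference = TRUE, model = model_label,
             stringsAsFactors = FALSE)
}

#' Weighted logistic regression odds-ratio table
#'
#' Fits the binary outcome on the dummy design by maximum-likelihood
#' logistic regression with sampling weights. In `adjusted` mode all
#' covariate blocks enter jointly (adjusted odds ratios, aOR); otherwise
#' each covariate block is fitted on its own (crude odds ratios, cOR).
#' Weights are normalized to sum to the unweighted sample size, so standard
#' errors are the frequency-weight approximation (no design-based
#' linearization). 95% confidence intervals are `exp(coef +/- 1.96 SE)`.
#' Reference levels appear with odds ratio fixed at 1 and no interval.
#'
#' @param design dummy design matrix from [dummy_encode()].
#' @param outcome binary 0/1 outcome vector.
#' @param weights positive sampling weights.
#' @param adjusted logical: joint (adjusted) fit or one covariate at a time.
#' @return a `data.frame` of class `regression_table`: `covariate`, `level`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `reference`, `model`.
#' @export
fit_logistic <- function(design, outcome, weights, adjusted = TRUE) {
  n <- length(outcome)
  check_weights(weights, n)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  w_norm <- weights * n / sum(weights)
  label <- if (adjusted) "adjusted" else "crude"
  est <- if (adjusted) {
    logistic_block(design, outcome, w_norm, label)
  } else {
    blocks <- lapply(unique(attr(design, "covariate")), function(cv) {
      sub <- design[, attr(design, "covariate") == cv, drop = FALSE]
      logistic_block(sub, outcome, w_norm, label)
    })
    do.call(rbind, blocks)
  }
  out <- rbind(est, ref_rows(design, label))
  split_terms <- strsplit(out$term, "=", fixed = TRUE)
  out$covariate <- vapply(split_terms, `[`, character(1), 1)
  out$level <- vapply(split_terms, `[`, character(1), 2)
  # order: covariates as in the design, reference level first within each
  cov_order <- unique(attr(design, "covariate"))
  refs <- attr(design, "references")
  lev_key <- vapply(seq_len(nrow(out)), function(i) {
    if (out$reference[i]) 0L else match(out$term[i], colnames(design))
  }, integer(1))
  out <- out[order(match(out$covariate, cov_order), lev_key), ]
  rownames(out) <- NULL
  out <- out[, c("covariate", "level", "odds_ratio", "ci_low", "ci_high",
                 "p_value", "reference", "model")]
  class(out) <- c("regression_table", "data.frame")
  out
}

#' Weighted linear probability model for the decomposition
#'
#' Weighted least squares of the 0/1 outcome on the dummy design with an
#' intercept. The linear probability model (LPM) is used because the
#' concentration-index decomposition is an exact algebraic identity under a
#' linear model: coefficient times dummy concentration sums, with the
#' residual term, to the outcome's concentration index.
#'
#' @inheritParams fit_logistic
#' @return an object of class `lpm_fit`: intercept `a0`, named coefficients
#'   `beta`, weighted dummy means `xbar`, `fitted`, `residuals`, the outcome
#'   `y`, `weights` and weighted outcome mean `mu`.
#' @export
fit_lpm <- function(design, outcome, weights) {
  n <- length(outcome)
  check_weights(weights, n)
  df <- data.frame(.y = outcome, design, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df, weights = weights)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("design is rank deficient; collinear column(s): ",
         paste(colnames(design)[is.na(co[-1])], collapse = ", "))
  }
  structure(list(a0 = unname(co[1]),
                 beta = stats::setNames(unname(co[-1]), colnames(design)),
                 xbar = apply(design, 2, wmean, w = weights),
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 y = outcome,
                 weights = weights,
                 mu = wmean(outcome, weights)),
            class = "lpm_fit")
}
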