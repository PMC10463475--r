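#' Drop records with missing values on the analysis variables
#'
#' Complete-case filter: keeps rows with no missing value in any of the
#' listed variables and logs the number dropped.
#'
#' @param data survey data frame.
#' @param variables character vector of column names that must be non-missing.
#' @return the filtered data frame; errors if no rows survive.
#' @export
drop_incomplete <- function(data, variables) {
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols)) {
    stop("variable(s) not in data: ", paste(missing_cols, collapse = ", "))
  }
  ok <- Reduce(`&`, lapply(variables, function(v) !is.na(data[[v]])))
  dropped <- sum(!ok)
  if (dropped > 0) log_msg("complete_cases", dropped, " record(s) dropped")
  out <- data[ok, , drop = FALSE]
  if (nrow(out) == 0) stop("no complete cases remain; nothing to analyse")
  rownames(out) <- NULL
  out
}

covariate_levels <- function(x, covariate) {
  if (anyNA(x)) {
    stop("missing values in covariate '", covariate,
         "'; apply drop_incomplete() first")
  }
  if (is.factor(x)) levels(x) else unique(as.character(x))
}

#' Weighted prevalence of the outcome by covariate category
#'
#' Builds one block of a survey-style descriptive table: for each level of
#' the covariate, the weighted and unweighted sample size and percentage,
#' and the weighted outcome prevalence within the level
#' (`sum(w*y)/sum(w) * 100`). Weighted counts use weights normalized to the
#' unweighted sample total, the usual survey-report convention.
#'
#' @param data complete-case survey data frame.
#' @param covariate name of a categorical column.
#' @param outcome name of the binary 0/1 outcome column.
#' @param weight name of the sampling-weight column.
#' @return a `data.frame` with one row per declared level: `covariate`,
#'   `level`, `weighted_n`, `weighted_pct`, `unweighted_n`, `unweighted_pct`,
#'   `prevalence_pct`.
#' @export
prevalence_table <- function(data, covariate, outcome = "outcome",
                             weight = "weight") {
  x <- data[[covariate]]
  y <- data[[outcome]]
  w <- data[[weight]]
  check_weights(w, nrow(data))
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  lv <- covariate_levels(x, covariate)
  extra <- setdiff(unique(as.character(x)), lv)
  if (length(extra)) {
    stop("undeclared category '", extra[1], "' in covariate '", covariate, "'")
  }
  n <- length(w)
  wn <- w * n / sum(w)
  rows <- lapply(lv, function(l) {
    in_l <- as.character(x) == l
    data.frame(covariate = covariate, level = l,
               weighted_n = sum(wn[in_l]),
               weighted_pct = 100 * sum(wn[in_l]) / n,
               unweighted_n = sum(in_l),
               unweighted_pct = 100 * mean(in_l),
               prevalence_pct = if (any(in_l)) {
                 100 * sum(w[in_l] * y[in_l]) / sum(w[in_l])
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Weighted chi-square test of association between outcome and covariate
#'
#' Pearson chi-square on the weighted level-by-outcome contingency table,
#' with weights normalized so the effective total equals the unweighted
#' sample size. This is an approximation that ignores the survey design
#' (no strata/PSU adjustment) and is intended for the significance stars of
#' descriptive tables. Levels with zero total weight are collapsed out with
#' a warning.
#'
#' @inheritParams prevalence_table
#' @return an object of class `htest` (statistic, df, p-value).
#' @export
association_test <- function(data, covariate, outcome = "outcome",
                             weight = "weight") {
  x <- data[[covariate]]
  y <- data[[outcome]]
  w <- data[[weight]]
  check_weights(w, nrow(data))
  lv <- covariate_levels(x, covariate)
  n <- length(w)
  wn <- w * n / sum(w)
  tab <- vapply(c(0, 1), function(o) {
    vapply(lv, function(l) sum(wn[as.character(x) == l & y == o]), numeric(1))
  }, numeric(length(lv)))
  tab <- matrix(tab, nrow = length(lv),
                dimnames = list(lv, c("0", "1")))
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("level(s) with zero weight collapsed out: ",
            paste(lv[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  if (nrow(tab) < 2) stop("need at least 2 nonempty levels in '", covariate, "'")
  suppressWarnings(stats::chisq.test(tab, correct = FALSE))
}
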