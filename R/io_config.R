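#' Analysis configuration
#'
#' Declares the variable roles the pipeline needs: the binary outcome column
#' and the label coded 1, the weight column, how wealth enters (raw asset
#' indicators, a precomputed continuous score, or precomputed quintile
#' labels), the categorical covariates with their level order and reference
#' level, missing-value sentinels and output rounding.
#'
#' @param outcome name of the outcome column.
#' @param weight name of the sampling-weight column.
#' @param wealth_mode one of `"assets"`, `"score"`, `"quintile"`.
#' @param asset_columns character vector of asset-indicator columns
#'   (required for mode `"assets"`).
#' @param wealth_column column holding the score or quintile (modes
#'   `"score"`/`"quintile"`).
#' @param covariates named list: covariate -> list(`levels`, `reference`);
#'   `reference` defaults to the first level.
#' @param outcome_positive label (or number) in the outcome column mapped to
#'   1; every other declared label maps to 0.
#' @param outcome_labels all labels the outcome column may take; values
#'   outside this set raise an error. 0/1 numeric outcomes pass through.
#' @param missing_tokens strings read as missing.
#' @param rounding decimal places for formatted report tables.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(outcome = "outcome",
                            weight = "weight",
                            wealth_mode = c("assets", "score", "quintile"),
                            asset_columns = NULL,
                            wealth_column = NULL,
                            covariates = NULL,
                            outcome_positive = "modern method",
                            outcome_labels = c("modern method", "other methods"),
                            missing_tokens = c("", "NA"),
                            rounding = 4) {
  wealth_mode <- match.arg(wealth_mode)
  if (outcome == weight) stop("outcome and weight columns must be distinct")
  if (wealth_mode == "assets" && is.null(asset_columns)) {
    stop("wealth_mode 'assets' requires asset_columns")
  }
  if (wealth_mode != "assets" && is.null(wealth_column)) {
    stop("wealth_mode '", wealth_mode, "' requires wealth_column")
  }
  if (is.null(covariates)) {
    covariates <- lapply(default_covariate_spec(), function(cv) {
      list(levels = cv$levels, reference = cv$levels[1])
    })
  }
  if (anyDuplicated(names(covariates))) stop("duplicate covariate names")
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (is.null(cv$reference)) covariates[[nm]]$reference <- cv$levels[1]
    else if (!cv$reference %in% cv$levels) {
      stop("reference '", cv$reference, "' is not a level of '", nm, "'")
    }
  }
  if (!outcome_positive %in% outcome_labels) {
    outcome_labels <- c(outcome_positive, outcome_labels)
  }
  structure(list(outcome = outcome, weight = weight,
                 wealth_mode = wealth_mode, asset_columns = asset_columns,
                 wealth_column = wealth_column, covariates = covariates,
                 outcome_positive = outcome_positive,
                 outcome_labels = outcome_labels,
                 missing_tokens = missing_tokens, rounding = rounding),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path path to a YAML file whose keys mirror the arguments of
#'   [analysis_config()].
#' @return an `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y)
}

#' Load survey microdata from CSV
#'
#' Reads a CSV with one row per respondent, applies the missing-value
#' sentinels, coerces the outcome to 0/1 from the declared positive label,
#' validates weights as positive reals, and turns each declared covariate
#' into a factor with its declared level order. Undeclared outcome labels,
#' undeclared covariate values and nonpositive weights raise errors (with
#' the row number where relevant). Missing covariate cells are retained:
#' apply [drop_incomplete()] before analysis.
#'
#' @param path CSV file path (header row required, RFC-4180 quoting).
#' @param config an [analysis_config()] object.
#' @return a `data.frame` ready for the pipeline.
#' @export
load_dataset <- function(path, config) {
  stopifnot(inherits(config, "analysis_config"))
  raw <- utils::read.csv(path, check.names = FALSE,
                         na.strings = config$missing_tokens,
                         stringsAsFactors = FALSE)
  need <- c(config$outcome, config$weight, names(config$covariates),
            config$asset_columns, config$wealth_column)
  absent <- setdiff(need, names(raw))
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }

  y <- raw[[config$outcome]]
  if (is.numeric(y) && all(y %in% c(0, 1))) {
    raw[[config$outcome]] <- as.integer(y)
  } else {
    y <- as.character(y)
    unknown <- setdiff(unique(y), config$outcome_labels)
    if (length(unknown)) {
      stop("unknown outcome label '", unknown[1], "'")
    }
    raw[[config$outcome]] <- as.integer(y == config$outcome_positive)
  }

  w <- suppressWarnings(as.numeric(raw[[config$weight]]))
  bad <- which(is.na(w) | w <= 0)
  if (length(bad)) stop("nonpositive or unreadable weight at row ", bad[1])
  raw[[config$weight]] <- w

  for (nm in names(config$covariates)) {
    lv <- config$covariates[[nm]]$levels
    x <- as.character(raw[[nm]])
    unknown <- setdiff(unique(x[!is.na(x)]), lv)
    if (length(unknown)) {
      stop("undeclared category '", unknown[1], "' in covariate '", nm, "'")
    }
    raw[[nm]] <- factor(x, levels = lv)
  }
  if (config$wealth_mode == "quintile") {
    qlv <- c("poorest", "poorer", "middle", "richer", "richest")
    x <- as.character(raw[[config$wealth_column]])
    unknown <- setdiff(unique(x[!is.na(x)]), qlv)
    if (length(unknown)) {
      stop("undeclared wealth quintile label '", unknown[1], "'")
    }
    raw[[config$wealth_column]] <- factor(x, levels = qlv, ordered = TRUE)
  }
  log_msg("load_dataset", nrow(raw), " record(s) read from ", path)
  raw
}

#' Write survey microdata to CSV
#'
#' @param data data frame to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
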