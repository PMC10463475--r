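p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

fmt_or <- function(or, lo, hi, stars = "") {
  ifelse(is.na(lo), "Reference (1.0)",
         sprintf("%.2f%s (%.2f-%.2f)", or, stars, lo, hi))
}

#' Assemble the result tables and figures of an analysis run
#'
#' Writes the standard outputs of the pipeline to `outdir`:
#' \describe{
#'   \item{table1.csv}{prevalence by covariate category with chi-square
#'     significance stars per covariate block}
#'   \item{table2.csv}{crude and adjusted odds ratios formatted
#'     `"x.xx (a.aa-b.bb)"`}
#'   \item{table3.csv}{decomposition rows (4 decimal places by default),
#'     reference rows blank, residual row appended}
#'   \item{fig1.csv / fig1.png}{weighted outcome prevalence by wealth
#'     quintile (bar chart)}
#'   \item{fig2.csv / fig2.png}{concentration curve with equality line}
#'   \item{loadings.csv}{PCA asset loadings, when the wealth index was
#'     computed from assets}
#'   \item{metadata.yaml}{seed, record counts, config fingerprint}
#' }
#' All numbers are written to the CSVs; figures are regenerated from the CSV
#' data only and are decorative artifacts. If no graphics device is
#' available the PNGs are skipped with a warning.
#'
#' @param analysis an [run_analysis()] result.
#' @param outdir output directory (created if absent).
#' @param seed optional integer recorded in the run metadata.
#' @param figures logical; render PNG figures.
#' @return an object of class `report_bundle`: named list of file paths plus
#'   the run metadata.
#' @export
build_report <- function(analysis, outdir, seed = NULL, figures = TRUE) {
  if (!inherits(analysis, "inequidec_analysis")) {
    stop("missing or invalid stage output: analysis")
  }
  for (stage in c("descriptives", "regression", "decomposition", "concentration")) {
    if (is.null(analysis[[stage]])) stop("missing stage output: ", stage)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  digits <- analysis$config$rounding

  # ---- table 1: prevalence by category, stars per covariate block
  t1 <- do.call(rbind, lapply(names(analysis$descriptives), function(cv) {
    blk <- analysis$descriptives[[cv]]
    tab <- blk$table
    tab$stars <- p_stars(blk$test$p.value)
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], round, digits = 1)
    tab
  }))
  paths$table1 <- file.path(outdir, "table1.csv")
  utils::write.csv(t1, paths$table1, row.names = FALSE)

  # ---- table 2: cOR and aOR side by side
  cr <- analysis$regression$crude
  ad <- analysis$regression$adjusted
  stopifnot(identical(cr$covariate, ad$covariate), identical(cr$level, ad$level))
  t2 <- data.frame(
    covariate = cr$covariate, level = cr$level,
    cOR = fmt_or(cr$odds_ratio, cr$ci_low, cr$ci_high,
                 vapply(cr$p_value, p_stars, character(1))),
    aOR = fmt_or(ad$odds_ratio, ad$ci_low, ad$ci_high,
                 vapply(ad$p_value, p_stars, character(1))),
    stringsAsFactors = FALSE
  )
  paths$table2 <- file.path(outdir, "table2.csv")
  utils::write.csv(t2, paths$table2, row.names = FALSE)

  # ---- table 3: decomposition with blank reference rows and residual row
  dec <- analysis$decomposition
  refs <- attr(dec, "references")
  rows <- list()
  for (cv in unique(dec$covariate)) {
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cv, level = refs[[cv]], elasticity = "", ck = "",
      absolute_contribution = "", percentage_contribution = "",
      stringsAsFactors = FALSE)
    sub <- dec[dec$covariate == cv, ]
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cv, level = sub$level,
      elasticity = sprintf("%.*f", digits, sub$elasticity),
      ck = sprintf("%.*f", digits, sub$ck),
      absolute_contribution = sprintf("%.*f", digits, sub$absolute_contribution),
      percentage_contribution = sprintf("%.*f", digits, sub$percentage_contribution),
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    covariate = "residual", level = "GC/mu", elasticity = "", ck = "",
    absolute_contribution = sprintf("%.*f", digits, attr(dec, "residual")),
    percentage_contribution = sprintf("%.*f", digits, attr(dec, "residual_pct")),
    stringsAsFactors = FALSE)
  paths$table3 <- file.path(outdir, "table3.csv")
  utils::write.csv(do.call(rbind, rows), paths$table3, row.names = FALSE)

  # ---- fig 1 data: prevalence by wealth quintile
  q1 <- analysis$descriptives$wealth_quintile$table
  f1 <- data.frame(quintile = q1$level, prevalence_pct = q1$prevalence_pct,
                   stringsAsFactors = FALSE)
  if (anyNA(f1$prevalence_pct)) {
    warning("empty wealth quintile(s) rendered at 0: ",
            paste(f1$quintile[is.na(f1$prevalence_pct)], collapse = ", "))
    f1$prevalence_pct[is.na(f1$prevalence_pct)] <- 0
  }
  paths$fig1_data <- file.path(outdir, "fig1.csv")
  utils::write.csv(f1, paths$fig1_data, row.names = FALSE)

  # ---- fig 2 data: concentration curve points
  paths$fig2_data <- file.path(outdir, "fig2.csv")
  utils::write.csv(analysis$concentration$curve$points, paths$fig2_data,
                   row.names = FALSE)

  if (!is.null(analysis$wealth)) {
    paths$loadings <- file.path(outdir, "loadings.csv")
    utils::write.csv(data.frame(asset = names(analysis$wealth$loadings),
                                loading = analysis$wealth$loadings,
                                row.names = NULL),
                     paths$loadings, row.names = FALSE)
  }

  if (figures) {
    ok <- tryCatch({
      d1 <- utils::read.csv(paths$fig1_data, stringsAsFactors = FALSE)
      d1$quintile <- factor(d1$quintile, levels = d1$quintile)
      g1 <- ggplot2::ggplot(d1, ggplot2::aes(x = quintile, y = prevalence_pct)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = "Wealth quintile", y = "Outcome prevalence (%)") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(outdir, "fig1.png"), g1,
                      width = 6, height = 4, dpi = 150)
      d2 <- utils::read.csv(paths$fig2_data)
      g2 <- ggplot2::ggplot(d2, ggplot2::aes(x = pop_share, y = outcome_share)) +
        ggplot2::geom_line(linewidth = 0.8) +
        ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
        ggplot2::labs(x = "Cumulative population share (poorest first)",
                      y = "Cumulative outcome share") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(outdir, "fig2.png"), g2,
                      width = 5, height = 5, dpi = 150)
      TRUE
    }, error = function(e) {
      warning("figure rendering skipped: ", conditionMessage(e))
      FALSE
    })
    if (ok) {
      paths$fig1 <- file.path(outdir, "fig1.png")
      paths$fig2 <- file.path(outdir, "fig2.png")
    }
  }

  meta <- list(seed = seed,
               n_input = analysis$meta$n_input,
               n_complete = analysis$meta$n_complete,
               n_dropped = analysis$meta$n_dropped,
               config_hash = config_fingerprint(analysis$config),
               cix = analysis$concentration$cix)
  paths$metadata <- file.path(outdir, "metadata.yaml")
  yaml::write_yaml(meta, paths$metadata)

  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing)) {
    stop("report file(s) not written: ",
         paste(unlist(paths[missing]), collapse = ", "))
  }
  structure(c(paths, list(meta = meta)), class = "report_bundle")
}

# Polynomial rolling hash over the deparsed config: a stable plain-R
# fingerprint for run metadata, not a cryptographic hash.
config_fingerprint <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
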