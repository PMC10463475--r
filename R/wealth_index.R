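#' Asset-based wealth index via principal component analysis
#'
#' Constructs the household wealth score as the first principal component of
#' the standardized binary asset indicators, the standard DHS construction.
#' Each asset column is standardized to weighted mean 0 and weighted variance
#' 1 (population moments), the weighted correlation matrix is
#' eigen-decomposed, and the score is the projection on the leading
#' eigenvector. The eigenvector sign is fixed so that the asset with the
#' largest absolute loading has a positive loading.
#'
#' Zero-variance assets carry no information and are excluded with a warning;
#' if no asset varies the index is undefined and an error is raised.
#'
#' @param assets numeric matrix or data frame of asset indicators
#'   (rows = households/records, columns = assets).
#' @param weights positive sampling weights, one per row.
#' @return an object of class `wealth_index`: a list with `score` (one value
#'   per record), `loadings` (named, one per retained asset),
#'   `explained_share` (share of total variance on the first component) and
#'   `dropped_assets` (names of excluded zero-variance assets).
#' @examples
#' a <- cbind(tv = c(0, 0, 1, 1), radio = c(0, 1, 0, 1))
#' wealth_index(a, rep(1, 4))$score
#' @export
wealth_index <- function(assets, weights) {
  assets <- as.matrix(assets)
  if (is.null(colnames(assets))) {
    colnames(assets) <- sprintf("asset_%02d", seq_len(ncol(assets)))
  }
  n <- nrow(assets)
  if (n < 3) stop("at least 3 records are required")
  check_weights(weights, n)

  v <- apply(assets, 2, wvar, w = weights)
  keep <- v > 1e-12
  if (!any(keep)) stop("all asset indicators are constant; wealth index undefined")
  if (any(!keep)) {
    log_msg("wealth_index", "excluding zero-variance asset(s): ",
            paste(colnames(assets)[!keep], collapse = ", "))
    warning("zero-variance asset(s) excluded: ",
            paste(colnames(assets)[!keep], collapse = ", "))
  }
  if (sum(keep) < 2) stop("fewer than 2 assets with nonzero variance")
  A <- assets[, keep, drop = FALSE]

  p <- wnorm(weights)
  m <- colSums(p * A)
  Z <- sweep(sweep(A, 2, m), 2, sqrt(v[keep]), "/")
  R <- crossprod(Z, p * Z)          # weighted correlation matrix
  e <- eigen(R, symmetric = TRUE)
  v1 <- e$vectors[, 1]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  structure(list(score = drop(Z %*% v1),
                 loadings = stats::setNames(v1, colnames(A)),
                 explained_share = e$values[1] / sum(e$values),
                 dropped_assets = colnames(assets)[!keep]),
            class = "wealth_index")
}

#' @export
print.wealth_index <- function(x, ...) {
  cat("Asset-based wealth index (first principal component)\n")
  cat(sprintf("  assets retained: %d; variance explained: %.1f%%\n",
              length(x$loadings), 100 * x$explained_share))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Assign weighted wealth quintiles
#'
#' Sorts records by wealth score and cuts the cumulative weight at 20/40/60/
#' 80% of the total. Records with tied scores form a block sharing one
#' quintile: the quintile containing the block's cumulative-weight midpoint.
#' With equal weights, distinct scores and `n` divisible by 5 this yields
#' exact 20% groups.
#'
#' @param score numeric wealth scores (finite).
#' @param weights positive sampling weights.
#' @return an ordered factor with levels
#'   `poorest < poorer < middle < richer < richest`.
#' @examples
#' assign_quintiles(1:10, rep(1, 10))
#' @export
assign_quintiles <- function(score, weights) {
  if (!all(is.finite(score))) stop("scores must be finite")
  check_weights(weights, length(score))
  labels <- c("poorest", "poorer", "middle", "richer", "richest")

  ord <- order(score)
  w <- weights[ord]
  s <- score[ord]
  total <- sum(w)
  # tie blocks: runs of equal score in sorted order
  block <- cumsum(c(TRUE, diff(s) > 0))
  bw <- tapply(w, block, sum)
  cum_hi <- cumsum(bw)
  mid <- (cum_hi - bw / 2) / total
  q_block <- findInterval(mid, c(0.2, 0.4, 0.6, 0.8)) + 1L
  q <- integer(length(score))
  q[ord] <- q_block[block]
  factor(labels[q], levels = labels, ordered = TRUE)
}
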