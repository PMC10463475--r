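# Internal weighted-moment helpers. All of these use *population* (uncorrected)
# weighted moments: the concentration index and its decomposition are exact
# algebraic identities only under the uncorrected covariance.

wnorm <- function(w) w / sum(w)

wmean <- function(x, w) sum(wnorm(w) * x)

wvar <- function(x, w) {
  p <- wnorm(w)
  m <- sum(p * x)
  sum(p * (x - m)^2)
}

wcov <- function(x, y, w) {
  p <- wnorm(w)
  mx <- sum(p * x)
  my <- sum(p * y)
  sum(p * (x - mx) * (y - my))
}

check_weights <- function(w, n = NULL) {
  if (!is.numeric(w) || anyNA(w)) stop("weights must be numeric with no missing values")
  bad <- which(w <= 0)
  if (length(bad)) stop("nonpositive weight at row ", bad[1])
  if (!is.null(n) && length(w) != n) stop("weights length does not match data")
  invisible(w)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the prior
#' RNG state, so seeded simulation calls do not disturb the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stage-tagged logging to stderr.
log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
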