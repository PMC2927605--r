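#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames vcov coef complete.cases
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Outcome vocabulary used throughout: "respondent" is always the reference.
ATTRITION_OUTCOMES <- c("respondent", "dead", "frail", "withdrawn", "lost")

STATUS_COLUMNS <- paste0("status_s", 2:5)

assert_proportion <- function(x, name, open_upper = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  }
  hi_ok <- if (open_upper) all(x < 1) else all(x <= 1)
  if (!all(x >= 0) || !hi_ok) {
    stop(sprintf("'%s' must lie in [0,%s]", name, if (open_upper) "1)" else "1"),
         call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched. seed = NULL runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Row-wise categorical sampler: prob is an n x k matrix of row-stochastic
# probabilities; returns integer column indices. One uniform per row.
sample_rowwise <- function(prob) {
  stopifnot(is.matrix(prob))
  cum <- t(apply(prob, 1L, cumsum))
  u <- runif(nrow(prob)) * cum[, ncol(cum)]
  1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
}
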