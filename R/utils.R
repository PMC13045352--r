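#' @keywords internal
#' @importFrom stats median sd rnorm runif rpois pnorm quantile setNames
#' @importFrom utils write.csv
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the state, so package functions that take a `seed` argument never
#' disturb the session RNG stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_vec3 <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 3L)
    stop(sprintf("'%s' must be a numeric 3-vector", name), call. = FALSE)
  if (finite && any(!is.finite(x)))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  as.numeric(x)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  as.numeric(x)
}

#' Row-wise Euclidean norms
#' @noRd
row_norms <- function(m) sqrt(rowSums(m * m))

#' Normalise rows to unit length (zero rows stay zero)
#' @noRd
normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

#' Median absolute deviation scaled to the normal (like stats::mad)
#' @noRd
mad_scale <- function(x) stats::median(abs(x - stats::median(x))) * 1.4826
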