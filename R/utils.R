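# Internal helpers: argument checking and seed scoping.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

check_number <- function(x, name, min = -Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' must be supplied", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < min)
    stop(sprintf("'%s' must be >= %g (got %g)", name, min, x), call. = FALSE)
  invisible(x)
}

check_finite_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len)
    stop(sprintf("'%s' must be a numeric vector of length >= %d",
                 name, min_len), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}

# Simple OLS of y on x returning slope, intercept, residuals and hat values.
# Used throughout instead of lm() where only the closed form is needed and
# speed matters (cross-validation grids, bootstrap refits).
ols_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop("zero variance in the predictor", call. = FALSE)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  resid <- y - fitted
  hat <- 1 / n + (x - mx)^2 / sxx
  list(slope = slope, intercept = intercept, fitted = fitted,
       residuals = resid, hat = hat, rss = sum(resid^2), n = n)
}
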