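# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom stats cor sd var median quantile qnorm rnorm runif rbinom
#'   rlnorm rexp rpois cov cor.test hclust dist cutree pnorm
NULL

# column-demean a matrix, ignoring NA
demean_cols <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sweep(x, 2, mu, "-")
}

# global variance normalization: divide by the sd of all (non-missing) entries
global_sd <- function(x) stats::sd(as.vector(x), na.rm = TRUE)

# check a numeric scalar
assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name) {
  assert_scalar(x, name, lower = 0)
  if (x != as.integer(x)) stop(sprintf("`%s` must be a non-negative integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# Pearson correlations between one vector and every column of a matrix,
# using pairwise-complete rows per column.  Returns a length-ncol vector.
cor_vec_cols <- function(v, m) {
  vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    ok <- is.finite(x) & is.finite(v)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(v[ok]) == 0) return(NA_real_)
    stats::cor(v[ok], x[ok])
  }, numeric(1))
}

# fast correlation of one complete vector against complete matrix columns
cor_vec_cols_complete <- function(v, m) {
  v <- v - mean(v)
  m <- demean_cols(m)
  num <- as.vector(crossprod(m, v))
  den <- sqrt(colSums(m^2)) * sqrt(sum(v^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
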