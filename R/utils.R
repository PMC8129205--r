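#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist hclust cutree prcomp p.adjust wilcox.test quantile
#'   rnorm runif rbinom rgamma rgeom rexp sd var complete.cases setNames aggregate
#'   predict lm coef dnorm qnorm uniroot
#' @importFrom utils head tail read.csv write.csv
NULL

# clamp values into [0, 1]
clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: keeps dim attributes

# min-max normalize a numeric array to [0, 1]; constant arrays map to 0
norm01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] - r[1] <= .Machine$double.eps) {
    return(array(0, dim = dim(x) %||% length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Separable Gaussian convolution with symmetric-reflection padding.
# sigma in pixels; kernel truncated at 3 sigma.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  m <- apply_sep_kernel(m, k)
  t(apply_sep_kernel(t(m), k))
}

# convolve each column of m with kernel k, reflecting at borders
apply_sep_kernel <- function(m, k) {
  n <- nrow(m)
  half <- (length(k) - 1L) %/% 2L
  idx <- seq_len(n)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    src <- idx + (j - half - 1L)
    src <- reflect_index(src, n)
    out <- out + k[j] * m[src, , drop = FALSE]
  }
  out
}

# symmetric (mirror, no repeated edge) index reflection into 1..n
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  ifelse(i >= n, period - i, i) + 1L
}

# deterministic child seed derived from a root seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) * 69069 + as.integer(k) * 12345) %% 2147483563L
}
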