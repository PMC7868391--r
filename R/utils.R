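#' @importFrom stats rnorm sd var qt fft quantile setNames runif cor
#' @importFrom utils head tail write.csv read.csv modifyList
#' @importFrom rlang %||% .data
NULL

# Deterministic substream seeds: fold any number of non-negative integer tags
# into a single seed below 2^31 - 1 (LCG fold in double arithmetic; exact
# because all intermediates stay below 2^53).
substream_seed <- function(master, ...) {
  tags <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (x in as.numeric(tags)) {
    s <- (s * 69069 + x + 12345) %% 2147483647
  }
  as.integer(s)
}

# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's state afterwards (so library code never disturbs user RNG).
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
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Row-wise Euclidean norms of a matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Symmetric part (guards tiny asymmetries from floating point).
symmpart_dense <- function(m) (m + t(m)) / 2

# Principal square root / inverse of a symmetric positive-definite 3x3 block.
spd_sqrt <- function(m) {
  e <- eigen(symmpart_dense(m), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

spd_solve <- function(m, rhs = diag(nrow(m)), tol = 1e-12) {
  e <- eigen(symmpart_dense(m), symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) stopf("matrix is numerically zero; cannot invert")
  inv <- e$vectors[, keep, drop = FALSE] %*%
    ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
  inv %*% rhs
}

# Moore-Penrose pseudo-inverse via SVD (dense, small matrices).
pinv <- function(m, tol = NULL) {
  s <- svd(m)
  if (is.null(tol)) tol <- max(dim(m)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}
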