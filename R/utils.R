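#' @useDynLib cellpath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head read.csv write.csv
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Zero-based (row, col) <-> 1-based column-major linear index. All user-facing
# pixel coordinates in this package are zero-based.
rc_to_index <- function(row, col, H) as.integer(col) * H + as.integer(row) + 1L
index_to_rc <- function(idx, H) {
  idx <- as.integer(idx) - 1L
  data.frame(row = idx %% H, col = idx %/% H)
}

# Separable Gaussian smoothing with renormalized (truncated) boundary
# handling; `x` is a plain numeric matrix.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  smooth_1d <- function(n) {
    rad <- max(1L, as.integer(ceiling(3 * sigma)))
    g <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - rad):(i + rad)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- g[ok]
      K[i, ] <- K[i, ] / sum(K[i, ])
    }
    K
  }
  Kh <- smooth_1d(nrow(x))
  Kw <- smooth_1d(ncol(x))
  Kh %*% x %*% t(Kw)
}

# Mean filter over a k x k window (k odd), truncated at image borders.
box_mean <- function(x, k) {
  rad <- (k - 1L) %/% 2L
  smooth_1d <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - rad):min(n, i + rad)
      K[i, j] <- 1 / length(j)
    }
    K
  }
  smooth_1d(nrow(x)) %*% x %*% t(smooth_1d(ncol(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_image_matrix <- function(x) is.matrix(x) && is.numeric(x)

check_image <- function(x, what = "image") {
  if (!is_image_matrix(x)) stopf("%s must be a numeric matrix", what)
  if (anyNA(x)) stopf("%s contains missing values", what)
  invisible(x)
}
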