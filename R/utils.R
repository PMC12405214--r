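# Internal numerical helpers shared across modules.

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 pmap map_dbl map_int map_lgl
NULL

#' Normalised 1D Gaussian kernel
#'
#' @param sigma standard deviation in pixels (> 0).
#' @param radius half-width; defaults to `ceiling(3 * sigma)`.
#' @return numeric vector of length `2 * radius + 1` summing to 1.
#' @keywords internal
#' @noRd
gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Replicate-pad a matrix by `p` pixels on every side.
pad_replicate <- function(x, p) {
  if (p == 0) return(x)
  ri <- pmin(pmax(seq_len(nrow(x) + 2 * p) - p, 1L), nrow(x))
  ci <- pmin(pmax(seq_len(ncol(x) + 2 * p) - p, 1L), ncol(x))
  x[ri, ci, drop = FALSE]
}

# 2D convolution with an arbitrary (odd-sized) kernel, replicate boundary.
# Implemented as a sum of shifted copies; kernels here are small (<= 21x21).
conv2_replicate <- function(x, kernel) {
  kh <- nrow(kernel)
  kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  p <- max((kh - 1) %/% 2, (kw - 1) %/% 2)
  xp <- pad_replicate(x, p)
  out <- matrix(0, nrow(x), ncol(x))
  oh <- p - (kh - 1L) %/% 2L
  ow <- p - (kw - 1L) %/% 2L
  for (i in seq_len(kh)) {
    rows <- (oh + i - 1L) + seq_len(nrow(x))
    for (j in seq_len(kw)) {
      w <- kernel[i, j]
      if (w == 0) next
      cols <- (ow + j - 1L) + seq_len(ncol(x))
      out <- out + w * xp[rows, cols]
    }
  }
  out
}

# Separable Gaussian blur with replicate boundary.
gauss_blur <- function(x, sigma, radius = ceiling(3 * sigma)) {
  k <- gaussian_kernel_1d(sigma, radius)
  p <- radius
  xp <- pad_replicate(x, p)
  # rows
  tmp <- matrix(0, nrow(x), ncol(xp))
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * xp[(i - 1L) + seq_len(nrow(x)), , drop = FALSE]
  }
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, (j - 1L) + seq_len(ncol(x)), drop = FALSE]
  }
  out
}

# Stable ordering: highest score first, ties by original position.
order_desc_stable <- function(scores) {
  order(-scores, seq_along(scores))
}

is_binary_matrix <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1, FALSE, TRUE))
}

assert_same_shape <- function(a, b, what = "arrays") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s must have identical shapes (got %s vs %s)",
                  what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

# Run a block with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
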