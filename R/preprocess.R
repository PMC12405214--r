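# Preprocessing: LoG-filtered images for radiomics, and standardized patches
# for the networks. Everything here is deterministic.

#' The three Laplacian-of-Gaussian scales
#'
#' Returns the fine / medium / coarse LoG scales used throughout the package.
#' In-plane kernel sizes are 3, 5, and 7 pixels; the default sigmas (0.5,
#' 1.0, 1.5 px) are chosen so that the ~3-sigma support of the Gaussian
#' matches those kernel widths. Analysis is strictly 2D, so only in-plane
#' kernels exist.
#'
#' @param sigmas optional length-3 numeric overriding the default sigmas.
#' @return a tibble with columns `name`, `kernel_size`, `sigma`.
#' @export
log_scales <- function(sigmas = c(0.5, 1.0, 1.5)) {
  stopifnot(length(sigmas) == 3, all(sigmas > 0))
  tibble(
    name = c("fine", "medium", "coarse"),
    kernel_size = c(3L, 5L, 7L),
    sigma = as.numeric(sigmas)
  )
}

#' Laplacian-of-Gaussian filter
#'
#' Gaussian smoothing with a normalised kernel of the scale's in-plane
#' support (`kernel_size`), followed by the 5-point discrete Laplacian; both
#' convolutions use replicate boundary handling. The combined operation is
#' the response of the discrete LoG kernel at that scale; a constant image
#' maps to an exactly zero response, and responses may be negative.
#'
#' @param image numeric matrix.
#' @param scale one row of [log_scales()] (or a list with `kernel_size` and
#'   `sigma`).
#' @return numeric matrix of the same shape.
#' @export
log_filter <- function(image, scale) {
  if (!all(is.finite(image))) abort("`image` must be finite.")
  ks <- as.integer(scale$kernel_size)
  sigma <- as.numeric(scale$sigma)
  if (length(sigma) != 1 || is.na(sigma) || sigma <= 0) {
    abort("LoG `sigma` must be a positive scalar.")
  }
  r <- (ks - 1L) %/% 2L
  g1 <- gaussian_kernel_1d(sigma, radius = r)
  smoothed <- conv2_replicate(image, outer(g1, g1))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  conv2_replicate(smoothed, lap)
}

#' Central crop around the mask centroid
#'
#' Extracts a `size` x `size` window centred on the (pixel-rounded) centroid
#' of the mask foreground; windows extending past the image border are
#' edge-padded by replication.
#'
#' @param image numeric matrix.
#' @param mask 0/1 matrix of the same shape with at least one foreground pixel.
#' @param size window side in pixels.
#' @return a `size` x `size` numeric matrix.
#' @export
crop_patch <- function(image, mask, size = 32L) {
  assert_same_shape(image, mask, "image and mask")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("`mask` has no foreground pixels.")
  cr <- round(mean(idx[, 1]))
  cc <- round(mean(idx[, 2]))
  half <- size %/% 2L
  rows <- (cr - half) : (cr - half + size - 1L)
  cols <- (cc - half) : (cc - half + size - 1L)
  ri <- pmin(pmax(rows, 1L), nrow(image))
  ci <- pmin(pmax(cols, 1L), ncol(image))
  out <- image[ri, ci, drop = FALSE]
  stopifnot(all(is.finite(out)))
  out
}

# Interpolation weight matrix mapping `from` samples to `to` samples along
# one axis, pixel-centre aligned: src = (dst + 0.5) * from/to - 0.5.
# Cubic uses the Keys kernel (a = -0.5); edge handling clamps sample indices.
resample_matrix <- function(from, to, method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  scale <- from / to
  src <- (seq_len(to) - 0.5) * scale - 0.5 # 0-based source coordinate
  W <- matrix(0, to, from)
  if (method == "bilinear") {
    taps <- 0:1; base <- floor(src)
    wfun <- function(d) pmax(0, 1 - abs(d))
  } else {
    taps <- -1:2; base <- floor(src)
    a <- -0.5
    wfun <- function(d) {
      d <- abs(d)
      ifelse(d <= 1, (a + 2) * d^3 - (a + 3) * d^2 + 1,
             ifelse(d < 2, a * d^3 - 5 * a * d^2 + 8 * a * d - 4 * a, 0))
    }
  }
  for (t in taps) {
    pos <- base + t
    w <- wfun(src - pos)
    cl <- pmin(pmax(pos, 0), from - 1) + 1L
    W[cbind(seq_len(to), cl)] <- W[cbind(seq_len(to), cl)] + w
  }
  sweep(W, 1, rowSums(W), "/")
}

#' Resize a square patch by bicubic (or bilinear) interpolation
#'
#' Separable resampling with the Keys cubic kernel (a = -0.5), pixel-centre
#' aligned, edge-clamped. A constant input maps to the same constant, and
#' both kernels reproduce affine ramps exactly away from numerical noise.
#'
#' @param patch square numeric matrix.
#' @param target output side in pixels.
#' @param method `"bicubic"` (default) or `"bilinear"`.
#' @return `target` x `target` numeric matrix.
#' @export
resize_patch <- function(patch, target = 224L, method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  if (!is.matrix(patch) || nrow(patch) != ncol(patch)) {
    abort("`patch` must be a square matrix.")
  }
  n <- nrow(patch)
  W <- resample_matrix(n, as.integer(target), method)
  W %*% patch %*% t(W)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param mask_a,mask_b 0/1 matrices of identical shape.
#' @return a number in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  assert_same_shape(mask_a, mask_b, "masks")
  a <- mask_a != 0
  b <- mask_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Prepare a network input patch from an ROI sample
#'
#' Crops a `crop_size` patch at the mask centroid, resizes it bicubically to
#' `input_size`, linearly rescales to `[0, 1]` per patch (constant patches
#' map to 0), and replicates to 3 channels.
#'
#' @param image,mask as in [crop_patch()].
#' @param crop_size central crop side (default 32).
#' @param input_size network input side (default 224).
#' @return an `input_size` x `input_size` x 3 array.
#' @export
prepare_patch <- function(image, mask, crop_size = 32L, input_size = 224L) {
  p <- crop_patch(image, mask, crop_size)
  if (input_size != crop_size) p <- resize_patch(p, input_size, "bicubic")
  rng <- range(p)
  p <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1]) else p * 0
  array(p, dim = c(input_size, input_size, 3L))
}
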