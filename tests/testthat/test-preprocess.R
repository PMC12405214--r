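test_that("crop window is centred on the mask centroid", {
  img <- matrix(seq_len(128 * 128) / (128 * 128), 128, 128)
  mask <- matrix(0, 128, 128)
  mask[60:68, 60:68] <- 1 # centroid (64, 64)
  p <- crop_patch(img, mask, 32)
  expect_identical(dim(p), c(32L, 32L))
  expect_identical(p, img[48:79, 48:79])
})

test_that("crops near the border are edge-padded to full size", {
  img <- matrix(rnorm(128 * 128), 128, 128)
  mask <- matrix(0, 128, 128)
  mask[4:6, 4:6] <- 1 # centroid (5, 5): window extends past the border
  p <- crop_patch(img, mask, 32)
  expect_identical(dim(p), c(32L, 32L))
  expect_true(all(is.finite(p)))
  # replicated edge rows: out-of-range rows clamp to row 1
  expect_identical(p[1, ], p[2, ])
})

test_that("centroid of an irregular mask matches direct coordinate averaging", {
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- matrix(0, 64, 64)
  mask[10:30, 12] <- 1
  mask[30, 12:25] <- 1 # L-shape
  idx <- which(mask == 1, arr.ind = TRUE)
  cr <- round(mean(idx[, 1])); cc <- round(mean(idx[, 2]))
  p <- crop_patch(img, mask, 8)
  expect_identical(p, img[(cr - 4):(cr + 3), (cc - 4):(cc + 3)])
})

test_that("empty mask is rejected", {
  expect_error(crop_patch(matrix(1, 8, 8), matrix(0, 8, 8)), "foreground")
})

test_that("bicubic resize: shape, constancy, and affine reproduction", {
  const <- matrix(0.5, 32, 32)
  out <- resize_patch(const, 224)
  expect_identical(dim(out), c(224L, 224L))
  expect_lt(max(abs(out - 0.5)), 1e-6)
  # both kernels reproduce a linear ramp away from the clamped borders
  ramp <- matrix(rep(seq(0, 1, length.out = 32), each = 32), 32, 32)
  bc <- resize_patch(ramp, 96, "bicubic")
  bl <- resize_patch(ramp, 96, "bilinear")
  interior <- 7:90
  expect_lt(max(abs(bc[interior, interior] - bl[interior, interior])), 1e-6)
  # exact linearity of the interior bicubic reconstruction
  slope <- (ramp[1, 2] - ramp[1, 1]) / 3 # output grid is 3x finer
  expect_lt(max(abs(diff(bc[48, interior]) - slope)), 1e-9)
  expect_error(resize_patch(matrix(0, 4, 5)), "square")
})

test_that("LoG responds zero to constants and matches the impulse oracle", {
  sc <- log_scales()[2, ]
  expect_lt(max(abs(log_filter(matrix(3.7, 40, 40), sc))), 1e-12)
  # impulse response away from borders equals the discrete LoG kernel,
  # reconstructed here by direct convolution of an independent Gaussian
  # with the 5-point Laplacian
  img <- matrix(0, 41, 41)
  img[21, 21] <- 1
  resp <- log_filter(img, sc)
  r <- (sc$kernel_size - 1) / 2
  xs <- -r:r
  g1 <- exp(-xs^2 / (2 * sc$sigma^2)); g1 <- g1 / sum(g1)
  G <- outer(g1, g1)
  ker <- matrix(0, sc$kernel_size + 2, sc$kernel_size + 2)
  lap <- rbind(c(0, 1, 0), c(1, -4, 1), c(0, 1, 0))
  for (i in 1:3) for (j in 1:3) {
    ker[(i - 1) + seq_len(sc$kernel_size), (j - 1) + seq_len(sc$kernel_size)] <-
      ker[(i - 1) + seq_len(sc$kernel_size), (j - 1) + seq_len(sc$kernel_size)] + lap[i, j] * G
  }
  ker <- ker[1 + seq_len(sc$kernel_size), 1 + seq_len(sc$kernel_size)]
  # response at (21 + dr, 21 + dc) is kernel value at (-dr, -dc); symmetric kernel
  sub <- resp[21 + (-r:r), 21 + (-r:r)]
  expect_equal(sub, ker, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(log_filter(img, list(kernel_size = 5, sigma = -1)), "positive")
})

test_that("LoG is linear: aX + b maps to a * LoG(X)", {
  withr::with_seed(3, {
    x <- matrix(runif(30 * 30), 30, 30)
    for (i in seq_len(3)) {
      sc <- log_scales()[i, ]
      base <- log_filter(x, sc)
      expect_lt(max(abs(log_filter(2.5 * x + 0.7, sc) - 2.5 * base)), 1e-6)
    }
  })
})

test_that("three LoG scales yield three filtered images", {
  x <- matrix(runif(16), 4, 4)
  out <- lapply(seq_len(nrow(log_scales())), function(i) log_filter(x, log_scales()[i, ]))
  expect_length(out, 3)
  expect_true(all(vapply(out, function(m) identical(dim(m), dim(x)), TRUE)))
})

test_that("dice coefficient: identical, disjoint, hand-counted overlap", {
  a <- matrix(0, 6, 6); a[2:3, 2:3] <- 1
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(0, 6, 6); b[5:6, 5:6] <- 1
  expect_equal(dice_coefficient(a, b), 0)
  shifted <- matrix(0, 6, 6); shifted[2:3, 3:4] <- 1 # overlap on 2 pixels
  expect_equal(dice_coefficient(a, shifted), 0.5)
  expect_equal(dice_coefficient(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  expect_error(dice_coefficient(a, matrix(0, 5, 5)), "identical shapes")
})

test_that("prepared patches are standardized 3-channel arrays", {
  co <- tiny_cohort(n_per_class = 2)
  p <- prepare_patch(co$image[[1]], co$mask[[1]], 32, 64)
  expect_identical(dim(p), c(64L, 64L, 3L))
  expect_gte(min(p), 0); expect_lte(max(p), 1)
  expect_identical(p[, , 1], p[, , 3])
  # deterministic preprocessing chain
  expect_identical(p, prepare_patch(co$image[[1]], co$mask[[1]], 32, 64))
})
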