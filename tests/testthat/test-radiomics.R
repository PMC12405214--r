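test_that("discretization: constants, two-point, histogram oracle", {
  img <- matrix(0.4, 5, 5)
  mk <- matrix(1, 5, 5)
  q <- discretize(img, mk, 8)
  expect_true(all(q$levels == 1))
  img2 <- matrix(c(0, 1), 2, 2)
  q2 <- discretize(img2, matrix(1, 2, 2), 2)
  expect_setequal(unique(as.vector(q2$levels)), c(1L, 2L))
  withr::with_seed(10, {
    img3 <- matrix(runif(100), 10, 10)
    q3 <- discretize(img3, matrix(1, 10, 10), 8)
    counts <- tabulate(q3$levels, 8)
    edges <- seq(min(img3), max(img3), length.out = 9)
    hist_counts <- as.integer(table(cut(as.vector(img3), edges, include.lowest = TRUE)))
    expect_equal(counts, hist_counts)
  })
  expect_error(discretize(img, matrix(0, 5, 5)), "foreground")
})

test_that("first-order features match hand computations", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  mk <- matrix(1, 2, 2)
  f <- firstorder_features(img, mk, "original")
  expect_length(f, 18)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Median"]), 2.5)
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Variance"]), 1.25) # population variance
  expect_equal(unname(f["Energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(30 / 4))
  # constant ROI
  fc <- firstorder_features(matrix(2, 3, 3), matrix(1, 3, 3), "original")
  expect_equal(unname(fc[c("Variance", "Range")]), c(0, 0))
  expect_equal(unname(fc["Energy"]), 9 * 4)
  expect_equal(unname(fc["Uniformity"]), 1)
  # LoG sources omit Total Energy
  fl <- firstorder_features(img, mk, "log")
  expect_length(fl, 17)
  expect_false("TotalEnergy" %in% names(fl))
  expect_true(all(c("Energy", "Maximum", "Range") %in% names(fl)))
})

test_that("skewness and kurtosis agree with direct moment formulas", {
  withr::with_seed(21, {
    img <- matrix(rexp(400), 20, 20)
    mk <- matrix(rbinom(400, 1, 0.7), 20, 20)
    mk[1] <- 1
    f <- firstorder_features(img, mk, "original")
    x <- img[mk == 1]
    m <- mean(x)
    expect_equal(unname(f["Skewness"]),
                 mean((x - m)^3) / mean((x - m)^2)^1.5, tolerance = 1e-12)
    expect_equal(unname(f["Kurtosis"]),
                 mean((x - m)^4) / mean((x - m)^2)^2, tolerance = 1e-12)
    expect_equal(unname(f["MeanAbsoluteDeviation"]), mean(abs(x - m)), tolerance = 1e-12)
  })
})

test_that("2D shape features: square and disk geometry", {
  mk <- matrix(0, 20, 20)
  mk[6:15, 6:15] <- 1 # 10x10 solid square
  s <- shape2d_features(mk)
  expect_length(s, 9)
  expect_equal(unname(s["PixelSurface"]), 100)
  expect_equal(unname(s["MaximumDiameter"]), 9 * sqrt(2))
  expect_equal(unname(s["Elongation"]), 1) # equal principal moments
  expect_equal(unname(s["MeshSurface"]), 99.5) # marching-squares mesh
  # disk of radius 20: sphericity close to the analytic limit of 1
  n <- 64
  xs <- matrix(seq_len(n), n, n); ys <- t(xs)
  disk <- 1 * ((xs - 32)^2 + (ys - 32)^2 <= 20^2)
  sd_ <- shape2d_features(disk)
  expect_gte(unname(sd_["Sphericity"]), 0.95)
  expect_lte(unname(sd_["Sphericity"]), 1.0)
  expect_error(shape2d_features(matrix(0, 4, 4)), "foreground")
})

test_that("texture features on worked examples", {
  # 2x2 checkerboard, horizontal GLCM: only off-diagonal pairs
  q <- structure(list(levels = matrix(c(1L, 2L, 2L, 1L), 2, 2),
                      n_bins = 2L, bin_edges = c(0, 0.5, 1)),
                 class = "quantized_roi")
  glcm <- texture_matrix("glcm", q)
  expect_equal(glcm$deg0, matrix(c(0, 2, 2, 0), 2, 2))
  # constant ROI: joint entropy 0, NGTDM contrast 0
  qc <- discretize(matrix(1, 3, 3), matrix(1, 3, 3), 4)
  fc <- texture_features("glcm", texture_matrix("glcm", qc), 9)
  expect_equal(unname(fc["JointEntropy"]), 0)
  fn <- texture_features("ngtdm", texture_matrix("ngtdm", qc), 9)
  expect_equal(unname(fn["Contrast"]), 0)
  # GLSZM of a constant 3x3 ROI: one zone of size 9
  zm <- texture_matrix("glszm", qc)
  expect_equal(sum(zm), 1)
  expect_equal(zm[1, 9], 1)
  # 1x4 row "1 1 2 2": horizontal runs (1,2) and (2,2); LRE = 4
  qr <- structure(list(levels = matrix(c(1L, 1L, 2L, 2L), 1, 4),
                       n_bins = 2L, bin_edges = c(0, 0.5, 1)),
                  class = "quantized_roi")
  rl <- texture_matrix("glrlm", qr)
  expect_equal(rl$deg0[1, 2], 1)
  expect_equal(rl$deg0[2, 2], 1)
  lre_h <- sum(rl$deg0 %*% diag((1:2)^2)) / sum(rl$deg0)
  expect_equal(lre_h, 4)
  # GLSZM zone of size 9 at top level g: high gray-level zone emphasis g^2
  g <- 4L
  qz <- structure(list(levels = matrix(g, 3, 3), n_bins = 4L,
                       bin_edges = seq(0, 1, length.out = 5)),
                  class = "quantized_roi")
  fz <- texture_features("glszm", texture_matrix("glszm", qz), 9)
  expect_equal(unname(fz["HighGrayLevelZoneEmphasis"]), g^2)
  expect_error(texture_matrix("wavelet", qc), "unknown texture family")
})

test_that("texture matrices reproduce brute-force enumeration on random ROIs", {
  check_texture_matrices_against_oracles(n_trials = 40, seed = 1)
})

test_that("GLCM F-like symmetry: feature families have catalog cardinalities", {
  withr::with_seed(2, {
    q <- random_quantized_roi(6, 4)
    np <- sum(!is.na(q$levels))
    expect_length(texture_features("glcm", texture_matrix("glcm", q), np), 24)
    expect_length(texture_features("glszm", texture_matrix("glszm", q), np), 16)
    expect_length(texture_features("glrlm", texture_matrix("glrlm", q), np), 16)
    expect_length(texture_features("ngtdm", texture_matrix("ngtdm", q), np), 5)
    expect_length(texture_features("gldm", texture_matrix("gldm", q), np), 14)
  })
})
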