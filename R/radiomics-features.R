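# Feature definitions. Gray levels enter the texture formulas as their
# integer bin index i = 1..Ng; logs are base 2 with 0 log 0 = 0.

xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)

#' First-order intensity statistics over in-mask pixels
#'
#' Eighteen statistics for the original image; LoG-filtered sources omit
#' Total Energy (17). Entropy and Uniformity are computed on the same
#' equal-width discretization used for the texture matrices. Variance,
#' skewness and kurtosis use population moments; kurtosis is not
#' excess-corrected.
#'
#' @param image numeric matrix.
#' @param mask 0/1 matrix, same shape, non-empty.
#' @param source_kind `"original"` or `"log"`; controls whether Total Energy
#'   is included.
#' @param n_bins discretization levels for Entropy/Uniformity.
#' @return a named numeric vector (length 18 or 17).
#' @export
firstorder_features <- function(image, mask, source_kind = c("original", "log"),
                                n_bins = 32L) {
  source_kind <- match.arg(source_kind)
  assert_same_shape(image, mask, "image and mask")
  x <- image[mask != 0]
  if (length(x) == 0) abort("`mask` has no foreground pixels.")
  n <- length(x)
  m <- mean(x)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE, type = 7)
  lev <- discretize(image, mask, n_bins)$levels
  p <- tabulate(lev[mask != 0], nbins = n_bins) / n
  mu2 <- mean((x - m)^2)
  mu3 <- mean((x - m)^3)
  mu4 <- mean((x - m)^4)
  robust <- x[x >= qs[1] & x <= qs[5]]
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = sum(x^2), # unit pixel area: numerically equal to Energy
    Entropy = -sum(xlogx(p)),
    Minimum = min(x),
    Percentile10 = qs[1],
    Percentile90 = qs[5],
    Maximum = max(x),
    Mean = m,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (mu2 > 0) mu3 / mu2^1.5 else 0,
    Kurtosis = if (mu2 > 0) mu4 / mu2^2 else 0,
    Variance = mu2,
    Uniformity = sum(p^2)
  )
  if (source_kind == "log") out <- out[setdiff(names(out), "TotalEnergy")]
  out
}

# Marching-squares contour of a binary mask. Vertices sit at midpoints
# between adjacent pixel centres; the diagonal (ambiguous) case is resolved
# as two separate corners. The mesh area comes from exact per-cell polygon
# contributions; the perimeter is measured on the assembled contour after
# two corner-cutting (Chaikin) passes, which removes most of the staircase
# overestimate of the raw midpoint polygon (the raw length of a digitized
# circle is ~5-7% above the true circumference; the smoothed one is within
# ~2%). Smoothing is applied to the length only, not the area.
marching_squares_stats <- function(bw) {
  bwp <- matrix(0L, nrow(bw) + 2L, ncol(bw) + 2L)
  bwp[1L + seq_len(nrow(bw)), 1L + seq_len(ncol(bw))] <- bw * 1L
  h <- nrow(bwp); w <- ncol(bwp)
  a <- bwp[-h, -w] > 0; b <- bwp[-h, -1] > 0
  d <- bwp[-1, -w] > 0; cc <- bwp[-1, -1] > 0
  ncorn <- a + b + cc + d
  diag_case <- (ncorn == 2) & (a == cc) # opposite corners
  area <- sum(
    (ncorn == 1) * 0.125 +
    (ncorn == 2 & !diag_case) * 0.5 +
    diag_case * 0.25 +
    (ncorn == 3) * 0.875 +
    (ncorn == 4) * 1
  )
  # contour segments between edge midpoints, in doubled integer coordinates
  # cell (i,j): T=(2i,2j+1) R=(2i+1,2j+2) B=(2i+2,2j+1) L=(2i+1,2j)
  segs <- list()
  add <- function(cells, ends) {
    idx <- which(cells, arr.ind = TRUE)
    if (nrow(idx) == 0) return(invisible(NULL))
    i <- idx[, 1]; j <- idx[, 2]
    pt <- function(which_pt) switch(which_pt,
      T = cbind(2 * i, 2 * j + 1), R = cbind(2 * i + 1, 2 * j + 2),
      B = cbind(2 * i + 2, 2 * j + 1), L = cbind(2 * i + 1, 2 * j))
    segs[[length(segs) + 1L]] <<- cbind(pt(ends[1]), pt(ends[2]))
    invisible(NULL)
  }
  add((a & !b & !d) | (!a & b & d & cc), c("L", "T"))
  add((b & !a & !cc) | (!b & a & cc & d), c("T", "R"))
  add((cc & !b & !d) | (!cc & b & d & a), c("R", "B"))
  add((d & !a & !cc) | (!d & a & cc & b), c("B", "L"))
  add((a & b & !cc & !d) | (!a & !b & cc & d), c("L", "R"))
  add((a & d & !b & !cc) | (!a & !d & b & cc), c("T", "B"))
  segs <- do.call(rbind, segs)
  perim <- if (is.null(segs) || nrow(segs) == 0) 0 else contour_length(segs)
  list(area = area, perimeter = perim)
}

chaikin_closed <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  pts <- matrix(0, 2 * nrow(poly), 2)
  pts[seq(1, nrow(pts), 2), ] <- 0.75 * poly + 0.25 * nxt
  pts[seq(2, nrow(pts), 2), ] <- 0.25 * poly + 0.75 * nxt
  pts
}

closed_polyline_length <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sum(sqrt(rowSums((poly - nxt)^2)))
}

# chain marching-squares segments into closed loops and measure their
# smoothed length; `segs` is an m x 4 matrix (r1, c1, r2, c2)
contour_length <- function(segs, passes = 2L) {
  m <- nrow(segs)
  k1 <- paste(segs[, 1], segs[, 2])
  k2 <- paste(segs[, 3], segs[, 4])
  adj <- split(rep(seq_len(m), 2L), c(k1, k2))
  used <- rep(FALSE, m)
  total <- 0
  for (s0 in seq_len(m)) {
    if (used[s0]) next
    pts <- list()
    cur_seg <- s0
    cur_key <- k1[s0]
    cur_xy <- segs[s0, 1:2]
    repeat {
      used[cur_seg] <- TRUE
      pts[[length(pts) + 1L]] <- cur_xy
      if (k1[cur_seg] == cur_key) {
        cur_key <- k2[cur_seg]; cur_xy <- segs[cur_seg, 3:4]
      } else {
        cur_key <- k1[cur_seg]; cur_xy <- segs[cur_seg, 1:2]
      }
      cand <- adj[[cur_key]]
      nxt <- cand[!used[cand]]
      if (length(nxt) == 0) break # loop closed
      cur_seg <- nxt[1]
    }
    poly <- do.call(rbind, pts) / 2
    for (p in seq_len(passes)) poly <- chaikin_closed(poly)
    total <- total + closed_polyline_length(poly)
  }
  total
}

#' 2D shape features of a mask
#'
#' Computed on the largest 8-connected component. Mesh surface and perimeter
#' come from a marching-squares polygonal contour with vertices at pixel-edge
#' midpoints; axis lengths come from the principal components of the
#' foreground pixel-centre coordinates (population covariance; axis length
#' `4 * sqrt(eigenvalue)`); the maximum diameter is the largest pairwise
#' distance between boundary pixel centres.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return named numeric vector of the 9 shape features.
#' @export
shape2d_features <- function(mask) {
  if (sum(mask != 0) == 0) abort("`mask` has no foreground pixels.")
  lab <- label_components8(mask != 0)
  sizes <- tabulate(lab[lab > 0L])
  bw <- lab == which.max(sizes)
  ms <- marching_squares_stats(bw)
  coords <- which(bw, arr.ind = TRUE)
  npix <- nrow(coords)
  # boundary pixels: any 4-neighbour outside the component
  inb <- function(dr, dc) {
    rr <- coords[, 1] + dr; cc <- coords[, 2] + dc
    ok <- rr >= 1 & rr <= nrow(bw) & cc >= 1 & cc <= ncol(bw)
    inside <- rep(FALSE, npix)
    inside[ok] <- bw[cbind(rr[ok], cc[ok])]
    inside
  }
  boundary <- !(inb(0, 1) & inb(0, -1) & inb(1, 0) & inb(-1, 0))
  bc <- coords[boundary, , drop = FALSE]
  dmax <- if (nrow(bc) == 1) 0 else max(stats::dist(bc))
  ctr <- colMeans(coords)
  cen <- sweep(coords, 2, ctr)
  cov <- crossprod(cen) / npix
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev[ev < 0] <- 0
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  c(
    MeshSurface = ms$area,
    PixelSurface = as.numeric(npix),
    Perimeter = ms$perimeter,
    PerimeterSurfaceRatio = ms$perimeter / ms$area,
    Sphericity = 2 * sqrt(pi * ms$area) / ms$perimeter,
    MaximumDiameter = dmax,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Elongation = if (major > 0) sqrt(ev[2] / ev[1]) else 1
  )
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) return(stats::setNames(rep(0, length(glcm_names)), glcm_names))
  p <- P / tot
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(i * p)
  sigma2 <- sum((i - mu)^2 * p)
  sigma <- sqrt(sigma2)
  # diagonal and cross-diagonal distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(k_diff * p_diff)
  hxy <- -sum(xlogx(p))
  pxpy <- outer(px, px)
  hxy1 <- -sum(ifelse(p > 0 & pxpy > 0, p * log2(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  hx <- -sum(xlogx(px))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  # maximal correlation coefficient: second-largest eigenvalue of Q
  nz <- which(px > 0)
  mcc <- if (length(nz) < 2) 1 else {
    psub <- p[nz, nz, drop = FALSE]
    pxs <- px[nz]
    Q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz)) for (b in seq_along(nz)) {
      Q[a, b] <- sum(psub[a, ] * psub[b, ] / (pxs[a] * pxs))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(0, min(ev[2], 1)))
  }
  corr <- if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 1
  c(
    Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlogx(p_diff)),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(ifelse(i != j, p / (i - j)^2, 0)),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(xlogx(p_sum)),
    SumSquares = sigma2
  )
}

# Shared machinery for the size/length/dependence families: a count matrix
# M[gray level, size] with weights 1/size^2 etc.
sld_features <- function(M, np, prefix) {
  nz_total <- sum(M)
  ng <- nrow(M); ns <- ncol(M)
  i <- matrix(seq_len(ng), ng, ns)
  j <- matrix(seq_len(ns), ng, ns, byrow = TRUE)
  p <- M / nz_total
  mg <- rowSums(M)
  msz <- colSums(M)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  vals <- c(
    small = sum(M / j^2) / nz_total,
    large = sum(M * j^2) / nz_total,
    gln = sum(mg^2) / nz_total,
    glnn = sum(mg^2) / nz_total^2,
    szn = sum(msz^2) / nz_total,
    sznn = sum(msz^2) / nz_total^2,
    pct = nz_total / np,
    glv = sum(p * (i - mu_i)^2),
    szv = sum(p * (j - mu_j)^2),
    ent = -sum(xlogx(p)),
    lgl = sum(M / i^2) / nz_total,
    hgl = sum(M * i^2) / nz_total,
    sl = sum(M / (i^2 * j^2)) / nz_total,
    sh = sum(M * i^2 / j^2) / nz_total,
    ll = sum(M * j^2 / i^2) / nz_total,
    lh = sum(M * i^2 * j^2) / nz_total
  )
  vals
}

glrlm_features_one <- function(M, np) {
  v <- sld_features(M, np, "run")
  stats::setNames(
    c(v["small"], v["large"], v["gln"], v["glnn"], v["szn"], v["sznn"], v["pct"],
      v["glv"], v["szv"], v["ent"], v["lgl"], v["hgl"], v["sl"], v["sh"],
      v["ll"], v["lh"]),
    glrlm_names
  )
}

glszm_features_impl <- function(M, np) {
  v <- sld_features(M, np, "zone")
  stats::setNames(
    c(v["small"], v["large"], v["gln"], v["glnn"], v["szn"], v["sznn"], v["pct"],
      v["glv"], v["szv"], v["ent"], v["lgl"], v["hgl"], v["sl"], v["sh"],
      v["ll"], v["lh"]),
    glszm_names
  )
}

gldm_features_impl <- function(M, np) {
  v <- sld_features(M, np, "dep")
  stats::setNames(
    c(v["small"], v["large"], v["gln"], v["szn"], v["sznn"],
      v["glv"], v["szv"], v["ent"], v["lgl"], v["hgl"], v["sl"], v["sh"],
      v["ll"], v["lh"]),
    gldm_names
  )
}

ngtdm_features_impl <- function(mat) {
  n_i <- mat$n; s_i <- mat$s; nvp <- mat$nvp
  p_i <- n_i / nvp
  nz <- which(p_i > 0)
  ngp <- length(nz)
  ps <- sum(p_i * s_i)
  coarseness <- if (ps > 0) 1 / ps else 1e6
  if (ngp == 1) {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  } else {
    iz <- nz
    pz <- p_i[nz]; sz <- s_i[nz]
    dif2 <- outer(iz, iz, function(a, b) (a - b)^2)
    contrast <- (sum(outer(pz, pz) * dif2) / (ngp * (ngp - 1))) * (sum(s_i) / nvp)
    denom_b <- sum(abs(outer(iz * pz, iz * pz, "-"))) # all ordered pairs
    busyness <- if (denom_b > 0) ps / denom_b else 0
    num_c <- outer(pz * sz, pz * sz, "+")
    pp <- outer(pz, pz, "+")
    complexity <- sum(abs(outer(iz, iz, "-")) * num_c / pp) / nvp
    strength <- if (sum(s_i) > 0) sum(pp * dif2) / sum(s_i) else 0
  }
  stats::setNames(c(coarseness, contrast, busyness, complexity, strength), ngtdm_names)
}

#' Texture feature values for one family
#'
#' Directional families (GLCM, GLRLM) average feature values over the four
#' in-plane directions; the others are computed from their single count
#' structure. `np` (the in-mask pixel count) is required by the
#' run/zone/dependence-percentage features.
#'
#' @param kind family name.
#' @param mat the matching [texture_matrix()] output.
#' @param np number of in-mask pixels.
#' @return named numeric vector with the family's catalog cardinality
#'   (glcm 24, glszm 16, glrlm 16, ngtdm 5, gldm 14).
#' @export
texture_features <- function(kind, mat, np) {
  out <- switch(kind,
    glcm = {
      per_dir <- lapply(mat, glcm_features_one)
      Reduce(`+`, per_dir) / length(per_dir)
    },
    glrlm = {
      per_dir <- lapply(mat, function(m) glrlm_features_one(m, np))
      Reduce(`+`, per_dir) / length(per_dir)
    },
    glszm = glszm_features_impl(mat, np),
    ngtdm = ngtdm_features_impl(mat),
    gldm = gldm_features_impl(mat, np),
    abort(sprintf("unknown texture family '%s'", kind))
  )
  expected <- texture_family_names[[kind]]
  if (!identical(names(out), expected)) {
    abort(sprintf("internal consistency error: %s features do not match the catalog", kind))
  }
  out
}
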