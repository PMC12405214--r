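# Independent brute-force oracles for the texture count structures, written
# as naive pixel loops so they share no code with the package implementation.

oracle_offsets <- list(deg0 = c(0L, 1L), deg45 = c(-1L, 1L),
                       deg90 = c(1L, 0L), deg135 = c(1L, 1L))

in_bounds <- function(lev, r, c) {
  r >= 1 && r <= nrow(lev) && c >= 1 && c <= ncol(lev)
}

oracle_glcm <- function(lev, ng, off) {
  m <- matrix(0, ng, ng)
  for (r in seq_len(nrow(lev))) for (c in seq_len(ncol(lev))) {
    a <- lev[r, c]
    if (is.na(a)) next
    r2 <- r + off[1]; c2 <- c + off[2]
    if (!in_bounds(lev, r2, c2)) next
    b <- lev[r2, c2]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

oracle_glrlm <- function(lev, ng, off) {
  runs <- list()
  for (r in seq_len(nrow(lev))) for (c in seq_len(ncol(lev))) {
    g <- lev[r, c]
    if (is.na(g)) next
    # start of a maximal run: predecessor missing or different
    pr <- r - off[1]; pc <- c - off[2]
    if (in_bounds(lev, pr, pc) && !is.na(lev[pr, pc]) && lev[pr, pc] == g) next
    len <- 1L
    nr <- r + off[1]; nc <- c + off[2]
    while (in_bounds(lev, nr, nc) && !is.na(lev[nr, nc]) && lev[nr, nc] == g) {
      len <- len + 1L
      nr <- nr + off[1]; nc <- nc + off[2]
    }
    runs[[length(runs) + 1L]] <- c(g, len)
  }
  max_len <- max(c(1L, vapply(runs, `[`, 0, 2)))
  m <- matrix(0, ng, max_len)
  for (rn in runs) m[rn[1], rn[2]] <- m[rn[1], rn[2]] + 1
  m
}

# zone sizes via iterative region growing over explicit coordinate sets
oracle_glszm <- function(lev, ng) {
  remaining <- which(!is.na(lev), arr.ind = TRUE)
  remaining <- remaining[order(remaining[, 1], remaining[, 2]), , drop = FALSE]
  taken <- rep(FALSE, nrow(remaining))
  key <- paste(remaining[, 1], remaining[, 2])
  sizes <- list()
  for (s in seq_len(nrow(remaining))) {
    if (taken[s]) next
    g <- lev[remaining[s, 1], remaining[s, 2]]
    zone <- s
    taken[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nxt <- c()
      for (fidx in frontier) {
        fr <- remaining[fidx, 1]; fc <- remaining[fidx, 2]
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          j <- match(paste(fr + dr, fc + dc), key)
          if (!is.na(j) && !taken[j] &&
              lev[remaining[j, 1], remaining[j, 2]] == g) {
            taken[j] <- TRUE
            zone <- c(zone, j)
            nxt <- c(nxt, j)
          }
        }
      }
      frontier <- nxt
    }
    sizes[[length(sizes) + 1L]] <- c(g, length(zone))
  }
  max_size <- max(vapply(sizes, `[`, 0, 2))
  m <- matrix(0, ng, max_size)
  for (z in sizes) m[z[1], z[2]] <- m[z[1], z[2]] + 1
  m
}

oracle_ngtdm <- function(lev, ng) {
  n_i <- numeric(ng); s_i <- numeric(ng); nvp <- 0L
  for (r in seq_len(nrow(lev))) for (c in seq_len(ncol(lev))) {
    g <- lev[r, c]
    if (is.na(g)) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (in_bounds(lev, r + dr, c + dc) && !is.na(lev[r + dr, c + dc])) {
        nb <- c(nb, lev[r + dr, c + dc])
      }
    }
    if (length(nb) == 0) next
    nvp <- nvp + 1L
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  list(n = n_i, s = s_i, nvp = nvp)
}

oracle_gldm <- function(lev, ng, alpha = 0) {
  entries <- list()
  for (r in seq_len(nrow(lev))) for (c in seq_len(ncol(lev))) {
    g <- lev[r, c]
    if (is.na(g)) next
    dep <- 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (in_bounds(lev, r + dr, c + dc) && !is.na(lev[r + dr, c + dc]) &&
          abs(lev[r + dr, c + dc] - g) <= alpha) {
        dep <- dep + 1L
      }
    }
    entries[[length(entries) + 1L]] <- c(g, dep)
  }
  max_d <- max(vapply(entries, `[`, 0, 2))
  m <- matrix(0, ng, max_d)
  for (e in entries) m[e[1], e[2]] <- m[e[1], e[2]] + 1
  m
}

# random small quantized ROI (levels matrix with NA outside a random mask)
random_quantized_roi <- function(side_max = 6L, ng = 4L) {
  h <- sample(2:side_max, 1)
  w <- sample(2:side_max, 1)
  lev <- matrix(sample.int(ng, h * w, replace = TRUE), h, w)
  mask <- matrix(stats::runif(h * w) < 0.8, h, w)
  if (!any(mask)) mask[sample.int(h * w, 1)] <- TRUE
  lev[!mask] <- NA_integer_
  structure(list(levels = lev, n_bins = as.integer(ng),
                 bin_edges = seq(0, 1, length.out = ng + 1)),
            class = "quantized_roi")
}

# shared suite: compare package texture matrices against the oracles on
# `n_trials` random small ROIs; returns invisibly, failing via expect_*
check_texture_matrices_against_oracles <- function(n_trials = 100, seed = 42) {
  withr::with_seed(seed, {
    for (trial in seq_len(n_trials)) {
      q <- random_quantized_roi()
      ng <- q$n_bins
      glcm <- texture_matrix("glcm", q)
      glrlm <- texture_matrix("glrlm", q)
      for (d in names(oracle_offsets)) {
        expect_equal(glcm[[d]], oracle_glcm(q$levels, ng, oracle_offsets[[d]]),
                     ignore_attr = TRUE)
        expect_equal(glrlm[[d]], oracle_glrlm(q$levels, ng, oracle_offsets[[d]]),
                     ignore_attr = TRUE)
      }
      expect_equal(texture_matrix("glszm", q), oracle_glszm(q$levels, ng),
                   ignore_attr = TRUE)
      ng_pkg <- texture_matrix("ngtdm", q)
      ng_or <- oracle_ngtdm(q$levels, ng)
      expect_equal(ng_pkg$n, ng_or$n, ignore_attr = TRUE)
      expect_equal(ng_pkg$s, ng_or$s, tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(ng_pkg$nvp, ng_or$nvp, ignore_attr = TRUE)
      expect_equal(texture_matrix("gldm", q), oracle_gldm(q$levels, ng),
                   ignore_attr = TRUE)
    }
  })
  invisible(TRUE)
}

# small deterministic cohort for pipeline tests
tiny_cohort <- function(n_per_class = 4, seed = 7, contrast = 0.3) {
  generate_cohort(phantom_params(n_per_class = n_per_class, seed = seed,
                                 class_contrast = contrast, noise_sd = 0.05))
}
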