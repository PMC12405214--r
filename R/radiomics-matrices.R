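# Gray-level discretization and the five texture count structures
# (GLCM, GLSZM, GLRLM, NGTDM, GLDM), computed over in-mask pixels only.
# Conventions: gray levels 1..n_bins; pixel distance 1; 2D in-plane
# directions 0/45/90/135 degrees for the directional families; 8-connected
# neighbourhoods for GLSZM zones, NGTDM and GLDM; GLDM similarity alpha = 0.

#' Discretize in-mask intensities into equal-width gray levels
#'
#' Bins span the in-mask `[min, max]` range; a constant ROI maps entirely to
#' level 1. Pixels outside the mask are `NA` in the returned level matrix.
#'
#' @param image numeric matrix.
#' @param mask 0/1 matrix, same shape, non-empty.
#' @param n_bins number of gray levels (>= 2).
#' @return an object of class `quantized_roi`: list with `levels` (integer
#'   matrix, `NA` outside the mask), `n_bins`, and `bin_edges`.
#' @export
discretize <- function(image, mask, n_bins = 32L) {
  assert_same_shape(image, mask, "image and mask")
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  inmask <- mask != 0
  if (!any(inmask)) abort("`mask` has no foreground pixels.")
  vals <- image[inmask]
  mn <- min(vals); mx <- max(vals)
  lev <- matrix(NA_integer_, nrow(image), ncol(image))
  if (mx > mn) {
    w <- (mx - mn) / n_bins
    lev[inmask] <- pmin(as.integer(floor((vals - mn) / w)) + 1L, as.integer(n_bins))
    edges <- mn + w * (0:n_bins)
  } else {
    lev[inmask] <- 1L
    edges <- c(mn, mx)
  }
  structure(list(levels = lev, n_bins = as.integer(n_bins), bin_edges = edges),
            class = "quantized_roi")
}

# The four in-plane direction offsets (delta_row, delta_col).
texture_offsets <- function() {
  list(deg0 = c(0L, 1L), deg45 = c(-1L, 1L), deg90 = c(1L, 0L), deg135 = c(1L, 1L))
}

# Shift a matrix by (dr, dc), filling with NA.
shift_na <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_integer_, h, w)
  rs <- seq_len(h) + dr
  cs <- seq_len(w) + dc
  ok_r <- rs >= 1 & rs <= h
  ok_c <- cs >= 1 & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# 8-neighbourhood offsets.
neigh8 <- function() {
  expand.grid(dr = -1:1, dc = -1:1) |> subset(dr != 0 | dc != 0)
}

glcm_one_direction <- function(lev, ng, off) {
  nb <- shift_na(lev, off[1], off[2])
  ok <- !is.na(lev) & !is.na(nb)
  m <- matrix(0, ng, ng)
  if (any(ok)) {
    tab <- table(factor(lev[ok], levels = seq_len(ng)),
                 factor(nb[ok], levels = seq_len(ng)))
    m <- matrix(as.numeric(tab), ng, ng)
    m <- m + t(m) # symmetrize
  }
  m
}

glrlm_one_direction <- function(lev, ng, off) {
  h <- nrow(lev); w <- ncol(lev)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  key <- switch(paste(off, collapse = ","),
    "0,1" = rows,                 # horizontal lines
    "1,0" = cols,                 # vertical lines
    "1,1" = cols - rows,          # main diagonals
    "-1,1" = cols + rows          # anti-diagonals
  )
  ord <- order(as.vector(key), as.vector(rows), as.vector(cols))
  v <- as.vector(lev)[ord]
  k <- as.vector(key)[ord]
  # runs break at line boundaries (key changes) and at out-of-mask pixels
  r <- rle(paste(k, ifelse(is.na(v), "NA", v)))
  lab <- sub("^[^ ]+ ", "", r$values)
  keep <- lab != "NA"
  g <- as.integer(lab[keep])
  len <- r$lengths[keep]
  max_len <- max(c(len, 1L))
  m <- matrix(0, ng, max_len)
  if (length(g)) {
    for (i in seq_along(g)) m[g[i], len[i]] <- m[g[i], len[i]] + 1
  }
  m
}

# 8-connected components of a logical matrix; returns integer labels (0 = bg).
label_components8 <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  lab <- matrix(0L, h, w)
  cur <- 0L
  idx <- which(bw)
  offs <- neigh8()
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      r0 <- ((p - 1L) %% h) + 1L
      c0 <- ((p - 1L) %/% h) + 1L
      rr <- r0 + offs$dr
      cc <- c0 + offs$dc
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      np <- (cc[ok] - 1L) * h + rr[ok]
      np <- np[bw[np] & lab[np] == 0L]
      if (length(np)) {
        lab[np] <- cur
        queue <- c(queue, np)
      }
    }
  }
  lab
}

glszm_matrix_impl <- function(lev, ng) {
  sizes_by_level <- lapply(seq_len(ng), function(g) {
    bw <- !is.na(lev) & lev == g
    if (!any(bw)) return(integer(0))
    lab <- label_components8(bw)
    as.integer(tabulate(lab[lab > 0L]))
  })
  max_size <- max(c(1L, unlist(sizes_by_level)))
  m <- matrix(0, ng, max_size)
  for (g in seq_len(ng)) {
    s <- sizes_by_level[[g]]
    if (length(s)) {
      t <- tabulate(s, nbins = max_size)
      m[g, ] <- m[g, ] + t
    }
  }
  m
}

# Stack of the 8 shifted neighbour matrices (NA where the neighbour is
# outside the image or outside the mask).
neighbour_stack <- function(lev) {
  offs <- neigh8()
  arr <- array(NA_integer_, c(nrow(lev), ncol(lev), nrow(offs)))
  for (i in seq_len(nrow(offs))) {
    arr[, , i] <- shift_na(lev, offs$dr[i], offs$dc[i])
  }
  arr
}

ngtdm_matrix_impl <- function(lev, ng) {
  nbm <- matrix(neighbour_stack(lev), ncol = 8L)
  nb_n <- rowSums(!is.na(nbm))
  nb_sum <- rowSums(nbm, na.rm = TRUE)
  valid <- !is.na(as.vector(lev)) & nb_n > 0
  abar <- nb_sum[valid] / nb_n[valid]
  g <- as.vector(lev)[valid]
  n_i <- tabulate(g, nbins = ng)
  s_i <- numeric(ng)
  agg <- rowsum(abs(g - abar), group = g)
  s_i[as.integer(rownames(agg))] <- agg[, 1]
  list(n = as.numeric(n_i), s = s_i, nvp = sum(valid))
}

gldm_matrix_impl <- function(lev, ng, alpha = 0) {
  nbm <- matrix(neighbour_stack(lev), ncol = 8L)
  ctr <- as.vector(lev)
  dep_nb <- rowSums(!is.na(nbm) & abs(nbm - ctr) <= alpha, na.rm = TRUE)
  valid <- !is.na(ctr)
  d <- dep_nb[valid] + 1L # dependence size includes the centre pixel
  g <- ctr[valid]
  max_d <- max(d)
  m <- matrix(0, ng, max_d)
  for (i in seq_along(g)) m[g[i], d[i]] <- m[g[i], d[i]] + 1
  m
}

crop_to_mask_bbox <- function(lev) {
  idx <- which(!is.na(lev), arr.ind = TRUE)
  lev[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
}

#' Texture count structure for one family
#'
#' Computes the standard count structure restricted to in-mask pixels:
#' * `glcm`: list of symmetric co-occurrence matrices at distance 1, one per
#'   direction (0/45/90/135 degrees);
#' * `glrlm`: list of run-length count matrices (gray level x run length),
#'   one per direction; out-of-mask pixels break runs;
#' * `glszm`: zone-size counts (gray level x zone size, 8-connected zones);
#' * `ngtdm`: list with per-level pixel counts `n`, summed absolute
#'   neighbourhood differences `s`, and the number of valid pixels `nvp`;
#' * `gldm`: dependence counts (gray level x dependence size) at distance 1
#'   with similarity threshold alpha = 0; the dependence size counts the
#'   centre pixel plus its equal-level in-mask 8-neighbours.
#'
#' @param kind one of `"glcm"`, `"glszm"`, `"glrlm"`, `"ngtdm"`, `"gldm"`.
#' @param q a [discretize()] result.
#' @return the family's count structure (see details).
#' @export
texture_matrix <- function(kind, q) {
  if (!inherits(q, "quantized_roi")) abort("`q` must come from `discretize()`.")
  kind <- as.character(kind)
  if (!kind %in% c("glcm", "glszm", "glrlm", "ngtdm", "gldm")) {
    abort(sprintf("unknown texture family '%s'", kind))
  }
  lev <- crop_to_mask_bbox(q$levels)
  ng <- q$n_bins
  switch(kind,
    glcm = lapply(texture_offsets(), function(off) glcm_one_direction(lev, ng, off)),
    glrlm = lapply(texture_offsets(), function(off) glrlm_one_direction(lev, ng, off)),
    glszm = glszm_matrix_impl(lev, ng),
    ngtdm = ngtdm_matrix_impl(lev, ng),
    gldm = gldm_matrix_impl(lev, ng)
  )
}
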