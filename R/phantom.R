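# Synthetic phantom cohort: a two-class set of 2D "T2-like" slices with
# bilateral elliptical ROIs whose first-order and texture statistics differ
# by class, so the downstream radiomics + fusion pipeline has signal to find.

#' Parameters of the synthetic phantom cohort
#'
#' The phantom emulates the structure of a two-region CSF study: a balanced
#' cohort of infected and control patients, each contributing a left and a
#' right ROI in two anatomical regions (ventricular system and sub-lentiform
#' nucleus parenchyma) on a 2D slice. Class differences are expressed as a
#' mean-intensity offset (`class_contrast`) and a change in the correlation
#' length of the within-ROI noise field (`class_texture_scale`), i.e. exactly
#' the kind of signal that first-order and texture radiomics capture.
#'
#' @param n_per_class number of patients per class (>= 1). Default 52, the
#'   cohort size of a balanced 104-patient study.
#' @param image_size side of the square slice in pixels.
#' @param roi_radius_range length-2 numeric, min/max semi-axis of the
#'   elliptical ROIs in pixels.
#' @param class_contrast mean-intensity offset added inside infected ROIs,
#'   on the `[0, 1]` intensity scale.
#' @param class_texture_scale correlation length (Gaussian smoothing sigma,
#'   pixels) of the within-ROI noise field for infected patients; controls
#'   use a correlation length of 1 pixel.
#' @param noise_sd marginal standard deviation of the within-ROI noise field.
#' @param seed master seed; expanded into one substream per patient, so a
#'   cohort can be extended without perturbing existing patients.
#' @return an object of class `phantom_params`.
#' @export
#' @examples
#' p <- phantom_params(n_per_class = 2, seed = 1)
#' cohort <- generate_cohort(p)
phantom_params <- function(n_per_class = 52,
                           image_size = 128,
                           roi_radius_range = c(10, 16),
                           class_contrast = 0.15,
                           class_texture_scale = 2.5,
                           noise_sd = 0.05,
                           seed = 1L) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    abort("`n_per_class` must be a positive integer.")
  }
  if (length(roi_radius_range) != 2 || any(roi_radius_range <= 0) ||
      roi_radius_range[1] > roi_radius_range[2]) {
    abort("`roi_radius_range` must be an increasing pair of positive radii.")
  }
  # ROI centres sit at ~0.30/0.70 of the image width; the largest semi-axis
  # plus centre jitter must stay inside the slice.
  if (roi_radius_range[2] + 4 > 0.28 * image_size) {
    abort("`roi_radius_range` exceeds the image bounds for this `image_size`.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (class_texture_scale <= 0) abort("`class_texture_scale` must be positive.")
  structure(
    list(
      n_per_class = as.integer(n_per_class),
      image_size = as.integer(image_size),
      roi_radius_range = as.numeric(roi_radius_range),
      class_contrast = as.numeric(class_contrast),
      class_texture_scale = as.numeric(class_texture_scale),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed)
    ),
    class = "phantom_params"
  )
}

phantom_regions <- c("ventricle", "sublentiform")
phantom_hemispheres <- c("left", "right")
phantom_labels <- c("infection", "control")

# Correlated Gaussian field with (approximately) unit marginal sd:
# white noise smoothed at `corr_len`, renormalised by the theoretical
# variance shrinkage of the smoothing kernel.
correlated_field <- function(n, corr_len) {
  z <- matrix(stats::rnorm(n * n), n, n)
  if (corr_len <= 0.1) return(z)
  s <- gauss_blur(z, corr_len)
  k <- gaussian_kernel_1d(corr_len)
  shrink <- sum(k^2) # per-axis variance factor; separable => squared overall
  s / shrink
}

ellipse_mask <- function(n, cx, cy, a, b, theta) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE) # column index
  ys <- matrix(seq_len(n), n, n)               # row index
  dx <- xs - cx
  dy <- ys - cy
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

generate_patient <- function(params, idx, label) {
  n <- params$image_size
  rr <- params$roi_radius_range
  corr_len <- if (label == "infection") params$class_texture_scale else 1.0
  contrast <- if (label == "infection") params$class_contrast else 0
  with_local_seed(params$seed + idx, {
    # parenchyma-like darker background with mild smooth structure
    bg <- 0.35 + 0.03 * correlated_field(n, 3)
    rows <- vector("list", 4L)
    i <- 1L
    for (region in phantom_regions) {
      cy0 <- if (region == "ventricle") 0.40 * n else 0.62 * n
      for (hemi in phantom_hemispheres) {
        cx0 <- if (hemi == "left") 0.30 * n else 0.70 * n
        cx <- cx0 + stats::runif(1, -3, 3)
        cy <- cy0 + stats::runif(1, -3, 3)
        a <- stats::runif(1, rr[1], rr[2])
        b <- stats::runif(1, rr[1], rr[2])
        theta <- stats::runif(1, 0, pi)
        mask <- ellipse_mask(n, cx, cy, a, b, theta)
        img <- bg
        roi_noise <- params$noise_sd * correlated_field(n, corr_len)
        img[mask] <- 0.55 + contrast + roi_noise[mask]
        img <- pmin(pmax(img, 0), 1)
        rows[[i]] <- tibble(
          patient_id = sprintf("P%03d", idx),
          label = label,
          region = region,
          hemisphere = hemi,
          image = list(img),
          mask = list(mask * 1)
        )
        i <- i + 1L
      }
    }
    bind_rows(rows)
  })
}

#' Generate a synthetic phantom cohort
#'
#' Produces `2 * n_per_class` patients, each with 2 regions x 2 hemispheres =
#' 4 ROI samples. Infected ROIs have their mean intensity shifted by
#' `class_contrast` and their noise correlation length set by
#' `class_texture_scale`; controls come from the baseline process. The same
#' `phantom_params` (including seed) always reproduce a bit-identical cohort.
#'
#' @param params a [phantom_params()] object.
#' @return a `roi_cohort` tibble with columns `patient_id`, `label`
#'   (`"infection"`/`"control"`), `region` (`"ventricle"`/`"sublentiform"`),
#'   `hemisphere` (`"left"`/`"right"`), and list-columns `image` (numeric
#'   matrix in `[0, 1]`) and `mask` (0/1 matrix of the same shape).
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "phantom_params")) {
    abort("`params` must be created with `phantom_params()`.")
  }
  n <- params$n_per_class
  labels <- rep(phantom_labels, each = n)
  cohort <- bind_rows(lapply(seq_len(2L * n), function(i) {
    generate_patient(params, i, labels[i])
  }))
  new_roi_cohort(cohort)
}

new_roi_cohort <- function(x) {
  class(x) <- c("roi_cohort", class(tibble()))
  x
}

validate_roi_cohort <- function(cohort) {
  need <- c("patient_id", "label", "region", "hemisphere", "image", "mask")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("cohort is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  ok <- purrr::map2_lgl(cohort$image, cohort$mask, function(im, mk) {
    identical(dim(im), dim(mk)) && sum(mk) >= 1
  })
  if (!all(ok)) abort("every mask must match its image shape and be non-empty.")
  invisible(cohort)
}

#' @export
print.roi_cohort <- function(x, ...) {
  if ("patient_id" %in% names(x)) {
    cat(sprintf("<roi_cohort> %d ROI samples, %d patients\n",
                nrow(x), dplyr::n_distinct(x$patient_id)))
  }
  NextMethod()
}

#' Persist a cohort as NIfTI images plus a CSV manifest
#'
#' Images and masks are written as uncompressed-precision (float64) NIfTI
#' files so that a write/read round trip is lossless; the manifest lists one
#' row per ROI sample with relative paths.
#'
#' @param cohort a `roi_cohort` tibble.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  validate_roi_cohort(cohort)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'", dir))
  stem <- sprintf("%s_%s_%s", cohort$patient_id, cohort$region, cohort$hemisphere)
  img_rel <- file.path("images", paste0(stem, ".nii.gz"))
  msk_rel <- file.path("masks", paste0(stem, "_mask.nii.gz"))
  for (i in seq_len(nrow(cohort))) {
    RNifti::writeNifti(cohort$image[[i]], file.path(dir, img_rel[i]), datatype = "double")
    RNifti::writeNifti(cohort$mask[[i]], file.path(dir, msk_rel[i]), datatype = "uint8")
  }
  manifest <- tibble(
    patient_id = cohort$patient_id,
    label = cohort$label,
    region = cohort$region,
    hemisphere = cohort$hemisphere,
    image = img_rel,
    mask = msk_rel
  )
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  invisible(path)
}

#' Load a cohort from a manifest CSV
#'
#' @param manifest path to a manifest CSV with columns `patient_id`, `label`,
#'   `region`, `hemisphere`, `image`, `mask` (paths relative to the manifest).
#' @return a `roi_cohort` tibble.
#' @export
read_cohort <- function(manifest) {
  if (!file.exists(manifest)) abort(sprintf("manifest '%s' does not exist", manifest))
  tab <- readr::read_csv(manifest, show_col_types = FALSE)
  base <- dirname(manifest)
  need <- c("patient_id", "label", "region", "hemisphere", "image", "mask")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(paste0("manifest is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  paths <- c(file.path(base, tab$image), file.path(base, tab$mask))
  bad <- paths[!file.exists(paths)]
  if (length(bad)) {
    abort(paste0("manifest refers to missing files: ", paste(utils::head(bad, 3), collapse = ", ")))
  }
  read_img <- function(p) {
    arr <- as.array(RNifti::readNifti(p))
    matrix(as.numeric(arr), nrow = dim(arr)[1])
  }
  cohort <- tab |>
    mutate(
      image = purrr::map(file.path(base, .data$image), read_img),
      mask = purrr::map(file.path(base, .data$mask), read_img)
    )
  validate_roi_cohort(cohort)
  new_roi_cohort(cohort)
}
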