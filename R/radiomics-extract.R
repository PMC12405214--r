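# Full 378-feature extraction for one ROI and for whole cohorts.

texture_families <- c("glcm", "glszm", "glrlm", "ngtdm", "gldm")

extract_source_features <- function(image, mask, source, n_bins) {
  kind <- if (source == "original") "original" else "log"
  fo <- firstorder_features(image, mask, kind, n_bins)
  out <- stats::setNames(fo, paste(source, "firstorder", names(fo), sep = "_"))
  if (source == "original") {
    sh <- shape2d_features(mask)
    out <- c(out, stats::setNames(sh, paste(source, "shape2d", names(sh), sep = "_")))
  }
  q <- discretize(image, mask, n_bins)
  np <- sum(mask != 0)
  for (fam in texture_families) {
    fv <- tryCatch(
      texture_features(fam, texture_matrix(fam, q), np),
      error = function(e) {
        abort(sprintf("feature extraction failed for source '%s', family '%s': %s",
                      source, fam, conditionMessage(e)))
      }
    )
    out <- c(out, stats::setNames(fv, paste(source, fam, names(fv), sep = "_")))
  }
  out
}

#' Extract the full 378-feature vector from one ROI
#'
#' Applies the three LoG scales to the image and concatenates, in catalog
#' order, the features of the original image (first-order, 2D shape, five
#' texture families) and of each filtered image (first-order without Total
#' Energy, five texture families). Deterministic: the same inputs always
#' yield the same vector.
#'
#' @param image numeric matrix.
#' @param mask 0/1 matrix, same shape, non-empty.
#' @param scales a [log_scales()] tibble.
#' @param n_bins gray levels for discretization.
#' @return named numeric vector of length 378, ordered as [feature_catalog()].
#' @export
extract_roi_features <- function(image, mask, scales = log_scales(), n_bins = 32L) {
  validate_sample(image, mask)
  sources <- list(original = image)
  for (i in seq_len(nrow(scales))) {
    sources[[paste0("log_", scales$name[i])]] <- log_filter(image, scales[i, ])
  }
  out <- unlist(lapply(names(sources), function(src) {
    extract_source_features(sources[[src]], mask, src, n_bins)
  }))
  expected <- feature_catalog()$name
  if (!identical(names(out), expected)) {
    abort("internal consistency error: extracted names do not match the catalog.")
  }
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    abort(paste0("non-finite feature values: ", paste(utils::head(bad, 5), collapse = ", ")))
  }
  out
}

validate_sample <- function(image, mask) {
  assert_same_shape(image, mask, "image and mask")
  if (!all(is.finite(image))) abort("`image` must be finite.")
  if (sum(mask != 0) < 1) abort("`mask` has no foreground pixels.")
  invisible(TRUE)
}

#' Extract features for every ROI sample of a cohort
#'
#' @param cohort a `roi_cohort` tibble (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param scales a [log_scales()] tibble.
#' @param n_bins gray levels for discretization.
#' @return a tibble with the identifier columns (`patient_id`, `label`,
#'   `region`, `hemisphere`) followed by 378 named feature columns.
#' @export
extract_features <- function(cohort, scales = log_scales(), n_bins = 32L) {
  validate_roi_cohort(cohort)
  feats <- purrr::map2(cohort$image, cohort$mask, function(im, mk) {
    extract_roi_features(im, mk, scales, n_bins)
  })
  mat <- do.call(rbind, feats)
  bind_cols(
    cohort |> select("patient_id", "label", "region", "hemisphere"),
    as_tibble(mat)
  )
}

#' Split a feature table into identifiers and the feature matrix
#' @keywords internal
#' @noRd
feature_matrix <- function(feature_tbl) {
  id_cols <- intersect(c("patient_id", "label", "region", "hemisphere"), names(feature_tbl))
  as.matrix(feature_tbl[, setdiff(names(feature_tbl), id_cols), drop = FALSE])
}
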