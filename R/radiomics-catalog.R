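# Feature catalog: 378 features = 102 from the original image
# (18 first-order + 9 shape + 75 texture) and 92 from each of the three
# LoG-filtered images (17 first-order + 75 texture; Total Energy is defined
# for the original intensities only).

firstorder_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
  "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
)

shape2d_names <- c(
  "MeshSurface", "PixelSurface", "Perimeter", "PerimeterSurfaceRatio",
  "Sphericity", "MaximumDiameter", "MajorAxisLength", "MinorAxisLength",
  "Elongation"
)

glcm_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
)

glszm_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"
)

glrlm_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"
)

ngtdm_names <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

gldm_names <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis"
)

texture_family_names <- list(
  glcm = glcm_names, glszm = glszm_names, glrlm = glrlm_names,
  ngtdm = ngtdm_names, gldm = gldm_names
)

feature_sources <- c("original", "log_fine", "log_medium", "log_coarse")

#' The 378-feature radiomics catalog
#'
#' One row per feature, in extraction order: for each image source (original,
#' then the fine/medium/coarse LoG responses) the first-order features, then
#' (original only) the 2D shape features, then the five texture families.
#' Per-source counts are enforced at construction: the original image yields
#' 102 features (first-order 18, shape 9, GLCM 24, GLSZM 16, GLRLM 16,
#' NGTDM 5, GLDM 14) and each LoG image 92 (first-order 17, same texture
#' families), for a total of 378.
#'
#' @return a tibble with columns `name` (unique, `source_family_feature`),
#'   `source`, `family`, and `feature`.
#' @export
feature_catalog <- function() {
  one_source <- function(source) {
    fo <- if (source == "original") firstorder_names else setdiff(firstorder_names, "TotalEnergy")
    rows <- list(tibble(source = source, family = "firstorder", feature = fo))
    if (source == "original") {
      rows <- c(rows, list(tibble(source = source, family = "shape2d", feature = shape2d_names)))
    }
    for (fam in names(texture_family_names)) {
      rows <- c(rows, list(tibble(source = source, family = fam,
                                  feature = texture_family_names[[fam]])))
    }
    bind_rows(rows)
  }
  cat_tbl <- bind_rows(lapply(feature_sources, one_source)) |>
    mutate(name = paste(.data$source, .data$family, .data$feature, sep = "_")) |>
    select("name", "source", "family", "feature")
  counts <- cat_tbl |> count(.data$source)
  n_orig <- counts$n[counts$source == "original"]
  n_log <- counts$n[counts$source != "original"]
  stopifnot(n_orig == 102L, all(n_log == 92L), nrow(cat_tbl) == 378L)
  cat_tbl
}
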