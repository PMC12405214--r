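# Filter-based feature selection: univariate ANOVA F ranking on the outer
# fold's training+validation samples, top-k retention, and cross-fold
# selection-frequency reporting. Test-fold samples must never reach the
# ranking; callers thread the test patient ids through `forbidden_ids` and
# the functions refuse leaking inputs.

#' Univariate ANOVA F scores for every feature
#'
#' One-way ANOVA F statistic (between-class over within-class mean square)
#' per feature column, for a binary class label. Constant features score 0;
#' perfect separators (zero within-class variance with distinct class means)
#' receive a large finite sentinel (`1e12`) so the ordering stays total.
#'
#' @param feature_tbl tibble/data frame: identifier columns (`patient_id`,
#'   `label`, `region`, `hemisphere`, any of which may be absent) plus
#'   numeric feature columns.
#' @param labels optional class vector (defaults to `feature_tbl$label`).
#' @param forbidden_ids patient ids that must not appear in `feature_tbl`
#'   (the outer test fold); any overlap raises a leakage error.
#' @return named numeric vector of F scores, one per feature column.
#' @export
rank_features <- function(feature_tbl, labels = NULL, forbidden_ids = NULL) {
  if (is.null(labels)) {
    if (!"label" %in% names(feature_tbl)) abort("`labels` not given and no `label` column.")
    labels <- feature_tbl$label
  }
  if (!is.null(forbidden_ids) && "patient_id" %in% names(feature_tbl)) {
    leak <- intersect(unique(feature_tbl$patient_id), forbidden_ids)
    if (length(leak)) {
      abort(paste0("leakage: test-fold patients present in ranking data: ",
                   paste(utils::head(leak, 3), collapse = ", ")))
    }
  }
  X <- feature_matrix(feature_tbl)
  cls <- as.character(labels)
  groups <- unique(cls)
  if (length(groups) < 2) abort("`labels` must contain at least two classes.")
  counts <- table(cls)
  if (any(counts < 2)) abort("need >= 2 samples per class to rank features.")
  n <- nrow(X)
  k <- length(groups)
  grand <- colMeans(X)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    Xg <- X[cls == g, , drop = FALSE]
    mg <- colMeans(Xg)
    ssb <- ssb + nrow(Xg) * (mg - grand)^2
    ssw <- ssw + colSums(sweep(Xg, 2, mg)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw,
              ifelse(msb > 0, 1e12, 0)) # perfect separator / constant feature
  stats::setNames(as.numeric(f), colnames(X))
}

#' Select the top-k features of a fold
#'
#' Keeps the `k` highest-scoring features; ties are broken by catalog
#' (column) order so selection is deterministic. Standardization statistics
#' (per-feature mean and sd) are computed from `training_tbl` — the training
#' subset only, not the validation samples used for early stopping.
#'
#' @param scores named score vector from [rank_features()].
#' @param k number of features to keep (default 50).
#' @param fold_id integer identifier carried through to the result.
#' @param training_tbl optional tibble of training-only samples from which
#'   the per-feature scaler statistics are computed.
#' @return an object of class `selection_result`: list with `fold_id`,
#'   `scores`, `selected` (ordered character vector of length `k`), and
#'   `scaler` (tibble `feature`, `mean`, `sd`).
#' @export
select_top_k <- function(scores, k = 50L, fold_id = NA_integer_, training_tbl = NULL) {
  if (k <= 0) abort("`k` must be positive.")
  if (k > length(scores)) abort("`k` exceeds the number of features.")
  ord <- order_desc_stable(scores)
  selected <- names(scores)[ord[seq_len(k)]]
  scaler <- NULL
  if (!is.null(training_tbl)) {
    X <- feature_matrix(training_tbl)[, selected, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    scaler <- tibble(
      feature = selected,
      mean = colMeans(X),
      sd = ifelse(sds > 0, sds, 1) # degenerate features pass through unscaled
    )
  }
  structure(
    list(fold_id = as.integer(fold_id), scores = scores,
         selected = selected, scaler = scaler),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> fold %s: %d features selected (top: %s)\n",
              x$fold_id, length(x$selected),
              paste(utils::head(x$selected, 3), collapse = ", ")))
  invisible(x)
}

#' Apply a fold's scaler to a feature table
#'
#' Restricts to the selected features and z-scores them with the fold's
#' training statistics.
#'
#' @param feature_tbl feature tibble (id columns + features).
#' @param selection a `selection_result` with a fitted scaler.
#' @return numeric matrix, rows = samples, columns = selected features.
#' @export
apply_selection <- function(feature_tbl, selection) {
  if (is.null(selection$scaler)) abort("selection has no fitted scaler.")
  X <- feature_matrix(feature_tbl)[, selection$selected, drop = FALSE]
  sweep(sweep(X, 2, selection$scaler$mean), 2, selection$scaler$sd, "/")
}

#' Cross-fold selection frequency table
#'
#' Counts, for every catalog feature, in how many folds it was selected;
#' sorted by decreasing frequency, ties in catalog order. Mirrors the usual
#' supplementary "feature stability" table (feature name, image source,
#' feature class, frequency).
#'
#' @param results list of `selection_result` objects.
#' @param catalog the [feature_catalog()] tibble.
#' @return tibble with columns `feature` (full name), `source`, `family`,
#'   `frequency`.
#' @export
selection_frequency <- function(results, catalog = feature_catalog()) {
  if (length(results) < 1) abort("need at least one fold.")
  for (r in results) {
    if (!all(r$selected %in% catalog$name)) {
      abort("selection results use features absent from the catalog.")
    }
  }
  counts <- table(factor(unlist(lapply(results, `[[`, "selected")),
                         levels = catalog$name))
  catalog |>
    mutate(frequency = as.integer(counts[.data$name])) |>
    arrange(desc(.data$frequency)) |>
    transmute(feature = .data$name, source = .data$source,
              family = .data$family, frequency = .data$frequency)
}
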