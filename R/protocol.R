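# Patient-grouped nested cross-validation plumbing: fold plans, augmentation,
# ROI-level metrics, fold aggregation, and the strict patient-wise rules.

#' Patient-grouped, label-stratified nested fold plan
#'
#' Partitions patients into `outer_k` outer folds, stratified by label (per
#' class, fold sizes differ by at most one; the round-robin assignment
#' continues across classes so total fold sizes are balanced too). Within
#' each outer fold's training+validation patients, an inner `inner_k`-fold
#' assignment is drawn the same way. All ROIs of a patient share its fold by
#' construction.
#'
#' @param patients tibble with columns `patient_id` and `label` (one row per
#'   patient).
#' @param outer_k,inner_k fold counts.
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return a `fold_plan`: list with `outer` (tibble `patient_id`, `label`,
#'   `outer_fold`), `inner` (tibble `outer_fold`, `patient_id`,
#'   `inner_fold`), `outer_k`, `inner_k`, `seed`.
#' @export
make_fold_plan <- function(patients, outer_k = 5L, inner_k = 3L, seed = 1L) {
  patients <- distinct(as_tibble(patients), .data$patient_id, .data$label)
  if (anyDuplicated(patients$patient_id)) abort("a patient has more than one label.")
  counts <- table(patients$label)
  if (any(counts < outer_k)) abort("need at least `outer_k` patients per class.")
  assign_rr <- function(tbl, k, start = 0L) {
    # per class: shuffle, then deal round-robin continuing a global pointer
    ptr <- start
    out <- tbl |> mutate(fold = NA_integer_)
    for (cl in sort(unique(tbl$label))) {
      idx <- which(tbl$label == cl)
      idx <- idx[sample.int(length(idx))]
      out$fold[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
      ptr <- ptr + length(idx)
    }
    out
  }
  with_local_seed(seed, {
    outer <- assign_rr(patients, outer_k) |> rename(outer_fold = "fold")
    inner <- bind_rows(lapply(seq_len(outer_k), function(f) {
      tv <- outer |> filter(.data$outer_fold != f)
      assign_rr(tv |> select("patient_id", "label"), inner_k) |>
        transmute(outer_fold = f, patient_id = .data$patient_id,
                  inner_fold = .data$fold)
    }))
    structure(list(outer = outer |> select("patient_id", "label", "outer_fold"),
                   inner = inner, outer_k = as.integer(outer_k),
                   inner_k = as.integer(inner_k), seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d patients, %d outer x %d inner folds (seed %d)\n",
              nrow(x$outer), x$outer_k, x$inner_k, x$seed))
  invisible(x)
}

#' Serialize / load a fold plan as JSON
#' @param plan a `fold_plan`.
#' @param path output file.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(list(outer = plan$outer, inner = plan$inner,
                            outer_k = plan$outer_k, inner_k = plan$inner_k,
                            seed = plan$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(outer = as_tibble(x$outer), inner = as_tibble(x$inner),
                 outer_k = as.integer(x$outer_k), inner_k = as.integer(x$inner_k),
                 seed = as.integer(x$seed)),
            class = "fold_plan")
}

# ---- augmentation ---------------------------------------------------------

#' Augmentation parameter set
#'
#' @param rotation maximum absolute rotation in degrees.
#' @param zoom maximum relative zoom (0.1 = +/-10%).
#' @param translation maximum translation as a fraction of the patch side.
#' @param flip allow horizontal/vertical flips.
#' @param prob probability with which each transform is applied.
#' @export
augment_params <- function(rotation = 15, zoom = 0.1, translation = 0.1,
                           flip = TRUE, prob = 0.5) {
  list(rotation = rotation, zoom = zoom, translation = translation,
       flip = flip, prob = prob)
}

# inverse-mapped bilinear warp with edge clamping; A maps output-centred
# coords to input-centred coords
warp_bilinear <- function(x, A, shift) {
  n <- nrow(x); m <- ncol(x)
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  ro <- matrix(seq_len(n), n, m) - cy
  co <- matrix(seq_len(m), n, m, byrow = TRUE) - cx
  ri <- A[1, 1] * ro + A[1, 2] * co + cy - shift[1]
  ci <- A[2, 1] * ro + A[2, 2] * co + cx - shift[2]
  ri <- pmin(pmax(ri, 1), n)
  ci <- pmin(pmax(ci, 1), m)
  r0 <- floor(ri); c0 <- floor(ci)
  r1 <- pmin(r0 + 1, n); c1 <- pmin(c0 + 1, m)
  fr <- ri - r0; fc <- ci - c0
  v00 <- x[cbind(as.vector(r0), as.vector(c0))]
  v01 <- x[cbind(as.vector(r0), as.vector(c1))]
  v10 <- x[cbind(as.vector(r1), as.vector(c0))]
  v11 <- x[cbind(as.vector(r1), as.vector(c1))]
  out <- (1 - fr) * (1 - fc) * v00 + (1 - fr) * fc * v01 +
    fr * (1 - fc) * v10 + fr * fc * v11
  matrix(out, n, m)
}

#' Randomly augment a 2D patch
#'
#' Applies, each with independent probability `params$prob`: rotation
#' (uniform within +/- `rotation` degrees), zoom (+/- `zoom`), translation
#' (+/- `translation` of the side), and horizontal/vertical flips. Rotation,
#' zoom and translation are composed into a single bilinear warp so the
#' patch is resampled at most once; a draw with no active transform returns
#' the input bit-identically. Output shape is preserved.
#'
#' @param patch numeric matrix.
#' @param params an [augment_params()] list.
#' @param seed optional seed for a reproducible draw.
#' @return augmented matrix of the same shape.
#' @export
augment <- function(patch, params = augment_params(), seed = NULL) {
  draw <- function() {
    list(
      rot = if (stats::runif(1) < params$prob) stats::runif(1, -params$rotation, params$rotation) else 0,
      zoom = if (stats::runif(1) < params$prob) stats::runif(1, 1 - params$zoom, 1 + params$zoom) else 1,
      tr = if (stats::runif(1) < params$prob) {
        stats::runif(2, -params$translation, params$translation) * dim(patch)
      } else c(0, 0),
      fh = params$flip && stats::runif(1) < params$prob,
      fv = params$flip && stats::runif(1) < params$prob
    )
  }
  d <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  out <- patch
  if (d$rot != 0 || d$zoom != 1 || any(d$tr != 0)) {
    th <- d$rot * pi / 180
    # inverse of (zoom * rotation): rotate back and unscale
    A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) / d$zoom
    out <- warp_bilinear(out, A, d$tr)
  }
  if (d$fh) out <- out[, ncol(out):1, drop = FALSE]
  if (d$fv) out <- out[nrow(out):1, , drop = FALSE]
  out
}

# ---- metrics --------------------------------------------------------------

#' ROI-level classification metrics for one fold
#'
#' The infection class is the positive class; the per-ROI decision is
#' `prob_infection >= 0.5` (argmax of the softmax). Accuracy, precision,
#' recall and F1 are percentages; the ROC curve and AUC come from sweeping a
#' threshold over the infection-class probability. With single-class labels
#' the ROC is undefined: the confusion-matrix metrics are still returned,
#' with `auc = NA` and a warning.
#'
#' @param prob_infection numeric vector of infection-class probabilities.
#' @param labels character/factor vector (`"infection"` / `"control"`).
#' @param fold_id identifier stored in the result.
#' @return one-row tibble: `fold_id`, `accuracy`, `precision`, `recall`,
#'   `f1`, `auc`, and a `roc` list-column (tibble `fpr`, `tpr`).
#' @export
compute_metrics <- function(prob_infection, labels, fold_id = NA_integer_) {
  if (length(prob_infection) != length(labels)) abort("prediction/label length mismatch.")
  labels <- as.character(labels)
  pred <- ifelse(prob_infection >= 0.5, "infection", "control")
  tp <- sum(pred == "infection" & labels == "infection")
  fp <- sum(pred == "infection" & labels == "control")
  fn <- sum(pred == "control" & labels == "infection")
  tn <- sum(pred == "control" & labels == "control")
  acc <- 100 * (tp + tn) / length(labels)
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  if (length(unique(labels)) < 2) {
    warn("ROC undefined for single-class labels; returning metrics with auc = NA.")
    auc <- NA_real_
    roc_tbl <- tibble(fpr = numeric(), tpr = numeric())
  } else {
    r <- pROC::roc(response = labels, predictor = prob_infection,
                   levels = c("control", "infection"), direction = "<",
                   quiet = TRUE)
    auc <- as.numeric(pROC::auc(r))
    roc_tbl <- tibble(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  }
  tibble(fold_id = fold_id, accuracy = acc, precision = prec, recall = rec,
         f1 = f1, auc = auc, roc = list(roc_tbl))
}

#' Aggregate per-fold metrics: mean +/- sd and the mean ROC curve
#'
#' Metrics are averaged across folds with the sample standard deviation. The
#' mean ROC is obtained by vertical averaging: each fold's TPR is linearly
#' interpolated on a common FPR grid (0 to 1, step 0.01, with (0,0)/(1,1)
#' anchors) and averaged pointwise with a +/- 1 sd band.
#'
#' @param metrics tibble from rows of [compute_metrics()] (>= 2 folds).
#' @return a `fold_aggregate`: list with `summary` (tibble `metric`, `mean`,
#'   `sd`), `roc` (tibble `fpr`, `tpr_mean`, `tpr_sd`), `auc_mean`, `auc_sd`.
#' @export
aggregate_folds <- function(metrics) {
  if (nrow(metrics) < 2) abort("need at least two folds to aggregate.")
  long <- metrics |>
    select("fold_id", "accuracy", "precision", "recall", "f1") |>
    tidyr::pivot_longer(-"fold_id", names_to = "metric", values_to = "value")
  summary <- long |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              .groups = "drop") |>
    arrange(match(.data$metric, c("accuracy", "precision", "recall", "f1")))
  grid <- seq(0, 1, by = 0.01)
  tprs <- vapply(metrics$roc, function(rt) {
    if (nrow(rt) == 0) return(rep(NA_real_, length(grid)))
    stats::approx(c(0, rt$fpr, 1), c(0, rt$tpr, 1), xout = grid,
                  ties = max, rule = 2)$y
  }, numeric(length(grid)))
  roc <- tibble(fpr = grid,
                tpr_mean = rowMeans(tprs),
                tpr_sd = apply(tprs, 1, stats::sd))
  structure(list(summary = summary, roc = roc,
                 auc_mean = mean(metrics$auc), auc_sd = stats::sd(metrics$auc)),
            class = "fold_aggregate")
}

#' @export
print.fold_aggregate <- function(x, ...) {
  cat("<fold_aggregate>\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %6.2f +/- %5.2f %%\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  cat(sprintf("  AUC       %6.3f +/- %5.3f\n", x$auc_mean, x$auc_sd))
  invisible(x)
}

# ---- strict patient-wise rules -------------------------------------------

validate_paired <- function(decisions) {
  need <- c("patient_id", "label", "prediction")
  if (!all(need %in% names(decisions))) {
    abort(paste0("decisions need columns: ", paste(need, collapse = ", ")))
  }
  counts <- decisions |> count(.data$patient_id)
  if (any(counts$n != 2)) {
    abort("every patient must have exactly two ROI predictions.")
  }
  invisible(decisions)
}

patient_decision_tbl <- function(decisions) {
  decisions |>
    group_by(across(any_of(c("fold_id"))), .data$patient_id, .data$label) |>
    summarise(n_infected = sum(.data$prediction == "infection"),
              discordant = n_distinct(.data$prediction) > 1,
              .groups = "drop") |>
    mutate(correct = ifelse(.data$label == "infection",
                            .data$n_infected >= 1, .data$n_infected == 0))
}

#' Strict patient-wise accuracy per class
#'
#' Clinical decision rule over a patient's two (left/right) ROI predictions:
#' an infected patient counts as correctly classified if at least one ROI is
#' predicted infected; a control patient only if both ROIs are predicted
#' non-infected. Accuracy is reported per class; when a `fold_id` column is
#' present it is computed per fold and per class (with the across-fold mean
#' +/- sd per class alongside).
#'
#' @param decisions tibble with `patient_id`, `label`, `prediction`
#'   (`"infection"`/`"control"`, one row per ROI) and optionally `fold_id`.
#' @return list with `patients` (per-patient decisions: `correct`,
#'   `discordant`), `per_class` (accuracy by fold and class, percent), and
#'   `summary` (per-class mean +/- sd across folds).
#' @export
strict_patient_accuracy <- function(decisions) {
  validate_paired(decisions)
  pats <- patient_decision_tbl(decisions)
  grouping <- intersect(c("fold_id", "label"), names(pats))
  per_class <- pats |>
    group_by(across(all_of(grouping))) |>
    summarise(accuracy = 100 * mean(.data$correct), n = dplyr::n(), .groups = "drop")
  summary <- per_class |>
    group_by(.data$label) |>
    summarise(mean = mean(.data$accuracy),
              sd = if (dplyr::n() > 1) stats::sd(.data$accuracy) else NA_real_,
              .groups = "drop")
  list(patients = pats, per_class = per_class, summary = summary)
}

#' Left/right discordance rate
#'
#' Fraction of patients whose two ROI predictions disagree; computed per
#' fold when a `fold_id` column is present, then averaged (mean +/- sd).
#'
#' @inheritParams strict_patient_accuracy
#' @return list with `per_fold` (tibble `fold_id`, `discordance` percent),
#'   `mean`, `sd`.
#' @export
discordance_rate <- function(decisions) {
  validate_paired(decisions)
  pats <- patient_decision_tbl(decisions)
  if ("fold_id" %in% names(pats)) {
    per_fold <- pats |>
      group_by(.data$fold_id) |>
      summarise(discordance = 100 * mean(.data$discordant), .groups = "drop")
  } else {
    per_fold <- tibble(fold_id = NA_integer_,
                       discordance = 100 * mean(pats$discordant))
  }
  list(per_fold = per_fold, mean = mean(per_fold$discordance),
       sd = if (nrow(per_fold) > 1) stats::sd(per_fold$discordance) else NA_real_)
}
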