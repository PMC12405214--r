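# The end-to-end protocol: for each outer fold, select features on the
# training+validation patients only, fit the scaler on training patients,
# train the classifier in two phases, and evaluate on the held-out test
# fold. Every stage asserts the patient-grouping no-leakage invariant.

#' Run nested patient-grouped cross-validation on a cohort
#'
#' For one anatomical region, extracts the 378 radiomics features of every
#' ROI, builds a stratified patient-grouped fold plan, and per outer fold:
#' ranks features on the training+validation samples only (the held-out
#' test patients never reach the ranking), keeps the top `k`, standardizes
#' them with training-only statistics, trains the requested model with the
#' two-phase schedule, and computes test-fold ROI metrics, strict
#' patient-wise decisions, and the fold's selection record.
#'
#' @param cohort a `roi_cohort` tibble.
#' @param region `"sublentiform"` or `"ventricle"`.
#' @param model_kind `"fusion"` (dual-branch) or `"base"` (image-only).
#' @param model_config a [fusion_config()]; defaults to the reduced-scale
#'   configuration, which is what a desk-scale synthetic cohort warrants.
#' @param config a [train_config()].
#' @param k number of selected radiomics features.
#' @param outer_k,inner_k fold counts.
#' @param scales LoG scales for extraction.
#' @param n_bins gray levels for extraction.
#' @param features optional precomputed feature table (from
#'   [extract_features()] on the same cohort) to skip re-extraction.
#' @return a `nested_cv` object: list with `metrics` (per-fold tibble),
#'   `aggregate` ([aggregate_folds()] result), `decisions` (per-ROI test
#'   predictions), `patient` (strict patient-wise accuracy), `discordance`,
#'   `selections` (per-fold `selection_result`s), `frequency` (selection
#'   frequency table), `history` (per-fold training history), `plan`,
#'   `region`, `model_kind`, and the configs.
#' @export
run_nested_cv <- function(cohort, region = c("sublentiform", "ventricle"),
                          model_kind = c("fusion", "base"),
                          model_config = fusion_config_tiny(radiomics_input_dim = k),
                          config = train_config_desk(),
                          k = 50L, outer_k = 5L, inner_k = 3L,
                          scales = log_scales(), n_bins = 32L,
                          features = NULL) {
  region <- match.arg(region)
  model_kind <- match.arg(model_kind)
  validate_roi_cohort(cohort)
  roi <- cohort |> filter(.data$region == !!region) |>
    arrange(.data$patient_id, .data$hemisphere)
  if (nrow(roi) == 0) abort(sprintf("cohort has no '%s' ROIs", region))
  if (is.null(features)) {
    features <- extract_features(roi, scales, n_bins)
  } else {
    features <- features |> filter(.data$region == !!region) |>
      arrange(.data$patient_id, .data$hemisphere)
    if (!identical(features$patient_id, roi$patient_id)) {
      abort("`features` does not match the cohort's ROIs.")
    }
  }
  patients <- roi |> distinct(.data$patient_id, .data$label)
  plan <- make_fold_plan(patients, outer_k, inner_k, seed = config$seed)
  patches <- purrr::map2(roi$image, roi$mask, function(im, mk) {
    prepare_patch(im, mk, crop_size = 32L, input_size = model_config$input_size)
  })
  all_images <- array(0, c(model_config$input_size, model_config$input_size, 3L, nrow(roi)))
  for (i in seq_along(patches)) all_images[, , , i] <- patches[[i]]
  y_all <- ifelse(roi$label == "infection", 1L, 2L)

  fold_rows <- list(); decision_rows <- list(); selections <- list()
  histories <- list(); prev_model <- NULL
  for (f in seq_len(outer_k)) {
    fold_res <- with_local_seed(config$seed + 7919L * f, {
      test_ids <- plan$outer$patient_id[plan$outer$outer_fold == f]
      inner_f <- plan$inner |> filter(.data$outer_fold == f)
      stopifnot(length(intersect(test_ids, inner_f$patient_id)) == 0)
      trainval_idx <- which(!roi$patient_id %in% test_ids)
      test_idx <- which(roi$patient_id %in% test_ids)
      scores <- rank_features(features[trainval_idx, ], forbidden_ids = test_ids)

      rotations <- if (config$inner_rotations) seq_len(inner_k) else 1L
      best <- NULL
      for (rot in rotations) {
        val_ids <- inner_f$patient_id[inner_f$inner_fold == rot]
        train_ids <- setdiff(inner_f$patient_id, val_ids)
        sel <- select_top_k(scores, k, fold_id = f,
                            training_tbl = features[roi$patient_id %in% train_ids, ])
        tr_idx <- which(roi$patient_id %in% train_ids)
        va_idx <- which(roi$patient_id %in% val_ids)
        rad_all <- if (model_kind == "fusion") apply_selection(features, sel) else NULL
        dat <- function(idx) model_data(
          all_images[, , , idx, drop = FALSE],
          if (is.null(rad_all)) NULL else rad_all[idx, , drop = FALSE],
          y_all[idx], roi$patient_id[idx])
        model <- if (config$weight_carryover && !is.null(prev_model)) {
          model_map_layers(prev_model, function(l, i) { l$trainable <- TRUE; l })
        } else if (model_kind == "fusion") {
          build_fusion_model(model_config, seed = config$seed + f)
        } else {
          build_base_model(model_config, seed = config$seed + f)
        }
        tr <- train_two_phase(model, dat(tr_idx), dat(va_idx), config)
        val_best <- min(tr$history$val_loss)
        if (is.null(best) || val_best < best$val_loss) {
          best <- list(model = tr$model, history = tr$history, sel = sel,
                       rad_all = rad_all, val_loss = val_best, dat = dat)
        }
      }
      test_dat <- best$dat(test_idx)
      probs <- predict(best$model, test_dat$images, test_dat$radiomics)
      prob_inf <- probs[, 1]
      met <- compute_metrics(prob_inf, roi$label[test_idx], fold_id = f)
      dec <- tibble(
        fold_id = f,
        patient_id = roi$patient_id[test_idx],
        label = roi$label[test_idx],
        hemisphere = roi$hemisphere[test_idx],
        prob_infection = prob_inf,
        prediction = ifelse(prob_inf >= 0.5, "infection", "control")
      )
      list(metrics = met, decisions = dec, selection = best$sel,
           history = best$history |> mutate(fold_id = f), model = best$model)
    })
    fold_rows[[f]] <- fold_res$metrics
    decision_rows[[f]] <- fold_res$decisions
    selections[[f]] <- fold_res$selection
    histories[[f]] <- fold_res$history
    prev_model <- fold_res$model
  }
  metrics <- bind_rows(fold_rows)
  decisions <- bind_rows(decision_rows)
  structure(
    list(metrics = metrics,
         aggregate = aggregate_folds(metrics),
         decisions = decisions,
         patient = strict_patient_accuracy(decisions),
         discordance = discordance_rate(decisions),
         selections = selections,
         frequency = selection_frequency(selections),
         history = bind_rows(histories),
         plan = plan, region = region, model_kind = model_kind,
         model_config = model_config, config = config),
    class = "nested_cv"
  )
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("<nested_cv> %s model, %s region, %d folds\n",
              x$model_kind, x$region, nrow(x$metrics)))
  print(x$aggregate)
  cat(sprintf("  discordance %.1f +/- %.1f %%\n", x$discordance$mean,
              x$discordance$sd))
  invisible(x)
}
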