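make_patients <- function(n_per_class = 52) {
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(2 * n_per_class)),
    label = rep(c("infection", "control"), each = n_per_class))
}

test_that("fold plan: balanced stratified partition, patient-grouped", {
  plan <- make_fold_plan(make_patients(52), outer_k = 5, inner_k = 3, seed = 1)
  sizes <- sort(as.integer(table(plan$outer$outer_fold)), decreasing = TRUE)
  expect_equal(sizes, c(21, 21, 21, 21, 20))
  per_class <- table(plan$outer$label, plan$outer$outer_fold)
  expect_lte(max(per_class) - min(per_class), 1)
  # partition: every patient in exactly one outer fold
  expect_equal(sort(plan$outer$patient_id), sort(make_patients(52)$patient_id))
  # inner folds partition the outer training+validation patients
  for (f in 1:5) {
    inner_f <- plan$inner[plan$inner$outer_fold == f, ]
    test_ids <- plan$outer$patient_id[plan$outer$outer_fold == f]
    expect_length(intersect(inner_f$patient_id, test_ids), 0)
    expect_setequal(inner_f$patient_id, setdiff(plan$outer$patient_id, test_ids))
  }
  # deterministic under the seed
  plan2 <- make_fold_plan(make_patients(52), 5, 3, seed = 1)
  expect_identical(plan$outer, plan2$outer)
  expect_identical(plan$inner, plan2$inner)
  expect_error(make_fold_plan(make_patients(3), 5), "at least")
})

test_that("fold plans serialize to JSON and back", {
  plan <- make_fold_plan(make_patients(10), 3, 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, path)
  back <- read_fold_plan(path)
  expect_equal(back$outer, plan$outer)
  expect_equal(back$inner, plan$inner)
})

test_that("augmentation: identity draw, flip involution, seeded determinism", {
  x <- matrix(runif(32 * 32), 32, 32)
  off <- augment_params(prob = 0) # no transform can fire
  expect_identical(augment(x, off), x)
  flips <- augment_params(rotation = 0, zoom = 0, translation = 0,
                          flip = TRUE, prob = 1)
  once <- augment(x, flips)
  expect_identical(once, x[32:1, 32:1]) # both flips applied
  expect_identical(augment(once, flips), x) # involution
  full <- augment_params(prob = 1)
  a1 <- augment(x, full, seed = 42)
  a2 <- augment(x, full, seed = 42)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(x))
  expect_false(identical(a1, x))
})

test_that("metrics match the hand-computed confusion matrix", {
  # TP = 3, FP = 1, FN = 2, TN = 4
  labels <- c(rep("infection", 5), rep("control", 5))
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.2, 0.1, 0.05)
  m <- compute_metrics(prob, labels, fold_id = 1)
  expect_equal(m$accuracy, 70)
  expect_equal(m$precision, 75)
  expect_equal(m$recall, 60)
  expect_equal(m$f1, 2 * 75 * 60 / 135, tolerance = 1e-6)
  # F1 consistency with precision/recall
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
               tolerance = 1e-6)
})

test_that("ROC extremes: perfect separation gives AUC 1, constants 0.5", {
  labels <- rep(c("infection", "control"), each = 4)
  perfect <- compute_metrics(c(rep(0.9, 4), rep(0.1, 4)), labels)
  expect_equal(perfect$auc, 1)
  flat <- compute_metrics(rep(0.5, 8), labels)
  expect_equal(flat$auc, 0.5)
  expect_warning(compute_metrics(rep(0.9, 4), rep("infection", 4)), "ROC undefined")
})

test_that("fold aggregation: mean +/- sd and vertically averaged ROC", {
  labels <- rep(c("infection", "control"), each = 5)
  m1 <- compute_metrics(c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.2, 0.1, 0.05),
                        labels, 1)
  agg_same <- aggregate_folds(dplyr::bind_rows(m1, m1 |> dplyr::mutate(fold_id = 2)))
  expect_true(all(agg_same$summary$sd == 0))
  expect_equal(agg_same$auc_sd, 0)
  # mean ROC of identical folds equals either curve on the grid
  single <- stats::approx(c(0, m1$roc[[1]]$fpr, 1), c(0, m1$roc[[1]]$tpr, 1),
                          xout = agg_same$roc$fpr, ties = max, rule = 2)$y
  expect_equal(agg_same$roc$tpr_mean, single)
  expect_true(all(agg_same$roc$tpr_sd == 0))
  # accuracies {70, 80} -> 75 +/- 7.07
  m2 <- m1 |> dplyr::mutate(fold_id = 2, accuracy = 80)
  agg <- aggregate_folds(dplyr::bind_rows(m1, m2))
  acc <- agg$summary[agg$summary$metric == "accuracy", ]
  expect_equal(acc$mean, 75)
  expect_equal(acc$sd, sd(c(70, 80)), tolerance = 1e-12)
})

test_that("strict patient rule reproduces the exhaustive truth table", {
  pairs <- expand.grid(a = c("infection", "control"),
                       b = c("infection", "control"),
                       stringsAsFactors = FALSE)
  for (lab in c("infection", "control")) {
    correct <- logical(4)
    for (i in 1:4) {
      dec <- tibble::tibble(
        patient_id = "P1", label = lab,
        hemisphere = c("left", "right"),
        prediction = c(pairs$a[i], pairs$b[i]))
      res <- strict_patient_accuracy(dec)
      correct[i] <- res$patients$correct[1]
    }
    n_inf <- (pairs$a == "infection") + (pairs$b == "infection")
    expected <- if (lab == "infection") n_inf >= 1 else n_inf == 0
    expect_equal(correct, unname(expected))
  }
  # infection correct in 3/4 pairs, control in 1/4
  dec_all <- function(lab) {
    dplyr::bind_rows(lapply(1:4, function(i) tibble::tibble(
      patient_id = paste0("P", i), label = lab,
      prediction = c(pairs$a[i], pairs$b[i]))))
  }
  expect_equal(strict_patient_accuracy(dec_all("infection"))$per_class$accuracy, 75)
  expect_equal(strict_patient_accuracy(dec_all("control"))$per_class$accuracy, 25)
  bad <- tibble::tibble(patient_id = c("P1", "P1", "P1"), label = "control",
                        prediction = "control")
  expect_error(strict_patient_accuracy(bad), "exactly two")
})

test_that("discordance counts disagreeing pairs", {
  dec <- dplyr::bind_rows(lapply(1:10, function(i) tibble::tibble(
    fold_id = 1L, patient_id = paste0("P", i), label = "control",
    prediction = if (i <= 3) c("infection", "control") else c("control", "control"))))
  d <- discordance_rate(dec)
  expect_equal(d$per_fold$discordance, 30)
  agree <- dec |> dplyr::mutate(prediction = "control")
  expect_equal(discordance_rate(agree)$per_fold$discordance, 0)
})

test_that("strict rule dominance over ROI-level rates", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      n <- 12
      dec <- dplyr::bind_rows(lapply(seq_len(n), function(i) tibble::tibble(
        patient_id = paste0("P", i),
        label = sample(c("infection", "control"), 1),
        prediction = sample(c("infection", "control"), 2, replace = TRUE))))
      res <- strict_patient_accuracy(dec)
      roi_inf <- dec |> dplyr::filter(label == "infection")
      roi_con <- dec |> dplyr::filter(label == "control")
      if (nrow(roi_inf)) {
        recall <- 100 * mean(roi_inf$prediction == "infection")
        inf_acc <- res$per_class$accuracy[res$per_class$label == "infection"]
        expect_gte(inf_acc, recall - 1e-9)
      }
      if (nrow(roi_con)) {
        spec <- 100 * mean(roi_con$prediction == "control")
        con_acc <- res$per_class$accuracy[res$per_class$label == "control"]
        expect_lte(con_acc, spec + 1e-9)
      }
    }
  })
})

test_that("scripted losses drive early stopping exactly at patience", {
  # constant loss: one improving epoch (from Inf), then `patience` stalls
  m <- scripted_model(rep(1, 50))
  cfg <- train_config(phase1 = list(max_epochs = 50, early_stop_patience = 3),
                      phase2 = list(epochs = 10, early_stop_patience = 2))
  out <- train_two_phase(m, config = cfg)
  h1 <- out$history[out$history$phase == "phase1", ]
  expect_equal(nrow(h1), 1 + 3) # patience + 1 epochs
  h2 <- out$history[out$history$phase == "phase2", ]
  expect_equal(nrow(h2), 1 + 2)
  # strictly improving losses never stop early
  m2 <- scripted_model(seq(1, 0.1, length.out = 8), seq(0.1, 0.05, length.out = 4))
  cfg2 <- train_config(phase1 = list(max_epochs = 8, early_stop_patience = 3),
                       phase2 = list(epochs = 4, early_stop_patience = 2))
  out2 <- train_two_phase(m2, config = cfg2)
  expect_equal(nrow(out2$history[out2$history$phase == "phase1", ]), 8)
  expect_equal(nrow(out2$history[out2$history$phase == "phase2", ]), 4)
})

test_that("plateau halves the learning rate and respects the floor", {
  m <- scripted_model(rep(1, 40))
  cfg <- train_config(phase1 = list(lr = 1e-4, plateau_factor = 0.5,
                                    plateau_patience = 1, min_lr = 2e-5,
                                    max_epochs = 40, early_stop_patience = 10),
                      phase2 = list(lr = 5e-5, epochs = 5, early_stop_patience = 2))
  out <- train_two_phase(m, config = cfg)
  h1 <- out$history[out$history$phase == "phase1", ]
  expect_equal(nrow(h1), 11)
  # lr recorded at the start of each epoch: halves after each stalled epoch
  expect_equal(h1$lr[1:5], c(1e-4, 1e-4, 5e-5, 2.5e-5, 2e-5))
  expect_true(all(h1$lr >= 2e-5))
  # the paper-scale floor
  cfg2 <- train_config(phase1 = list(lr = 1e-4, plateau_patience = 1,
                                     max_epochs = 60, early_stop_patience = 50),
                       phase2 = list(epochs = 5, early_stop_patience = 2))
  out2 <- train_two_phase(scripted_model(rep(1, 60)), config = cfg2)
  h <- out2$history[out2$history$phase == "phase1", ]
  expect_true(all(h$lr >= 1e-7))
  expect_equal(min(h$lr), 1e-7)
})

test_that("train/validation patient overlap is refused", {
  tr <- radfusion:::model_data(array(0, c(4, 4, 3, 2)), NULL, c(1L, 2L), c("P1", "P2"))
  va <- radfusion:::model_data(array(0, c(4, 4, 3, 2)), NULL, c(1L, 2L), c("P2", "P3"))
  expect_error(train_two_phase(scripted_model(1), tr, va, train_config()),
               "leakage")
})
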