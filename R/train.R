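# Two-phase training: full-network training with plateau-based learning-rate
# reduction and early stopping, then fine-tuning with the first 70% of the
# layers frozen at a reduced learning rate. The schedule logic is shared
# between real models and scripted stubs (predetermined validation losses),
# so the stopping semantics are unit-testable in isolation.

#' Training configuration
#'
#' Defaults follow the full-scale schedule: phase 1 trains all layers with
#' Adam at lr 1e-4, halving the learning rate after `plateau_patience`
#' epochs without validation-loss improvement (floor 1e-7), for up to 200
#' epochs with early-stopping patience 10 and best-validation weights
#' restored; phase 2 freezes the first 70% of layers and fine-tunes at lr
#' 1e-5 for up to 20 epochs with patience 5.
#'
#' @param phase1,phase2 lists overriding individual phase settings.
#' @param augmentation an [augment_params()] list.
#' @param batch_size minibatch size.
#' @param seed master seed for shuffling/augmentation/dropout streams.
#' @param weight_carryover start each outer fold from the previous fold's
#'   weights instead of a fresh initialization. Off by default: carry-over
#'   lets fold f start from weights that have seen fold f-1's test patients,
#'   which leaks information across folds.
#' @param inner_rotations train all inner-fold rotations and keep the model
#'   with the best validation loss (default: inner fold 1 is the validation
#'   set).
#' @return a `train_config` list.
#' @export
train_config <- function(phase1 = list(), phase2 = list(),
                         augmentation = augment_params(),
                         batch_size = 16L, seed = 1L,
                         weight_carryover = FALSE,
                         inner_rotations = FALSE) {
  p1 <- utils::modifyList(
    list(lr = 1e-4, plateau_factor = 0.5, plateau_patience = 5L,
         min_lr = 1e-7, max_epochs = 200L, early_stop_patience = 10L),
    phase1)
  p2 <- utils::modifyList(
    list(lr = 1e-5, freeze_fraction = 0.7, epochs = 20L,
         early_stop_patience = 5L),
    phase2)
  if (p1$min_lr > p1$lr || p1$min_lr > p2$lr) {
    abort("`min_lr` must not exceed the phase learning rates.")
  }
  if (p1$early_stop_patience >= p1$max_epochs || p2$early_stop_patience >= p2$epochs) {
    abort("early-stopping patience must be smaller than the epoch cap.")
  }
  structure(list(phase1 = p1, phase2 = p2, augmentation = augmentation,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 weight_carryover = isTRUE(weight_carryover),
                 inner_rotations = isTRUE(inner_rotations)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' The full schedule at reduced epoch caps (phase 1 capped at 20 epochs,
#' phase 2 at 5), for smoke runs and synthetic-cohort experiments.
#'
#' @param ... overrides passed to [train_config()].
#' @export
train_config_desk <- function(...) {
  args <- utils::modifyList(
    list(phase1 = list(max_epochs = 20L, early_stop_patience = 10L),
         phase2 = list(epochs = 5L, early_stop_patience = 3L)),
    list(...))
  do.call(train_config, args)
}

# bundle of inputs for one model: images (H,W,3,N), optional radiomics
# matrix (N,k), integer labels (1 = infection, 2 = control), patient ids
model_data <- function(images, radiomics, y, patient_id) {
  list(images = images, radiomics = radiomics, y = as.integer(y),
       patient_id = patient_id)
}

augment_batch <- function(images, aug) {
  for (n in seq_len(dim(images)[4])) {
    a <- augment(images[, , 1, n], aug)
    images[, , , n] <- array(rep(a, 3L), c(dim(images)[1], dim(images)[2], 3L))
  }
  images
}

# ---- scripted stub --------------------------------------------------------

#' Stub model with predetermined validation losses
#'
#' Used to test the training-schedule semantics (early stopping, plateau
#' learning-rate reduction) without touching a real network: the training
#' loop consumes one scripted validation loss per epoch and performs no
#' parameter updates.
#'
#' @param phase1_losses,phase2_losses numeric vectors of validation losses;
#'   if a phase runs longer than the script, the last value repeats.
#' @export
scripted_model <- function(phase1_losses, phase2_losses = phase1_losses) {
  structure(list(losses = list(phase1 = phase1_losses, phase2 = phase2_losses)),
            class = "scripted_model")
}

scripted_loss <- function(model, phase, epoch) {
  v <- model$losses[[phase]]
  v[min(epoch, length(v))]
}

# ---- phase runner ---------------------------------------------------------

run_phase <- function(model, train, val, pcfg, phase, cfg, has_plateau = TRUE) {
  scripted <- inherits(model, "scripted_model")
  lr <- pcfg$lr
  max_epochs <- pcfg$max_epochs %||% pcfg$epochs
  state <- if (!scripted) new_adam_state(lr = lr) else NULL
  best_loss <- Inf
  best_model <- model
  wait <- 0L
  plateau_wait <- 0L
  rows <- list()
  for (epoch in seq_len(max_epochs)) {
    train_loss <- NA_real_
    train_acc <- NA_real_
    if (!scripted) {
      state$lr <- lr
      n <- dim(train$images)[4]
      idx <- sample.int(n)
      losses <- c(); accs <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        take <- idx[start:min(start + cfg$batch_size - 1, n)]
        xb <- augment_batch(train$images[, , , take, drop = FALSE], cfg$augmentation)
        rb <- if (is.null(train$radiomics)) NULL else train$radiomics[take, , drop = FALSE]
        st <- nn_train_step(model, state, xb, rb, train$y[take])
        model <- st$handle
        state <- st$state
        losses <- c(losses, st$loss)
        accs <- c(accs, st$acc)
      }
      train_loss <- mean(losses)
      train_acc <- mean(accs)
      ev <- nn_evaluate(model, val$images, val$radiomics, val$y)
      val_loss <- ev$loss
      val_acc <- ev$acc
    } else {
      val_loss <- scripted_loss(model, phase, epoch)
      val_acc <- NA_real_
    }
    rows[[epoch]] <- tibble(phase = phase, epoch = epoch, lr = lr,
                            train_loss = train_loss, train_acc = train_acc,
                            val_loss = val_loss, val_acc = val_acc)
    if (val_loss < best_loss - 1e-12) {
      best_loss <- val_loss
      best_model <- model
      wait <- 0L
      plateau_wait <- 0L
    } else {
      wait <- wait + 1L
      plateau_wait <- plateau_wait + 1L
    }
    if (has_plateau && plateau_wait >= pcfg$plateau_patience) {
      lr <- max(lr * pcfg$plateau_factor, pcfg$min_lr)
      plateau_wait <- 0L
    }
    if (wait >= pcfg$early_stop_patience) break
  }
  list(model = best_model, history = bind_rows(rows))
}

#' Two-phase training with early stopping and plateau reduction
#'
#' Phase 1 trains all layers (Adam, plateau-based learning-rate halving down
#' to `min_lr`, early stopping on validation loss with best-weights
#' restoration). Phase 2 freezes the first 70% of the layer inventory and
#' fine-tunes the remainder at a reduced constant learning rate with its own
#' early stopping. Works on `rf_model` handles and on [scripted_model()]
#' stubs (schedule semantics only).
#'
#' @param model an `rf_model` or `scripted_model`.
#' @param train,val `model_data` bundles; their patient sets must be
#'   disjoint.
#' @param config a [train_config()].
#' @return list with `model` (best weights) and `history` (tibble: `phase`,
#'   `epoch`, `lr`, `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
train_two_phase <- function(model, train = NULL, val = NULL, config = train_config()) {
  if (!is.null(train$patient_id) && !is.null(val$patient_id)) {
    overlap <- intersect(unique(train$patient_id), unique(val$patient_id))
    if (length(overlap)) {
      abort(paste0("leakage: patients in both train and validation: ",
                   paste(utils::head(overlap, 3), collapse = ", ")))
    }
  }
  p1 <- run_phase(model, train, val, config$phase1, "phase1", config,
                  has_plateau = TRUE)
  model <- p1$model
  if (inherits(model, "rf_model")) {
    model <- freeze_fraction(model, config$phase2$freeze_fraction)
  }
  pcfg2 <- config$phase2
  pcfg2$max_epochs <- pcfg2$epochs
  p2 <- run_phase(model, train, val, pcfg2, "phase2", config,
                  has_plateau = FALSE)
  list(model = p2$model, history = bind_rows(p1$history, p2$history))
}
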