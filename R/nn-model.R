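# Forward/backward passes through whole models, the softmax cross-entropy
# loss, the Adam optimiser, shape inspection, and prediction.

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class labels in 1..n_classes
softmax_ce <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = p, dlogits = dl / n)
}

model_forward <- function(handle, ximg, xrad = NULL, training = FALSE, record = NULL) {
  segs <- handle$segments
  rec <- record %||% function(name, x) invisible(NULL)
  if (handle$kind == "base") {
    b <- seg_forward(segs$backbone, ximg, training, record)
    rec("backbone_map", b$out)
    h <- seg_forward(segs$head, b$out, training, record)
    return(list(logits = h$out, caches = list(backbone = b$caches, head = h$caches)))
  }
  if (is.null(xrad)) abort("fusion model requires radiomics inputs.")
  if (ncol(xrad) != handle$config$radiomics_input_dim) {
    abort(sprintf("radiomics input has %d features; config expects %d",
                  ncol(xrad), handle$config$radiomics_input_dim))
  }
  b <- seg_forward(segs$backbone, ximg, training, record)
  rec("backbone_map", b$out)
  aspp_out <- list()
  aspp_cache <- list()
  for (i in 1:4) {
    nm <- paste0("aspp_", i)
    r <- seg_forward(segs[[nm]], b$out, training, record)
    rec(nm, r$out)
    aspp_out[[i]] <- r$out
    aspp_cache[[nm]] <- r$caches
  }
  ctx <- seg_forward(segs$context, b$out, training, record)
  cat5 <- cat_channels(c(aspp_out, list(ctx$out)))
  rec("five_path_concat", cat5)
  comp <- seg_forward(segs$compress, cat5, training, record)
  rad <- seg_forward(segs$radiomics, xrad, training, record)
  fused <- cat_channels(list(comp$out, rad$out))
  rec("fused_concat", fused)
  h <- seg_forward(segs$head, fused, training, record)
  list(logits = h$out,
       caches = c(list(backbone = b$caches), aspp_cache,
                  list(context = ctx$caches, compress = comp$caches,
                       radiomics = rad$caches, head = h$caches)))
}

model_backward <- function(handle, caches, dlogits) {
  segs <- handle$segments
  grads <- list()
  if (handle$kind == "base") {
    h <- seg_backward(segs$head, caches$head, dlogits)
    grads$head <- h$grads
    b <- seg_backward(segs$backbone, caches$backbone, h$dx)
    grads$backbone <- b$grads
    return(grads)
  }
  h <- seg_backward(segs$head, caches$head, dlogits)
  grads$head <- h$grads
  cfg <- handle$config
  parts <- split_channels(h$dx, c(cfg$compress_filters, cfg$radiomics_widths[2]))
  rad <- seg_backward(segs$radiomics, caches$radiomics, parts[[2]])
  grads$radiomics <- rad$grads
  comp <- seg_backward(segs$compress, caches$compress, parts[[1]])
  grads$compress <- comp$grads
  five <- split_channels(comp$dx, c(rep(cfg$aspp_filters, 4), cfg$context_filters))
  dbmap <- NULL
  for (i in 1:4) {
    nm <- paste0("aspp_", i)
    a <- seg_backward(segs[[nm]], caches[[nm]], five[[i]])
    grads[[nm]] <- a$grads
    dbmap <- if (is.null(dbmap)) a$dx else dbmap + a$dx
  }
  ctx <- seg_backward(segs$context, caches$context, five[[5]])
  grads$context <- ctx$grads
  dbmap <- dbmap + ctx$dx
  b <- seg_backward(segs$backbone, caches$backbone, dbmap)
  grads$backbone <- b$grads
  grads
}

# apply freshly computed batch-norm running statistics after a training step
apply_bn_updates <- function(layers, caches) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "bn" && !is.null(caches[[i]]$new_running)) {
      layers[[i]]$running_mean <- caches[[i]]$new_running$mean
      layers[[i]]$running_var <- caches[[i]]$new_running$var
    } else if (l$type == "dense_unit") {
      layers[[i]]$inner <- apply_bn_updates(l$inner, caches[[i]]$inner)
    }
  }
  layers
}

model_apply_bn <- function(handle, caches) {
  for (nm in names(handle$segments)) {
    handle$segments[[nm]] <- apply_bn_updates(handle$segments[[nm]], caches[[nm]])
  }
  handle
}

# ---- Adam -----------------------------------------------------------------

new_adam_state <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, m = list())
}

adam_update_layers <- function(layers, grads, state, prefix) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    key <- paste0(prefix, "/", l$name)
    if (l$type == "dense_unit") {
      res <- adam_update_layers(l$inner, g$inner, state, key)
      layers[[i]]$inner <- res$layers
      state <- res$state
      next
    }
    if (is.null(g) || !l$trainable) next
    for (p in names(g)) {
      pk <- paste0(key, "#", p)
      mv <- state$m[[pk]] %||% list(m = 0 * g[[p]], v = 0 * g[[p]])
      mv$m <- state$beta1 * mv$m + (1 - state$beta1) * g[[p]]
      mv$v <- state$beta2 * mv$v + (1 - state$beta2) * g[[p]]^2
      state$m[[pk]] <- mv
      mhat <- mv$m / (1 - state$beta1^state$t)
      vhat <- mv$v / (1 - state$beta2^state$t)
      layers[[i]][[p]] <- l[[p]] - state$lr * mhat / (sqrt(vhat) + state$eps)
    }
  }
  list(layers = layers, state = state)
}

adam_step <- function(handle, grads, state) {
  state$t <- state$t + 1L
  for (nm in names(handle$segments)) {
    res <- adam_update_layers(handle$segments[[nm]], grads[[nm]], state, nm)
    handle$segments[[nm]] <- res$layers
    state <- res$state
  }
  list(handle = handle, state = state)
}

# one optimisation step on a batch; returns updated handle/state plus loss
nn_train_step <- function(handle, state, ximg, xrad, y) {
  fw <- model_forward(handle, ximg, xrad, training = TRUE)
  ce <- softmax_ce(fw$logits, y)
  grads <- model_backward(handle, fw$caches, ce$dlogits)
  handle <- model_apply_bn(handle, fw$caches)
  res <- adam_step(handle, grads, state)
  list(handle = res$handle, state = res$state, loss = ce$loss,
       acc = mean(max.col(ce$probs) == y))
}

# loss/accuracy without parameter updates
nn_evaluate <- function(handle, ximg, xrad, y, batch_size = 32L) {
  n <- dim(ximg)[4]
  total <- 0
  correct <- 0
  probs <- matrix(0, n, handle$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- model_forward(handle,
                        ximg[, , , idx, drop = FALSE],
                        if (is.null(xrad)) NULL else xrad[idx, , drop = FALSE],
                        training = FALSE)
    ce <- softmax_ce(fw$logits, y[idx])
    total <- total + ce$loss * length(idx)
    correct <- correct + sum(max.col(ce$probs) == y[idx])
    probs[idx, ] <- ce$probs
  }
  list(loss = total / n, acc = correct / n, probs = probs)
}

#' Class probabilities for a batch of inputs
#'
#' @param object an `rf_model`.
#' @param images `H x W x 3 x N` array of standardized patches.
#' @param radiomics `N x k` matrix of selected, standardized radiomics
#'   features (fusion models only).
#' @param ... unused.
#' @return `N x n_classes` matrix of softmax probabilities; column order is
#'   `(infection, control)` when used through the nested-CV protocol.
#' @export
predict.rf_model <- function(object, images, radiomics = NULL, ...) {
  fw <- model_forward(object, images, radiomics, training = FALSE)
  softmax_rows(fw$logits)
}

#' Named internal activation shapes for a probe batch
#'
#' Runs a forward pass on a randomly generated probe batch and records the
#' shape of every named activation, including the backbone feature map, each
#' ASPP path, the pooled/projected/upsampled context path, the five-path
#' concatenation, the compressed map, the radiomics branch stages, the fused
#' representation, and the head. `channels` is the channel dimension for
#' spatial activations and the feature dimension for vector activations.
#'
#' @param handle an `rf_model`.
#' @param batch_size probe batch size.
#' @param seed seed for the probe batch.
#' @return tibble with columns `name`, `shape`, `channels`.
#' @export
inspect_shapes <- function(handle, batch_size = 1L, seed = 1L) {
  cfg <- handle$config
  shapes <- list()
  record <- function(name, x) {
    d <- if (is.matrix(x)) c(nrow(x), ncol(x)) else dim(x)
    shapes[[length(shapes) + 1L]] <<- tibble(
      name = name,
      shape = paste(d, collapse = "x"),
      channels = if (length(d) == 4) d[3] else d[2]
    )
  }
  with_local_seed(seed, {
    ximg <- array(stats::runif(cfg$input_size^2 * 3 * batch_size),
                  c(cfg$input_size, cfg$input_size, 3L, batch_size))
    xrad <- if (handle$kind == "fusion") {
      matrix(stats::rnorm(batch_size * cfg$radiomics_input_dim),
             batch_size, cfg$radiomics_input_dim)
    } else NULL
    fw <- model_forward(handle, ximg, xrad, training = FALSE, record = record)
    record("logits", fw$logits)
  })
  bind_rows(shapes)
}
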