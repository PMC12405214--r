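# Base and fusion classifier architectures.
#
# The image branch of the fusion model processes the backbone feature map
# through five parallel paths: four atrous (dilated) 3x3 convolutions with
# dilation rates 1/6/12/18 (batch-norm + ReLU, `aspp_filters` channels each)
# and a global-context path (global average pooling, a 1x1 projection to
# `context_filters` channels with ReLU, and upsampling back to the grid —
# upsampling from a single cell is constant, so it is implemented as
# broadcast replication). The five outputs are concatenated and compressed
# by a 1x1 convolution. The radiomics branch maps the selected features
# through two fully connected layers with dropout, reshapes to 1x1 and
# upsamples to the grid. Both branches are concatenated along channels,
# globally pooled, and classified through a fully connected head with
# dropout and softmax.

#' Configuration of the base / fusion classifiers
#'
#' Defaults reproduce the full-scale architecture: 224x224 inputs, a
#' DenseNet-201-style backbone (1920 feature channels on a 7x7 grid), ASPP
#' dilation rates 1/6/12/18 with 512 filters, a 512-channel global-context
#' path and 512-channel compression, a 50-feature radiomics branch widened
#' through 128 and 512 units, and a 256-unit head with dropout 0.3. The
#' `"tiny"` backbone (see [fusion_config_tiny()]) is a reduced-scale variant
#' of the same topology for desk-scale experiments.
#'
#' @param backbone `"densenet201"`, `"mobilenetv3large"`, or `"tiny"`.
#' @param input_size input side in pixels.
#' @param aspp_dilations integer vector of 4 dilation rates.
#' @param aspp_filters,context_filters,compress_filters channel widths of the
#'   ASPP paths, global-context path, and 1x1 compression.
#' @param radiomics_input_dim number of selected radiomics features.
#' @param radiomics_widths widths of the two fully connected radiomics
#'   layers; the second must match the spatial branches for fusion.
#' @param head_width width of the fully connected head.
#' @param dropout_head,dropout_radiomics dropout rates.
#' @param n_classes number of output classes.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(backbone = c("densenet201", "mobilenetv3large", "tiny"),
                          input_size = 224L,
                          aspp_dilations = c(1L, 6L, 12L, 18L),
                          aspp_filters = 512L,
                          context_filters = 512L,
                          compress_filters = 512L,
                          radiomics_input_dim = 50L,
                          radiomics_widths = c(128L, 512L),
                          head_width = 256L,
                          dropout_head = 0.3,
                          dropout_radiomics = 0.3,
                          n_classes = 2L) {
  backbone <- match.arg(backbone)
  if (length(aspp_dilations) != 4L) abort("`aspp_dilations` must have 4 entries.")
  widths <- c(aspp_filters, context_filters, compress_filters,
              radiomics_widths, head_width)
  if (any(widths <= 0)) abort("all channel widths must be positive.")
  if (length(radiomics_widths) != 2L) abort("`radiomics_widths` must have 2 entries.")
  structure(
    list(backbone = backbone, input_size = as.integer(input_size),
         aspp_dilations = as.integer(aspp_dilations),
         aspp_filters = as.integer(aspp_filters),
         context_filters = as.integer(context_filters),
         compress_filters = as.integer(compress_filters),
         radiomics_input_dim = as.integer(radiomics_input_dim),
         radiomics_widths = as.integer(radiomics_widths),
         head_width = as.integer(head_width),
         dropout_head = dropout_head, dropout_radiomics = dropout_radiomics,
         n_classes = as.integer(n_classes)),
    class = "fusion_config"
  )
}

#' Reduced-scale configuration for desk-scale training
#'
#' Same dual-branch topology at a fraction of the width and resolution:
#' 32x32 inputs into a 3-stage convolutional backbone (64 channels on a 4x4
#' grid), 32-channel ASPP/context/compression paths and a 32/32 radiomics
#' branch. Used by the synthetic-cohort experiments and tests where the
#' full-scale model would be needlessly slow.
#'
#' @param ... overrides passed to [fusion_config()].
#' @export
fusion_config_tiny <- function(...) {
  defaults <- list(backbone = "tiny", input_size = 32L,
                   aspp_filters = 32L, context_filters = 32L,
                   compress_filters = 32L, radiomics_widths = c(32L, 32L),
                   head_width = 32L)
  args <- utils::modifyList(defaults, list(...))
  do.call(fusion_config, args)
}

backbone_layers <- function(config) {
  bb <- config$backbone
  if (bb == "densenet201") {
    layers <- list(
      layer_conv("stem_conv", 7L, 7L, 3L, 64L, stride = 2L),
      layer_bn("stem_bn", 64L),
      layer_relu("stem_relu"),
      layer_maxpool("stem_pool", 3L, 2L)
    )
    ch <- 64L
    growth <- 32L
    blocks <- c(6L, 12L, 48L, 32L)
    for (b in seq_along(blocks)) {
      for (u in seq_len(blocks[b])) {
        layers <- c(layers, list(layer_denseblock_unit(sprintf("db%d_u%02d", b, u), ch, growth)))
        ch <- ch + growth
      }
      if (b < length(blocks)) {
        half <- ch %/% 2L
        layers <- c(layers, list(
          layer_bn(sprintf("trans%d_bn", b), ch),
          layer_relu(sprintf("trans%d_relu", b)),
          layer_conv(sprintf("trans%d_conv", b), 1L, 1L, ch, half),
          layer_avgpool(sprintf("trans%d_pool", b), 2L, 2L)
        ))
        ch <- half
      }
    }
    layers <- c(layers, list(layer_bn("final_bn", ch), layer_relu("final_relu")))
    list(layers = layers, out_ch = ch, grid = config$input_size %/% 32L)
  } else if (bb == "mobilenetv3large") {
    widths <- c(24L, 40L, 80L, 160L)
    layers <- list(
      layer_conv("stem_conv", 3L, 3L, 3L, 16L, stride = 2L),
      layer_bn("stem_bn", 16L),
      layer_relu("stem_relu")
    )
    ch <- 16L
    for (s in seq_along(widths)) {
      layers <- c(layers, list(
        layer_conv(sprintf("stage%d_conv1", s), 3L, 3L, ch, widths[s], stride = 2L),
        layer_bn(sprintf("stage%d_bn1", s), widths[s]),
        layer_relu(sprintf("stage%d_relu1", s)),
        layer_conv(sprintf("stage%d_conv2", s), 3L, 3L, widths[s], widths[s]),
        layer_bn(sprintf("stage%d_bn2", s), widths[s]),
        layer_relu(sprintf("stage%d_relu2", s))
      ))
      ch <- widths[s]
    }
    layers <- c(layers, list(
      layer_conv("final_conv", 1L, 1L, ch, 960L),
      layer_bn("final_bn", 960L),
      layer_relu("final_relu")
    ))
    list(layers = layers, out_ch = 960L, grid = config$input_size %/% 32L)
  } else { # tiny
    widths <- c(16L, 32L, 64L)
    layers <- list()
    ch <- 3L
    for (s in seq_along(widths)) {
      layers <- c(layers, list(
        layer_conv(sprintf("stage%d_conv", s), 3L, 3L, ch, widths[s], stride = 2L),
        layer_bn(sprintf("stage%d_bn", s), widths[s]),
        layer_relu(sprintf("stage%d_relu", s))
      ))
      ch <- widths[s]
    }
    list(layers = layers, out_ch = ch, grid = config$input_size %/% 8L)
  }
}

head_layers <- function(in_dim, config, prefix = "head") {
  list(
    layer_gap(paste0(prefix, "_pool")),
    layer_dense(paste0(prefix, "_fc"), in_dim, config$head_width),
    layer_relu(paste0(prefix, "_relu")),
    layer_dropout(paste0(prefix, "_dropout"), config$dropout_head),
    layer_dense(paste0(prefix, "_logits"), config$head_width, config$n_classes)
  )
}

#' Build the base (image-only) classifier
#'
#' Backbone feature extractor, global average pooling, a fully connected
#' layer of `head_width` units with dropout, and a softmax output. All
#' weights are randomly initialised (no pretraining).
#'
#' @param config a [fusion_config()].
#' @param seed RNG seed for weight initialisation.
#' @return an `rf_model` handle.
#' @export
build_base_model <- function(config, seed = 1L) {
  if (!inherits(config, "fusion_config")) abort("`config` must be a `fusion_config`.")
  with_local_seed(seed, {
    bb <- backbone_layers(config)
    segments <- list(
      backbone = bb$layers,
      head = head_layers(bb$out_ch, config)
    )
    new_rf_model("base", config, segments, bb, seed)
  })
}

#' Build the dual-branch fusion classifier
#'
#' @inheritParams build_base_model
#' @return an `rf_model` handle.
#' @export
build_fusion_model <- function(config, seed = 1L) {
  if (!inherits(config, "fusion_config")) abort("`config` must be a `fusion_config`.")
  with_local_seed(seed, {
    bb <- backbone_layers(config)
    g <- bb$grid
    aspp <- lapply(seq_len(4L), function(i) {
      d <- config$aspp_dilations[i]
      list(
        layer_conv(sprintf("aspp%d_conv", i), 3L, 3L, bb$out_ch, config$aspp_filters,
                   dilation = d),
        layer_bn(sprintf("aspp%d_bn", i), config$aspp_filters),
        layer_relu(sprintf("aspp%d_relu", i))
      )
    })
    names(aspp) <- paste0("aspp_", seq_len(4L))
    context <- list(
      layer_gap("context_pool"),
      layer_dense("context_proj", bb$out_ch, config$context_filters),
      layer_relu("context_relu"),
      layer_broadcast("context_upsample", g, g)
    )
    concat_ch <- 4L * config$aspp_filters + config$context_filters
    compress <- list(
      layer_conv("compress_conv", 1L, 1L, concat_ch, config$compress_filters),
      layer_bn("compress_bn", config$compress_filters),
      layer_relu("compress_relu")
    )
    rw <- config$radiomics_widths
    radiomics <- list(
      layer_dense("rad_fc1", config$radiomics_input_dim, rw[1]),
      layer_relu("rad_relu1"),
      layer_dropout("rad_dropout1", config$dropout_radiomics),
      layer_dense("rad_fc2", rw[1], rw[2]),
      layer_relu("rad_relu2"),
      layer_dropout("rad_dropout2", config$dropout_radiomics),
      layer_broadcast("rad_upsample", g, g)
    )
    fused_ch <- config$compress_filters + rw[2]
    segments <- c(list(backbone = bb$layers), aspp,
                  list(context = context, compress = compress,
                       radiomics = radiomics,
                       head = head_layers(fused_ch, config)))
    new_rf_model("fusion", config, segments, bb, seed)
  })
}

new_rf_model <- function(kind, config, segments, bb, seed) {
  handle <- structure(
    list(kind = kind, config = config, segments = segments,
         out_ch = bb$out_ch, grid = bb$grid, seed = seed),
    class = "rf_model"
  )
  handle
}

#' @export
print.rf_model <- function(x, ...) {
  inv <- layer_inventory(x)
  cat(sprintf("<rf_model> %s / %s backbone: %d layers, %s parameters (%d trainable layers)\n",
              x$kind, x$config$backbone, nrow(inv),
              format(sum(inv$n_params), big.mark = ","), sum(inv$trainable)))
  invisible(x)
}

layer_param_count <- function(l) {
  if (l$type == "dense_unit") return(sum(vapply(l$inner, layer_param_count, 0)))
  sum(vapply(c("W", "b", "gamma", "beta"), function(p) length(l[[p]]), 0))
}

# Depth-first ordered walk over atomic layers; fn(layer, index) -> layer.
model_map_layers <- function(handle, fn) {
  counter <- 0L
  walk <- function(layers) {
    lapply(layers, function(l) {
      if (l$type == "dense_unit") {
        l$inner <- walk(l$inner)
        l
      } else {
        counter <<- counter + 1L
        fn(l, counter)
      }
    })
  }
  handle$segments <- lapply(handle$segments, walk)
  handle
}

#' Ordered layer inventory of a model
#'
#' Flattens the model into its atomic layers, in forward order; composite
#' DenseNet units contribute their inner layers. The inventory order defines
#' the meaning of "the first `x`% of the layers" for [freeze_fraction()].
#'
#' @param handle an `rf_model`.
#' @return tibble with `index`, `name`, `type`, `n_params`, `trainable`.
#' @export
layer_inventory <- function(handle) {
  rows <- list()
  handle <- model_map_layers(handle, function(l, i) {
    rows[[i]] <<- tibble(index = i, name = l$name, type = l$type,
                         n_params = layer_param_count(l), trainable = l$trainable)
    l
  })
  bind_rows(rows)
}

#' Freeze the first fraction of layers
#'
#' Marks the first `floor(fraction * L)` atomic layers of the inventory as
#' non-trainable (their parameters are skipped by the optimiser); remaining
#' layers stay trainable.
#'
#' @param handle an `rf_model`.
#' @param fraction in `[0, 1]`.
#' @return the modified handle.
#' @export
freeze_fraction <- function(handle, fraction = 0.7) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  total <- nrow(layer_inventory(handle))
  n_freeze <- floor(fraction * total)
  model_map_layers(handle, function(l, i) {
    l$trainable <- i > n_freeze
    l
  })
}

#' Sum of all model parameters (reproducibility checksum)
#' @param handle an `rf_model`.
#' @return a double.
#' @export
model_checksum <- function(handle) {
  total <- 0
  model_map_layers(handle, function(l, i) {
    for (p in c("W", "b", "gamma", "beta")) {
      if (!is.null(l[[p]])) total <<- total + sum(l[[p]])
    }
    l
  })
  total
}

#' Total parameter count
#' @param handle an `rf_model`.
#' @return integer-valued double.
#' @export
model_n_params <- function(handle) sum(layer_inventory(handle)$n_params)
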