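# The engine is validated by finite-difference gradient checks on a small
# configuration, then the architecture contracts are asserted on the handles.

grad_check <- function(model, ximg, xrad, y, picks, tol = 1e-5) {
  model <- radfusion:::model_map_layers(model, function(l, i) {
    if (l$type == "dropout") l$rate <- 0
    l
  })
  fw <- radfusion:::model_forward(model, ximg, xrad, training = TRUE)
  ce <- radfusion:::softmax_ce(fw$logits, y)
  gr <- radfusion:::model_backward(model, fw$caches, ce$dlogits)
  loss_at <- function(m) {
    f <- radfusion:::model_forward(m, ximg, xrad, training = TRUE)
    radfusion:::softmax_ce(f$logits, y)$loss
  }
  for (p in picks) {
    eps <- 1e-6
    mp <- model; mm <- model
    mp$segments[[p$seg]][[p$idx]][[p$par]][p$el] <-
      mp$segments[[p$seg]][[p$idx]][[p$par]][p$el] + eps
    mm$segments[[p$seg]][[p$idx]][[p$par]][p$el] <-
      mm$segments[[p$seg]][[p$idx]][[p$par]][p$el] - eps
    num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    ana <- gr[[p$seg]][[p$idx]][[p$par]][p$el]
    expect_equal(ana, num, tolerance = tol,
                 label = sprintf("analytic grad %s[%d]$%s", p$seg, p$idx, p$par))
  }
}

test_that("backpropagation matches finite differences across all layer types", {
  withr::with_seed(11, {
    cfg <- fusion_config_tiny(radiomics_input_dim = 5L)
    m <- build_fusion_model(cfg, seed = 3)
    N <- 2
    ximg <- array(runif(32 * 32 * 3 * N), c(32, 32, 3, N))
    xrad <- matrix(rnorm(N * 5), N, 5)
    y <- c(1L, 2L)
    grad_check(m, ximg, xrad, y, list(
      list(seg = "radiomics", idx = 1, par = "W", el = 1),
      list(seg = "aspp_3", idx = 1, par = "W", el = 5),
      list(seg = "aspp_1", idx = 2, par = "gamma", el = 2),
      list(seg = "backbone", idx = 1, par = "W", el = 10),
      list(seg = "backbone", idx = 2, par = "beta", el = 1),
      list(seg = "compress", idx = 1, par = "W", el = 7),
      list(seg = "head", idx = 2, par = "W", el = 3)
    ))
  })
})

test_that("composite dense units and pooling layers backpropagate correctly", {
  withr::with_seed(12, {
    layers <- list(
      radfusion:::layer_conv("c0", 3, 3, 2, 4, stride = 2),
      radfusion:::layer_denseblock_unit("du", 4, 3),
      radfusion:::layer_maxpool("mp", 3, 2),
      radfusion:::layer_avgpool("ap", 2, 2),
      radfusion:::layer_gap("g"),
      radfusion:::layer_dense("d", 7, 2)
    )
    x <- array(runif(16 * 16 * 2 * 2), c(16, 16, 2, 2))
    y <- c(2L, 1L)
    r <- radfusion:::seg_forward(layers, x, TRUE)
    ce <- radfusion:::softmax_ce(r$out, y)
    bk <- radfusion:::seg_backward(layers, r$caches, ce$dlogits)
    fwd <- function(ls) {
      rr <- radfusion:::seg_forward(ls, x, TRUE)
      radfusion:::softmax_ce(rr$out, y)$loss
    }
    for (pick in list(c(1, 3), c(6, 2))) {
      eps <- 1e-6
      lp <- layers; lp[[pick[1]]]$W[pick[2]] <- lp[[pick[1]]]$W[pick[2]] + eps
      lm <- layers; lm[[pick[1]]]$W[pick[2]] <- lm[[pick[1]]]$W[pick[2]] - eps
      expect_equal(bk$grads[[pick[1]]]$W[pick[2]],
                   (fwd(lp) - fwd(lm)) / (2 * eps), tolerance = 1e-5)
    }
    eps <- 1e-6
    lp <- layers; lp[[2]]$inner[[6]]$W[4] <- lp[[2]]$inner[[6]]$W[4] + eps
    lm <- layers; lm[[2]]$inner[[6]]$W[4] <- lm[[2]]$inner[[6]]$W[4] - eps
    expect_equal(bk$grads[[2]]$inner[[6]]$W[4],
                 (fwd(lp) - fwd(lm)) / (2 * eps), tolerance = 1e-5)
  })
})

test_that("model outputs are probability simplices", {
  withr::with_seed(13, {
    cfg <- fusion_config_tiny(radiomics_input_dim = 4L)
    for (m in list(build_base_model(cfg, 1), build_fusion_model(cfg, 1))) {
      N <- 3L
      ximg <- array(runif(32 * 32 * 3 * N), c(32, 32, 3, N))
      xrad <- if (m$kind == "fusion") matrix(rnorm(N * 4), N, 4) else NULL
      p <- predict(m, ximg, xrad)
      expect_identical(dim(p), c(N, 2L))
      expect_true(all(p >= 0))
      expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
    }
  })
})

test_that("fusion model has strictly more parameters than its base model", {
  cfg <- fusion_config_tiny(radiomics_input_dim = 4L)
  expect_gt(model_n_params(build_fusion_model(cfg, 1)),
            model_n_params(build_base_model(cfg, 1)))
})

test_that("construction is deterministic under a seed", {
  cfg <- fusion_config_tiny(radiomics_input_dim = 4L)
  expect_identical(model_checksum(build_fusion_model(cfg, 7)),
                   model_checksum(build_fusion_model(cfg, 7)))
  expect_false(identical(model_checksum(build_fusion_model(cfg, 7)),
                         model_checksum(build_fusion_model(cfg, 8))))
})

test_that("freeze_fraction freezes exactly the first floor(f * L) layers", {
  cfg <- fusion_config_tiny(radiomics_input_dim = 4L)
  m <- build_base_model(cfg, 1)
  inv <- layer_inventory(m)
  L <- nrow(inv)
  m7 <- freeze_fraction(m, 0.7)
  inv7 <- layer_inventory(m7)
  expect_equal(sum(!inv7$trainable), floor(0.7 * L))
  expect_false(any(inv7$trainable[seq_len(floor(0.7 * L))]))
  m0 <- freeze_fraction(m, 0)
  expect_true(all(layer_inventory(m0)$trainable))
  m1 <- freeze_fraction(m, 1)
  expect_true(all(!layer_inventory(m1)$trainable))
  expect_error(freeze_fraction(m, 1.2), "\\[0, 1\\]")
})

test_that("zeroed radiomics branch makes the output depend on images only", {
  withr::with_seed(14, {
    cfg <- fusion_config_tiny(radiomics_input_dim = 4L)
    m <- build_fusion_model(cfg, 2)
    m <- radfusion:::model_map_layers(m, function(l, i) {
      if (startsWith(l$name, "rad_")) {
        for (p in c("W", "b")) if (!is.null(l[[p]])) l[[p]] <- 0 * l[[p]]
      }
      l
    })
    ximg <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
    p1 <- predict(m, ximg, matrix(rnorm(4), 1))
    p2 <- predict(m, ximg, matrix(rnorm(4), 1))
    expect_equal(p1, p2, tolerance = 1e-12)
  })
})

test_that("one optimisation step decreases the loss on a tiny batch", {
  withr::with_seed(15, {
    cfg <- fusion_config_tiny(radiomics_input_dim = 4L)
    for (kind in c("base", "fusion")) {
      m <- if (kind == "base") build_base_model(cfg, 4) else build_fusion_model(cfg, 4)
      m <- radfusion:::model_map_layers(m, function(l, i) {
        if (l$type == "dropout") l$rate <- 0
        l
      })
      N <- 4
      ximg <- array(runif(32 * 32 * 3 * N), c(32, 32, 3, N))
      xrad <- if (kind == "fusion") matrix(rnorm(N * 4), N, 4) else NULL
      y <- c(1L, 2L, 1L, 2L)
      st <- radfusion:::new_adam_state(lr = 1e-3)
      before <- radfusion:::model_forward(m, ximg, xrad, training = TRUE)
      l0 <- radfusion:::softmax_ce(before$logits, y)$loss
      r <- radfusion:::nn_train_step(m, st, ximg, xrad, y)
      after <- radfusion:::model_forward(r$handle, ximg, xrad, training = TRUE)
      l1 <- radfusion:::softmax_ce(after$logits, y)$loss
      expect_lt(l1, l0)
    }
  })
})

test_that("radiomics input dimension is validated against the selection width", {
  cfg <- fusion_config_tiny(radiomics_input_dim = 4L)
  m <- build_fusion_model(cfg, 1)
  ximg <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_error(predict(m, ximg, matrix(0, 1, 7)), "expects 4")
})

test_that("shape inspection reports the documented internal geometry (tiny)", {
  cfg <- fusion_config_tiny(radiomics_input_dim = 4L)
  sh <- inspect_shapes(build_fusion_model(cfg, 1))
  get <- function(nm) sh$channels[sh$name == nm]
  expect_equal(get("backbone_map"), 64)
  expect_equal(get("five_path_concat"), 5 * 32)
  expect_equal(get("fused_concat"), 64)
  expect_equal(get("rad_upsample"), 32)
  expect_equal(get("context_pool"), 64)
  expect_equal(get("logits"), 2)
})
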