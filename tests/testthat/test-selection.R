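make_feature_tbl <- function(n_per_class = 10, p = 6, seed = 3) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
    lab <- rep(c("infection", "control"), each = n_per_class)
    X[, 1] <- X[, 1] + ifelse(lab == "infection", 2, 0) # informative
    X[, 2] <- 7                                          # constant
    dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%02d", seq_len(n)), label = lab),
      tibble::as_tibble(X))
  })
}

test_that("F scores match an independently fitted one-way ANOVA", {
  tbl <- make_feature_tbl(n_per_class = 20)
  scores <- rank_features(tbl)
  for (f in c("f1", "f3", "f5")) {
    oracle <- stats::oneway.test(tbl[[f]] ~ tbl$label, var.equal = TRUE)$statistic
    expect_equal(unname(scores[f]), unname(oracle), tolerance = 1e-10)
  }
})

test_that("degenerate features rank last, perfect separators first", {
  tbl <- make_feature_tbl()
  tbl$f4 <- ifelse(tbl$label == "infection", 1, 0) # perfect separator
  scores <- rank_features(tbl)
  expect_equal(unname(scores["f2"]), 0)
  expect_equal(unname(scores["f4"]), 1e12)
  ord <- names(sort(scores, decreasing = TRUE))
  expect_equal(ord[1], "f4")
  sel <- select_top_k(scores, k = 6)
  expect_equal(dplyr::last(sel$selected), "f2")
})

test_that("single-class and too-small inputs are rejected", {
  tbl <- make_feature_tbl()
  expect_error(rank_features(tbl |> dplyr::filter(label == "control")), "two classes")
})

test_that("top-k selection: count, tie-breaking by catalog order", {
  scores <- c(a = 3, b = 5, c = 5, d = 1)
  sel <- select_top_k(scores, 2)
  expect_equal(sel$selected, c("b", "c")) # b before c: earlier position wins tie
  scores2 <- c(a = 5, b = 5, c = 1)
  expect_equal(select_top_k(scores2, 1)$selected, "a")
  expect_equal(select_top_k(scores, 4)$selected, c("b", "c", "a", "d"))
  expect_error(select_top_k(scores, 0), "positive")
  expect_error(select_top_k(scores, 9), "exceeds")
})

test_that("leakage guard refuses test-fold patients in the ranking data", {
  tbl <- make_feature_tbl()
  expect_error(rank_features(tbl, forbidden_ids = c("P03", "P99")),
               "leakage")
  expect_silent(rank_features(tbl, forbidden_ids = c("P98", "P99")))
})

test_that("scaler comes from training rows and standardizes them", {
  tbl <- make_feature_tbl(n_per_class = 10)
  train <- tbl[1:14, ]
  scores <- rank_features(tbl)
  sel <- select_top_k(scores, 3, fold_id = 1, training_tbl = train)
  Z <- apply_selection(train, sel)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-10)
  # applying to other rows is not centred in general
  Z2 <- apply_selection(tbl[15:20, ], sel)
  expect_identical(dim(Z2), c(6L, 3L))
})

test_that("selection frequencies equal brute-force counting", {
  cat_tbl <- feature_catalog()
  withr::with_seed(5, {
    sels <- lapply(1:5, function(f) {
      sel_names <- sample(cat_tbl$name, 50)
      structure(list(fold_id = f, scores = NULL, selected = sel_names, scaler = NULL),
                class = "selection_result")
    })
  })
  freq <- selection_frequency(sels, cat_tbl)
  expect_equal(sum(freq$frequency), 50 * 5)
  expect_true(all(freq$frequency <= 5))
  brute <- table(unlist(lapply(sels, `[[`, "selected")))
  for (nm in names(brute)) {
    expect_equal(freq$frequency[freq$feature == nm], as.integer(brute[[nm]]))
  }
  # identical selections in all folds
  same <- lapply(1:5, function(f) sels[[1]])
  freq_same <- selection_frequency(same, cat_tbl)
  expect_equal(sum(freq_same$frequency == 5), 50)
  expect_equal(sum(freq_same$frequency == 0), 378 - 50)
})
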