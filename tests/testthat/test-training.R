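test_that("stratified folds partition samples and preserve class ratios", {
  y <- rep(c(1, 1, 1, 2), 25)            # 75 / 25 imbalance
  plan <- cv_plan(k = 5, repeats = 2, seed = 9)
  folds <- make_folds(y, plan)
  for (r in 1:2) {
    fr <- folds[folds$repeat_id == r, ]
    expect_setequal(fr$sample_idx, seq_along(y))
    for (f in 1:5) {
      idx <- fr$sample_idx[fr$fold == f]
      expect_equal(sum(y[idx] == 2), 5)  # 25 positives over 5 folds
      expect_lte(abs(length(idx) - 20), 1)
    }
  }
  expect_identical(folds, make_folds(y, plan))   # reproducible from seed
  expect_false(identical(folds, make_folds(y, cv_plan(5, 2, seed = 10))))
})

test_that("metrics match hand-derived values", {
  # perfect predictions
  m <- suppressWarnings(
    compute_metrics(c(1, 1, 2, 2), c(1, 1, 2, 2),
                    cbind(c(.9, .8, .1, .2), c(.1, .2, .9, .8))))
  expect_equal(m$macro_f1, 1); expect_equal(m$auc, 1)
  # all-positive predictor on balanced binary data:
  # F1(+) = 2/3, F1(-) = 0 -> macro-F1 = 1/3
  y <- rep(c(1, 2), each = 10)
  m2 <- compute_metrics(y, rep(2, 20))
  expect_equal(m2$macro_f1, 1 / 3)
  expect_equal(m2$weighted_f1, 1 / 3)
  # AUC of reversed scores is the complement
  set.seed(41)
  s <- runif(20)
  a1 <- suppressWarnings(compute_metrics(y, rep(2, 20), cbind(1 - s, s)))$auc
  a2 <- suppressWarnings(compute_metrics(y, rep(2, 20), cbind(s, 1 - s)))$auc
  expect_equal(a1 + a2, 1)
  # weighted F1 equals macro F1 on balanced data
  set.seed(42)
  pred <- sample(1:2, 20, replace = TRUE)
  m3 <- compute_metrics(y, pred)
  expect_equal(m3$weighted_f1, m3$macro_f1)
  expect_error(compute_metrics(rep(1, 5), rep(1, 5), cbind(1, 0)),
               "single-class")
})

test_that("macro-F1 is invariant under class relabeling", {
  set.seed(43)
  y <- sample(1:3, 60, replace = TRUE)
  pred <- sample(1:3, 60, replace = TRUE)
  m1 <- compute_metrics(y, pred)$macro_f1
  relab <- c(2L, 3L, 1L)
  m2 <- compute_metrics(relab[y], relab[pred])$macro_f1
  expect_equal(m1, m2)
})

test_that("rank-statistic AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  y <- rep(0:1, each = 30)
  s <- rnorm(60) + y
  ours <- suppressWarnings(
    compute_metrics(y + 1, rep(2, 60), cbind(1 - s, s)))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("sensitivity at fixed specificity matches an exhaustive scan", {
  # separated scores
  expect_equal(sensitivity_at_specificity(
    c(rep(0.1, 150), rep(0.9, 150)), rep(0:1, each = 150)), 1)
  # constant scores: nothing clears 99% specificity
  suppressWarnings(
    expect_equal(sensitivity_at_specificity(rep(0.5, 40),
                                            rep(0:1, each = 20)), 0))
  # 200 negatives U(0,1), 200 positives U(0.5,1.5) vs brute-force scan
  set.seed(45)
  sc <- c(runif(200), runif(200, 0.5, 1.5))
  y <- rep(0:1, each = 200)
  got <- sensitivity_at_specificity(sc, y, 0.99)
  cand <- sort(unique(c(sc, Inf)))
  ok <- vapply(cand, function(t) mean(sc[y == 0] < t) >= 0.99, TRUE)
  best <- min(cand[ok])
  expect_equal(got, mean(sc[y == 1] >= best))
})

test_that("training is deterministic and decreases the loss on a toy task", {
  mask <- matrix(1, 4, 2, dimnames = list(paste0("g", 1:4), c("p1", "p2")))
  set.seed(46)
  y <- rep(1:2, each = 10)
  eg <- array(rnorm(4 * 2 * 20), c(4, 2, 20))
  eg[1:2, , y == 2] <- eg[1:2, , y == 2] + 3      # linearly separable
  p0 <- matrix(0, 2, 2)
  cfg <- train_config(epochs = 6, batch_size = 10, val_fraction = 0,
                      seed = 7, model_mode = "psnn")
  f1 <- train_model(eg, y, mask, p0, cfg)
  f2 <- train_model(eg, y, mask, p0, cfg)
  expect_identical(model_params(f1$model)[[1]]$value,
                   model_params(f2$model)[[1]]$value)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_lt(mean(tail(f1$history$loss, 2)), mean(head(f1$history$loss, 2)))
  # and a different seed changes the fit
  f3 <- train_model(eg, y, mask, p0,
                    train_config(epochs = 6, batch_size = 10,
                                 val_fraction = 0, seed = 8,
                                 model_mode = "psnn"))
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("model modes drop the expected components", {
  fx <- small_fixture()
  dg <- dim(fx$eg)[2L]
  att <- attention_config(n_blocks = 1, n_heads = 2, head_dim = 2,
                          hidden = 4)
  n_par <- function(mode) {
    set.seed(1)
    m <- init_model(fx$mask, dg, fx$crosstalk$matrix, 2, att,
                    train_config(model_mode = mode))
    sum(vapply(model_params(m), function(p) length(p$value), 0))
  }
  expect_gt(n_par("full"), n_par("psnn"))
  # nn has no projection or attention blocks at all
  set.seed(1)
  m_nn <- init_model(fx$mask, dg, fx$crosstalk$matrix, 2, att,
                     train_config(model_mode = "nn"))
  expect_null(m_nn$proj); expect_null(m_nn$blocks)
  # transformer mode omits the row sub-layer in the forward pass
  set.seed(1)
  m_tr <- init_model(fx$mask, dg, fx$crosstalk$matrix, 2, att,
                     train_config(model_mode = "transformer"))
  egs <- fx$eg; egs[is.na(egs)] <- 0
  fw <- model_forward(m_tr, egs[, , 1:4, drop = FALSE], collect = TRUE)
  expect_length(fw$enc$row_maps, 0L)
})

test_that("pooling modes produce the documented shapes and values", {
  ep <- rand_cube(3, 4, 2, seed = 47)
  pm <- pool_embedding(ep, "mean_over_dims")
  expect_equal(dim(pm), c(2L, 3L))
  expect_equal(pm[1, ], rowMeans(ep[, , 1]))
  expect_equal(dim(pool_embedding(ep, "flatten")), c(2L, 12L))
  expect_equal(pool_embedding(ep, "max_over_dims")[2, ],
               apply(ep[, , 2], 1, max))
  # constant embedding pools to the constant
  expect_equal(unname(pool_embedding(array(3, c(2, 5, 1)))[1, ]), c(3, 3))
  expect_error(pool_embedding(ep, "nope"), "unknown pooling")
})

test_that("masked projection weights stay exactly zero through training", {
  fx <- small_fixture()
  fit <- train_model(fx$eg, fx$sim$labels$label, fx$mask,
                     fx$crosstalk$matrix,
                     train_config(epochs = 3, seed = 3, model_mode = "psnn"))
  w <- fit$model$proj$weights$value
  expect_true(all(w[fx$mask == 0] == 0))
  expect_true(any(w[fx$mask == 1] != 0))
})

test_that("cross-validation never fits the normalizer on test folds", {
  # a deliberate-leakage switch exists for regression testing; its
  # normalizer statistics must differ from the honest per-fold ones
  eg <- array(rnorm(3 * 1 * 30), c(3, 1, 30))
  norm_all <- fit_normalizer(eg)
  norm_tr <- fit_normalizer(eg, 1:20)
  expect_false(isTRUE(all.equal(norm_all$center, norm_tr$center)))
  y <- rep(1:2, 15)
  # a class missing from a training fold is an error
  expect_error(
    cross_validate(eg, c(rep(1, 28), 2, 2), matrix(1, 3, 1),
                   matrix(0, 1, 1), cv_plan(k = 5, repeats = 1),
                   train_config(epochs = 1, model_mode = "nn")),
    "samples per class|absent")
})

test_that("a fitted model round-trips through checkpoint serialization", {
  fx <- small_fixture()
  fit <- train_model(fx$eg, fx$sim$labels$label, fx$mask,
                     fx$crosstalk$matrix,
                     train_config(epochs = 2, seed = 5, model_mode = "psnn"))
  fit2 <- px$deserialize_fit(px$serialize_fit(fit))
  expect_equal(predict(fit2, fx$eg), predict(fit, fx$eg))
  expect_equal(fit2$classes, fit$classes)
})

test_that("tidiers expose history and fold metrics as tibbles", {
  fx <- small_fixture()
  fit <- train_model(fx$eg, fx$sim$labels$label, fx$mask,
                     fx$crosstalk$matrix,
                     train_config(epochs = 2, seed = 5, model_mode = "psnn"))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit), c("model_mode", "n_classes", "n_pathways",
                              "n_genes", "epochs_trained", "best_epoch",
                              "best_val_macro_f1"))
  expect_s3_class(autoplot(fit), "ggplot")
})
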