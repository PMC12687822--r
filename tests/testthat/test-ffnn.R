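# small separable toy: two Gaussian blobs in 2-d
toy_dataset <- function(n = 120, sep = 6, seed = 10) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 2), n, 2) + sep * labels
  structure(list(features = x, labels = labels,
                 meta = data.frame(cell = seq_len(n),
                                   date = as.Date("2022-01-01") + seq_len(n),
                                   provenance = "x"),
                 seq_len = 1L, vars = c("a", "b")),
            class = "labeled_dataset")
}

toy_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_sizes = c(8, 4), max_epochs = 200, batch_size = 32,
         seed = 1, seq_len = 1, variable_subset = c("a", "b")),
    list(...))
  do.call(model_config, args)
}

test_that("bce_with_logits matches the closed form and stays stable", {
  expect_equal(bce_with_logits(0, 1), log(2))
  expect_equal(bce_with_logits(0, 0), log(2))
  # softplus(-3), evaluated independently
  expect_equal(bce_with_logits(-3, 0), log1p(exp(-3)))
  expect_equal(round(bce_with_logits(-3, 0), 4), 0.0486)
  # saturated logits: loss ~ 0 on the correct side, finite on the wrong one
  expect_lt(bce_with_logits(50, 1), 1e-20)
  expect_equal(bce_with_logits(-800, 0), 0)
  expect_true(is.finite(bce_with_logits(800, 0)))
  expect_equal(bce_with_logits(800, 0), 800)
})

test_that("training separates a separable toy and is seed-deterministic", {
  ds <- toy_dataset()
  sp <- split_random(ds, seed = 1)
  m1 <- train(sp$train, sp$test, toy_config(), patience = 20)
  expect_equal(m1$best_val_auc, 1.0)
  # training loss trends down on the separable toy
  lg <- m1$log
  expect_lt(mean(tail(lg$train_loss, 3)), mean(head(lg$train_loss, 3)))
  # identical seed -> identical weights, bit for bit
  m2 <- train(sp$train, sp$test, toy_config(), patience = 20)
  expect_identical(m1$weights, m2$weights)
  # single-class sets are rejected
  bad <- subset_dataset(ds, which(ds$labels == 1))
  expect_error(train(bad, sp$test, toy_config()), "both classes")
})

test_that("label shuffling drives validation AUC to chance", {
  ds <- toy_dataset(n = 240)
  set.seed(5)
  ds$labels <- sample(ds$labels)
  sp <- split_random(ds, seed = 2)
  m <- train(sp$train, sp$test, toy_config(max_epochs = 60), patience = 60)
  auc <- roc_auc(predict_scores(m, sp$test$features), sp$test$labels)
  expect_lt(abs(auc - 0.5), 0.25)
})

test_that("early stopping returns the weights of the best-AUC epoch", {
  ds <- toy_dataset()
  sp <- split_random(ds, seed = 1)
  m <- train(sp$train, sp$test, toy_config(), patience = 15)
  # the returned weights must reproduce the logged maximum, even though
  # later epochs ran (and possibly degraded)
  expect_equal(m$best_val_auc, max(m$log$val_auc))
  expect_equal(m$log$val_auc[m$best_epoch], m$best_val_auc)
  got <- roc_auc(predict_scores(m, sp$test$features), sp$test$labels)
  expect_equal(got, m$best_val_auc)
  expect_gte(nrow(m$log), m$best_epoch)
})

test_that("prediction is monotone in the logit and order-invariant", {
  ds <- toy_dataset()
  sp <- split_random(ds, seed = 1)
  m <- train(sp$train, sp$test, toy_config(), patience = 10)
  s <- predict_scores(m, sp$test$features)
  expect_true(all(s > 0 & s < 1))
  perm <- sample(length(s))
  expect_identical(predict_scores(m, sp$test$features[perm, ]), s[perm])
  # an all-zero network scores exactly 0.5 everywhere
  m0 <- m
  m0$weights$W <- lapply(m0$weights$W, function(w) w * 0)
  m0$weights$b <- lapply(m0$weights$b, function(b) b * 0)
  expect_true(all(predict_scores(m0, sp$test$features) == 0.5))
})

test_that("save -> load -> predict is bit-identical", {
  ds <- toy_dataset()
  sp <- split_random(ds, seed = 1)
  m <- train(sp$train, sp$test, toy_config(), patience = 10)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_scores(m2, sp$test$features),
                   predict_scores(m, sp$test$features))
  expect_identical(m2$calibration, m$calibration)
})

test_that("cross_validate reports one AUC per fold", {
  ds <- toy_dataset(n = 150)
  cv <- cross_validate(ds, toy_config(max_epochs = 40, patience_cv = 5), k = 5)
  expect_length(cv$fold_auc, 5)
  expect_true(all(cv$fold_auc >= 0.95))  # separable
  expect_equal(cv$mean_auc, mean(cv$fold_auc))
})

test_that("predict_map equals per-cell scoring and masks missing history", {
  cube <- tiny_derived_cube(n_lat = 2, n_lon = 2, n_days = 10)
  # build a labeled dataset on this cube and train a tiny model
  set.seed(3)
  cells <- rep(1:4, 8)
  dates <- cube$dates[sample(4:10, 32, replace = TRUE)]
  feats <- assemble_features(cube, cells, dates, 3)
  ds <- structure(list(features = feats,
                       labels = rep(c(0L, 1L), 16),
                       meta = data.frame(cell = cells, date = dates,
                                         provenance = "x"),
                       seq_len = 3L, vars = derived_variables()),
                  class = "labeled_dataset")
  cfg <- model_config(hidden_sizes = c(4), max_epochs = 5, batch_size = 8,
                      seed = 1, seq_len = 3)
  m <- train(subset_dataset(ds, 1:24), subset_dataset(ds, 25:32), cfg,
             patience = 3)
  mp <- predict_map(m, cube, cube$dates[6])
  expect_equal(dim(mp), c(2, 2))
  for (cl in 1:4) {
    v <- assemble_sequence(cube, cl, cube$dates[6], 3)
    expect_equal(mp[cl], predict_scores(m, matrix(v, 1)))
  }
  expect_true(all(mp > 0 & mp < 1))
  expect_error(predict_map(m, cube, cube$dates[2]), "insufficient history")
})
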