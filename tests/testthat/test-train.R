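# Training loop: stratified split, learning progress, loss decomposition,
# shared-seed lambda comparison, checkpointing.

make_tiny_trainset <- function(n_per_class = 5, window = 20, seed = 50) {
  set.seed(seed)
  stacks <- list()
  for (cls in 0:2) {
    for (i in seq_len(n_per_class)) {
      # class-dependent mean shift makes the task learnable at tiny scale
      st <- fake_stack(sprintf("c%d_%d", cls, i), sample(1:2, 1), cls,
                       window = window)
      st$segments <- st$segments + 1.0 * (cls - 1)
      stacks[[length(stacks) + 1]] <- st
    }
  }
  stacks
}

test_that("stratified split hits the 9:1 ratio and is seed-deterministic", {
  spec <- synthetic_spec(n_records = 100, n_classes = 5,
                         duration_range = c(6, 7), seed = 60)
  ds <- generate_dataset(spec, corrupt = FALSE)
  cfg <- train_config(split_ratio = 0.9, seed = 3, epochs = 1)
  sp <- split_dataset(ds, cfg)
  expect_length(sp$train, 90)
  expect_length(sp$test, 10)
  # disjoint
  expect_length(intersect(vapply(sp$train, `[[`, "", "record_id"),
                          vapply(sp$test, `[[`, "", "record_id")), 0)
  # per-class proportions preserved within rounding
  tr_tab <- table(ecglink:::dataset_labels(sp$train))
  te_tab <- table(ecglink:::dataset_labels(sp$test))
  expect_true(all(as.vector(tr_tab) == 18))
  expect_true(all(as.vector(te_tab) == 2))

  sp2 <- split_dataset(ds, cfg)
  expect_identical(vapply(sp$train, `[[`, "", "record_id"),
                   vapply(sp2$train, `[[`, "", "record_id"))

  sp3 <- split_dataset(ds, train_config(seed = 4, epochs = 1))
  expect_false(identical(vapply(sp$test, `[[`, "", "record_id"),
                         vapply(sp3$test, `[[`, "", "record_id")))
})

test_that("a class with a single record goes to training with a warning", {
  spec <- synthetic_spec(n_records = 7, n_classes = 3,
                         duration_range = c(6, 6), seed = 61)
  ds <- generate_dataset(spec, corrupt = FALSE)   # 3/2/2 records per class
  ds_small <- ds[c(1, 4, 2, 5, 3)]                # class 2 has 1 record
  expect_warning(sp <- split_dataset(ds_small,
                                     train_config(seed = 1, epochs = 1)),
                 "training only")
  expect_true(2L %in% ecglink:::dataset_labels(sp$train))
  expect_false(2L %in% ecglink:::dataset_labels(sp$test))
})

test_that("one epoch on a tiny set trains, logs, and decomposes the loss", {
  stacks <- make_tiny_trainset()
  tcfg <- train_config(batch_size = 15, epochs = 1, lambda = 0.1, seed = 5)
  res <- train_model(stacks, tcfg, tiny_model_config(), verbose = FALSE)
  expect_equal(nrow(res$log), 1)
  expect_true(is.finite(res$log$train_loss))
  expect_equal(res$log$train_loss,
               res$log$ce_term + 0.1 * res$log$link_term, tolerance = 1e-12)
})

test_that("training reduces the loss on a learnable task", {
  stacks <- make_tiny_trainset()
  tcfg <- train_config(batch_size = 15, epochs = 8, lambda = 0, seed = 5,
                       eval_every = 8)
  res <- train_model(stacks, tcfg, tiny_model_config(), verbose = FALSE)
  expect_lt(res$log$train_loss[8], res$log$train_loss[1])
  expect_gt(res$log$train_accuracy[8], 0.5)
})

test_that("lambda enters only through the link term (shared-seed comparison)", {
  stacks <- make_tiny_trainset()
  base <- train_config(batch_size = 15, epochs = 1, seed = 6)
  # single batch per epoch: the epoch-1 CE is computed before any update
  base$batch_size <- length(stacks)
  cfg_l <- base; cfg_l$lambda <- 0.5
  cfg_0 <- base; cfg_0$lambda <- 0
  res_l <- train_model(stacks, cfg_l, tiny_model_config(), verbose = FALSE)
  res_0 <- train_model(stacks, cfg_0, tiny_model_config(), verbose = FALSE)
  expect_equal(res_l$log$ce_term[1], res_0$log$ce_term[1], tolerance = 1e-12)
  expect_equal(res_0$log$link_term[1], 0)
  expect_gt(res_l$log$link_term[1], 0)
})

test_that("training is bit-reproducible from (config, seed)", {
  stacks <- make_tiny_trainset()
  tcfg <- train_config(batch_size = 15, epochs = 2, lambda = 0.1, seed = 7)
  res1 <- train_model(stacks, tcfg, tiny_model_config(), verbose = FALSE)
  res2 <- train_model(stacks, tcfg, tiny_model_config(), verbose = FALSE)
  expect_identical(res1$log, res2$log)
  expect_identical(res1$model$params, res2$model$params)
  expect_identical(res1$model$bn_running, res2$model$bn_running)
})

test_that("evaluation is deterministic and conserves test counts", {
  stacks <- make_tiny_trainset()
  tcfg <- train_config(batch_size = 15, epochs = 1, seed = 8)
  res <- train_model(stacks, tcfg, tiny_model_config(), verbose = FALSE)
  ev1 <- evaluate_model(res$model, stacks[1:6], n_classes = 3)
  ev2 <- evaluate_model(res$model, stacks[1:6], n_classes = 3)
  expect_identical(ev1$predicted, ev2$predicted)
  expect_identical(ev1$diagnostics$macro_f1, ev2$diagnostics$macro_f1)
  expect_equal(sum(ev1$diagnostics$confusion), 6L)
  expect_length(ev1$diagnostics$per_class_f1, 3)
})

test_that("checkpoints round-trip weights and configuration exactly", {
  m <- model_init(tiny_model_config(), seed = 9)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)

  other <- tempfile(fileext = ".rds")
  saveRDS(list(1), other)
  expect_error(load_model(other), "ecg_model")
})

test_that("degenerate training inputs are rejected with diagnostics", {
  expect_error(train_model(list(), train_config(epochs = 1),
                           tiny_model_config()), "empty")
  st <- fake_stack("u", 1, NA, seed = 70)
  expect_error(train_model(list(st), train_config(epochs = 1),
                           tiny_model_config()), "labelled")
})
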