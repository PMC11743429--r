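test_that("training reduces the loss across seeds and is reproducible", {
  ds <- tiny_dataset()
  for (seed in 1:3) {
    m <- build_organnet(organnet_config(), seed = seed * 10)
    fit <- train_organnet(m, ds, train_config(epochs = 2, seed = seed))
    expect_lt(fit$history$loss[2], fit$history$loss[1])
  }
  m <- build_organnet(organnet_config(), seed = 50)
  f1 <- train_organnet(m, ds, train_config(epochs = 2, seed = 4))
  f2 <- train_organnet(m, ds, train_config(epochs = 2, seed = 4))
  expect_identical(f1$history, f2$history)
  expect_identical(organnet_params(f1$model), organnet_params(f2$model))
})

test_that("a zero learning rate leaves parameters untouched", {
  ds <- tiny_dataset()
  m <- build_organnet(organnet_config(widths = c(6L, 8L)), seed = 60)
  fit <- train_organnet(m, ds, train_config(learning_rate = 0, epochs = 1,
                                            seed = 2))
  expect_identical(organnet_params(fit$model), organnet_params(m))
})

test_that("evaluation equals the metrics module applied to dumped predictions", {
  ds <- tiny_dataset()
  m <- build_organnet(organnet_config(widths = c(6L, 8L)), seed = 70)
  rep <- evaluate_model(m, ds, split = "test")
  preds <- predict_dataset(m, ds, split = "test")
  wide_p <- matrix(preds$label, ncol = 5,
                   dimnames = list(NULL, unique(preds$organ)))
  wide_t <- matrix(preds$truth, ncol = 5)
  oracle <- metrics_report(wide_p[, ORGANS5], wide_t)
  expect_equal(rep$accuracy, oracle$accuracy)
  expect_equal(rep$f1, oracle$f1)
  expect_equal(attr(rep, "macro_f1"), attr(oracle, "macro_f1"))
})

test_that("a constant all-unhealthy predictor has perfect recall", {
  ds <- tiny_dataset()
  m <- set_head_outputs(build_organnet(organnet_config(widths = c(6L, 8L)),
                                       seed = 80), 0, 50)
  rep <- evaluate_model(m, ds, split = "test")
  expect_true(all(rep$recall == 1))
  idx <- which(ds$split == "test")
  expect_equal(rep$accuracy, unname(colMeans(ds$labels[idx, ])))
})

test_that("evaluation is invariant to sample order", {
  ds <- tiny_dataset()
  m <- build_organnet(organnet_config(widths = c(6L, 8L)), seed = 90)
  rep1 <- evaluate_model(m, ds, split = "test")
  perm <- withr::with_seed(1, sample(ds$n))
  ds2 <- ds
  ds2$tensors <- lapply(ds$tensors, function(t) t[perm, , drop = FALSE])
  ds2$labels <- ds$labels[perm, ]
  ds2$split <- ds$split[perm]
  rep2 <- evaluate_model(m, ds2, split = "test")
  expect_equal(tibble::as_tibble(rep1), tibble::as_tibble(rep2))
})

test_that("single-region models report only their organs", {
  ds <- tiny_dataset()
  mB <- build_organnet(organnet_config(widths = c(6L, 8L)), branches = "B",
                       seed = 95)
  rep <- evaluate_model(mB, ds, split = "test")
  expect_identical(rep$organ, "liver")
  pd <- predict_dataset(mB, ds, split = "test")
  expect_true(all(is.na(pd$full_path)))
  expect_equal(pd$fused, pd$region_path)
})

test_that("the ablation table has the six-method structure", {
  ds <- tiny_dataset()
  tab <- run_ablation(ds, train_config(epochs = 1, seed = 3),
                      organnet_config(widths = c(6L, 8L)))
  expect_equal(tab$method, c("baseline_full", "region_A", "region_B",
                             "region_C", "region_D", "organnet"))
  # region B row populated only for liver
  brow <- tab[tab$method == "region_B", ]
  expect_false(is.na(brow$liver_f1))
  expect_true(all(is.na(unlist(
    brow[paste0(c("heart", "lung", "spleen", "kidney"), "_f1")]))))
  # fused model row defined for all organs
  orow <- tab[tab$method == "organnet", ]
  expect_false(anyNA(unlist(orow[paste0(ORGANS5, "_f1")])))
  fits <- attr(tab, "fits")
  expect_named(fits, tab$method)
})

test_that("early stopping halts after stagnant validation epochs", {
  ds <- tiny_dataset()
  m <- build_organnet(organnet_config(widths = c(6L, 8L)), seed = 99)
  fit <- train_organnet(m, ds,
                        train_config(learning_rate = 0, epochs = 6,
                                     patience = 2, seed = 1))
  expect_lt(nrow(fit$history), 6)
  expect_true("val_macro_f1" %in% names(fit$history))
})
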