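test_that("train/test splits have the right size, are disjoint and seeded", {
  s <- split_train_test(100, 0.8, seed = 1)
  expect_length(s$train, 80)
  expect_length(s$test, 20)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:100)
  expect_identical(s, split_train_test(100, 0.8, seed = 1))
  expect_error(split_train_test(100, 1.2), "fraction")
  expect_error(split_train_test(5, 0.8), "at least 10")
})

test_that("a constant response is predicted to within 0.01", {
  set.seed(41)
  df <- data.frame(a = runif(400), b = runif(400), response = 0.37)
  fit <- rich_ann(data = df, config = ann_config(epochs = 50, seed = 2))
  expect_true(all(abs(predict(fit) - 0.37) < 0.01))
})

test_that("forward pass matches hand-computed matrix arithmetic", {
  # 2 features -> 1 relu unit -> output, weights set by hand
  fit <- structure(list(
    weights = list(list(W = matrix(c(0.5, -0.25), 2, 1), b = 0.1),
                   list(W = matrix(2, 1, 1), b = -0.05)),
    feature_names = c("f1", "f2"),
    formula = response ~ ., intercept_only = FALSE
  ), class = "rich_ann")
  X <- matrix(c(0.4, 0.8, 0.9, 0.1), 2, 2,
              dimnames = list(NULL, c("f1", "f2")))
  manual <- pmax(X %*% matrix(c(0.5, -0.25), 2, 1) + 0.1, 0) * 2 - 0.05
  expect_equal(predict(fit, X), as.numeric(manual), tolerance = 1e-10)
})

test_that("training is bit-reproducible under one seed", {
  w <- tiny_world()
  tab <- feature_table_of(w, n_drivers = 5)
  f1 <- rich_ann(data = tab, config = ann_config(epochs = 5, seed = 13))
  f2 <- rich_ann(data = tab, config = ann_config(epochs = 5, seed = 13))
  expect_identical(coef(f1), coef(f2))
  expect_identical(predict(f1), predict(f2))
})

test_that("compiled and reference trainers solve the same problem", {
  # both reach low loss on an easy linear target (trajectories differ;
  # the reference R loop is the independent check on the compiled path)
  set.seed(44)
  n <- 600
  df <- data.frame(a = runif(n), b = runif(n))
  df$response <- 0.2 + 0.3 * df$a + 0.4 * df$b
  cfg <- ann_config(epochs = 200, dropout = 0, seed = 3,
                    learning_rate = 0.02)
  X <- as.matrix(df[, c("a", "b")])
  fit_cpp <- richworld:::.mlp_train(X, df$response, cfg)
  fit_r <- richworld:::.mlp_train_r(X, df$response, cfg)
  pred_cpp <- richworld:::.mlp_forward(fit_cpp$weights, X)
  pred_r <- richworld:::.mlp_forward(fit_r$weights, X)
  expect_lt(sqrt(mean((pred_cpp - df$response)^2)), 0.01)
  expect_lt(sqrt(mean((pred_r - df$response)^2)), 0.01)
})

test_that("no test row enters training and leakage is structurally impossible", {
  w <- tiny_world()
  tab <- feature_table_of(w, n_drivers = 5)
  s <- split_train_test(nrow(tab), 0.8, seed = 5)
  expect_length(intersect(s$train, s$test), 0)
  bad <- s
  bad$test <- c(bad$test, bad$train[1])
  expect_error(rich_ann(data = tab, config = ann_config(epochs = 2),
                        split = bad), "overlap")
})

test_that("prediction validates feature arity and stays finite on the cube", {
  w <- tiny_world()
  tab <- feature_table_of(w, n_drivers = 5)
  fit <- rich_ann(data = tab, config = ann_config(epochs = 5, seed = 6))
  expect_error(predict(fit, tab[, 1:4]), "missing model features")
  set.seed(7)
  Xr <- matrix(runif(500 * 5), 500, 5,
               dimnames = list(NULL, fit$feature_names))
  expect_true(all(is.finite(predict(fit, Xr))))
})

test_that("feature column order does not change predictions", {
  w <- tiny_world()
  tab <- feature_table_of(w, n_drivers = 5)
  fit <- rich_ann(data = tab, config = ann_config(epochs = 5, seed = 8))
  shuffled <- tab[, c("cell_id", "lon", "lat",
                      rev(attr(tab, "feature_names")), "response")]
  expect_equal(predict(fit, shuffled), predict(fit, tab))
})

test_that("evaluate matches a direct two-line recomputation", {
  w <- tiny_world()
  tab <- feature_table_of(w, n_drivers = 5)
  fit <- rich_ann(data = tab, config = ann_config(epochs = 10, seed = 9))
  m <- evaluate(fit, scope = "test")
  obs <- tab$response[fit$split$test]
  pred <- predict(fit)[fit$split$test]
  expect_equal(m$r2, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  expect_equal(m$rmse, sqrt(mean((obs - pred)^2)))
  # perfect fit and null model limits
  fake <- fit
  fake$y <- predict(fit)
  mp <- evaluate(fake, scope = "test")
  expect_equal(mp$r2, 1)
  expect_equal(mp$rmse, 0)
  base <- rich_ann(
    data = tab, config = ann_config(nodes_per_layer = 0, seed = 1))
  expect_equal(evaluate(base, scope = "train")$r2, 0, tolerance = 1e-6)
})

test_that("cross validation partitions folds and selects sensibly", {
  w <- mid_world_noiseless()
  tab <- feature_table_of(w, n_drivers = 8)
  cfg <- ann_config(epochs = 30, seed = 10)
  cv1 <- cross_validate(tab, list(cfg), k = 5, seed = 11)
  expect_equal(cv1$selected_index, 1)
  expect_equal(sum(table(cv1$fold_id)), length(cv1$split$train))
  expect_equal(length(unique(cv1$fold_id)), 5)
  # an intercept-only baseline never beats the default on a nonlinear world
  base <- ann_config(nodes_per_layer = 0, seed = 10)
  cv2 <- cross_validate(tab, list(base, cfg), k = 5, seed = 11)
  expect_equal(cv2$selected_index, 2)
  expect_error(cross_validate(tab, list(cfg), k = 1), "k")
})

test_that("predicted surfaces respect the mask and invert to non-negative richness", {
  w <- tiny_world()
  tab <- feature_table_of(w, n_drivers = 5, domain = "ocean")
  fit <- rich_ann(data = tab, config = ann_config(epochs = 10, seed = 12))
  surf <- predict_surface(fit, tab, w$grid)
  expect_equal(surf$values[tab$cell_id], predict(fit, tab))
  off_cells <- setdiff(seq_len(n_cells(w$grid)), tab$cell_id)
  expect_true(all(is.na(surf$values[off_cells])))
  rich <- richness_from_response(surf$values[tab$cell_id],
                                 attr(tab, "provenance"))
  expect_true(all(rich >= 0))
})

test_that("model JSON round-trips predictions exactly", {
  w <- tiny_world()
  tab <- feature_table_of(w, n_drivers = 5)
  fit <- rich_ann(data = tab, config = ann_config(epochs = 5, seed = 14))
  path <- tempfile(fileext = ".json")
  model_to_json(fit, path)
  back <- model_from_json(path)
  expect_equal(predict(back, tab), predict(fit, tab), tolerance = 1e-12)
  unlink(path)
})
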