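#' Feed-forward neural network for richness modelling
#'
#' The central estimator: a small rectifier multilayer perceptron mapping
#' 0-1 scaled environmental features to the 0-1 scaled ln(x+1) richness
#' response. Defaults mirror the reference protocol: 3 hidden layers of 10
#' rectifier units, 0.2 inverted dropout, plain momentum SGD (momentum
#' 0.9), batch size 128, 10 epochs, squared-error loss, an 80/20
#' train/test split, and 5-fold cross-validated hyperparameter selection.
#' Dropout is disabled at inference, so predictions are deterministic
#' functions of the frozen weights.
#'
#' @name richness_ann
NULL

#' Network and training configuration
#'
#' @param hidden_layers number of hidden layers (default 3; 0 gives an
#'   intercept-only baseline)
#' @param nodes_per_layer rectifier units per hidden layer (default 10;
#'   0 gives an intercept-only baseline)
#' @param dropout dropout fraction in [0, 1) (inverted dropout; default 0.2)
#' @param momentum SGD momentum (default 0.9)
#' @param batch_size minibatch size (default 128)
#' @param epochs passes over the training data (default 10)
#' @param learning_rate SGD step size (default 0.02; with momentum 0.9
#'   the effective step is an order of magnitude larger, so rates above
#'   ~0.05 oscillate)
#' @param lr_decay multiplicative per-epoch learning-rate decay in (0, 1]
#'   (default 1 = constant rate). Annealing the step size averages out the
#'   gradient noise that dropout injects, which matters for long runs on
#'   low-noise targets.
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout masks
#' @return object of class `rw_ann_config`
#' @export
ann_config <- function(hidden_layers = 3L, nodes_per_layer = 10L,
                       dropout = 0.2, momentum = 0.9, batch_size = 128L,
                       epochs = 10L, learning_rate = 0.02, lr_decay = 1,
                       seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  if (batch_size < 1) stop("`batch_size` must be >= 1")
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  if (lr_decay <= 0 || lr_decay > 1) stop("`lr_decay` must be in (0, 1]")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 nodes_per_layer = as.integer(nodes_per_layer),
                 dropout = dropout, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "rw_ann_config")
}

#' @export
print.rw_ann_config <- function(x, ...) {
  cat(sprintf(
    "<rw_ann_config> %d x %d relu, dropout %.2g, momentum %.2g, batch %d, %d epochs, lr %.3g\n",
    x$hidden_layers, x$nodes_per_layer, x$dropout, x$momentum,
    x$batch_size, x$epochs, x$learning_rate))
  invisible(x)
}

#' Random train/test split
#'
#' @param n number of rows (or a data.frame)
#' @param fraction training fraction in (0, 1) (default 0.8)
#' @param seed integer seed
#' @return object of class `rw_split`: list with integer `train` and
#'   `test` index vectors
#' @export
split_train_test <- function(n, fraction = 0.8, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  if (n < 10) stop("need at least 10 rows to split")
  set.seed(seed)
  n_train <- floor(n * fraction)
  train <- sort(sample.int(n, n_train))
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 fraction = fraction, seed = as.integer(seed)),
            class = "rw_split")
}

# ---- MLP internals (base R matrix ops) -----------------------------------

# fan-in scaled uniform initialisation
.mlp_init <- function(sizes) {
  L <- length(sizes) - 1
  lapply(seq_len(L), function(l) {
    r <- sqrt(6 / sizes[l])
    list(W = matrix(stats::runif(sizes[l] * sizes[l + 1], -r, r),
                    sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

# forward pass; weights as produced by .mlp_init; returns n-vector
.mlp_forward <- function(weights, X) {
  A <- X
  L <- length(weights)
  for (l in seq_len(L)) {
    Z <- A %*% weights[[l]]$W
    Z <- sweep(Z, 2, weights[[l]]$b, "+")
    A <- if (l < L) pmax(Z, 0) else Z
  }
  as.numeric(A)
}

.mlp_train <- function(X, y, config) {
  n <- nrow(X); p <- ncol(X)
  set.seed(config$seed)
  intercept_only <- config$hidden_layers == 0L || config$nodes_per_layer == 0L
  if (intercept_only) {
    # degenerate baseline: a single trained bias (converges to mean(y))
    return(list(weights = list(list(W = matrix(0, p, 1), b = mean(y))),
                loss = mean((y - mean(y))^2), intercept_only = TRUE))
  }
  fit <- .mlp_train_cpp(X, as.numeric(y), config$hidden_layers,
                        config$nodes_per_layer, config$dropout,
                        config$momentum, config$batch_size, config$epochs,
                        config$learning_rate,
                        if (is.null(config$lr_decay)) 1 else config$lr_decay)
  fit$intercept_only <- FALSE
  fit
}

# pure-R reference trainer: same architecture/protocol, kept as an
# independent cross-check on the compiled path
.mlp_train_r <- function(X, y, config) {
  n <- nrow(X); p <- ncol(X)
  set.seed(config$seed)
  sizes <- c(p, rep(config$nodes_per_layer, config$hidden_layers), 1L)
  weights <- .mlp_init(sizes)
  vel <- lapply(weights, function(w)
    list(W = w$W * 0, b = w$b * 0))
  L <- length(weights)
  keep <- 1 - config$dropout
  lr <- config$learning_rate
  decay <- if (is.null(config$lr_decay)) 1 else config$lr_decay
  mom <- config$momentum
  loss_hist <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      rows <- ord[((bi - 1) * config$batch_size + 1):
                    min(bi * config$batch_size, n)]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      m <- length(rows)
      # forward with inverted dropout on hidden activations
      A <- vector("list", L + 1)
      masks <- vector("list", L)
      A[[1]] <- Xb
      for (l in seq_len(L)) {
        Z <- A[[l]] %*% weights[[l]]$W
        Z <- sweep(Z, 2, weights[[l]]$b, "+")
        if (l < L) {
          H <- pmax(Z, 0)
          if (config$dropout > 0) {
            msk <- matrix(stats::runif(length(H)) < keep, nrow(H), ncol(H))
            H <- H * msk / keep
            masks[[l]] <- msk
          }
          A[[l + 1]] <- H
        } else A[[l + 1]] <- Z
      }
      pred <- as.numeric(A[[L + 1]])
      err <- pred - yb
      bloss <- mean(err^2)
      if (!is.finite(bloss))
        stop("non-finite training loss at epoch ", ep, ", batch ", bi)
      ep_loss <- ep_loss + bloss * m
      # backward
      delta <- matrix(2 * err / m, m, 1)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(weights[[l]]$W)
          act <- A[[l]]           # post-dropout activations; >0 iff active
          delta <- delta * (act > 0)
          if (config$dropout > 0) delta <- delta * masks[[l - 1]] / keep
        }
        vel[[l]]$W <- mom * vel[[l]]$W - lr * gW
        vel[[l]]$b <- mom * vel[[l]]$b - lr * gb
        weights[[l]]$W <- weights[[l]]$W + vel[[l]]$W
        weights[[l]]$b <- weights[[l]]$b + vel[[l]]$b
      }
    }
    loss_hist[ep] <- ep_loss / n
    lr <- lr * decay
  }
  list(weights = weights, loss = loss_hist, intercept_only = FALSE)
}

# ---- user-facing fit ------------------------------------------------------

#' Fit the richness neural network
#'
#' Fits the rectifier MLP to a feature table by minibatch momentum SGD on
#' squared error. The default formula `response ~ .` uses every feature
#' column of an [build_feature_table()] table (coordinate columns are
#' excluded automatically).
#'
#' @param formula model formula; default `response ~ .` over the feature
#'   columns
#' @param data an `rw_features` table (or plain data.frame)
#' @param config an [ann_config()]
#' @param split an [split_train_test()] result; by default an 80/20 split
#'   seeded from `config$seed`
#' @param ... unused
#' @return object of class `rich_ann` with components `weights`, `config`,
#'   `split`, `feature_names`, `provenance`, `metrics` (train and test
#'   [evaluate()] results), `loss` (per-epoch training loss) and `data`.
#' @examples
#' \donttest{
#' w <- simulate_world(world_config(seed = 1, n_species = 20),
#'                     extent = c(0, 30, 0, 30), cell_km = 100)
#' tab <- build_feature_table(w$drivers$static, w$richness, w$grid)
#' fit <- rich_ann(data = tab, config = ann_config(epochs = 5))
#' print(fit)
#' }
#' @export
rich_ann <- function(formula = response ~ ., data, config = ann_config(),
                     split = NULL, ...) {
  stopifnot(inherits(config, "rw_ann_config"))
  xy <- .design_matrix(formula, data)
  X <- xy$X; y <- xy$y
  n <- nrow(X)
  if (is.null(split)) split <- split_train_test(n, 0.8, config$seed)
  if (max(split$train, split$test) > n) stop("split indices exceed data rows")
  if (length(intersect(split$train, split$test)) > 0)
    stop("train and test indices overlap")
  if (any(X < -1e-8 | X > 1 + 1e-8))
    warning("features outside [0, 1]; scale inputs with rescale_unit()")

  fit <- .mlp_train(X[split$train, , drop = FALSE], y[split$train], config)
  obj <- structure(list(
    weights = fit$weights, config = config, split = split,
    feature_names = colnames(X),
    provenance = attr(data, "provenance"),
    loss = fit$loss, intercept_only = fit$intercept_only,
    call = match.call(), formula = formula, data = data,
    X = X, y = y
  ), class = "rich_ann")
  safe_eval <- function(scope) tryCatch(
    evaluate(obj, scope = scope),
    error = function(e) {
      idx <- if (scope == "train") split$train else split$test
      list(r2 = NA_real_,
           rmse = sqrt(mean((y[idx] - predict(obj)[idx])^2)),
           n = length(idx), scope = scope)
    })
  obj$metrics <- list(train = safe_eval("train"),
                      test = safe_eval("test"))
  obj
}

# build X (features only) and y from formula + data
.design_matrix <- function(formula, data) {
  drop_cols <- c("cell_id", "lon", "lat")
  df <- as.data.frame(data)[, setdiff(names(data), drop_cols), drop = FALSE]
  mf <- stats::model.frame(formula, df)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(mf), mf)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  if (!is.numeric(y)) stop("response must be numeric")
  if (any(!is.finite(y))) stop("response contains non-finite values")
  list(X = X, y = as.numeric(y))
}

#' @export
print.rich_ann <- function(x, ...) {
  cat("Richness feed-forward network\n")
  cat(sprintf("  features: %d; architecture: %s\n", length(x$feature_names),
              if (x$intercept_only) "intercept only"
              else sprintf("%d x %d relu -> 1", x$config$hidden_layers,
                           x$config$nodes_per_layer)))
  cat(sprintf("  train: n = %d, R2 = %.3f, RMSE = %.4f\n",
              x$metrics$train$n, x$metrics$train$r2, x$metrics$train$rmse))
  cat(sprintf("  test:  n = %d, R2 = %.3f, RMSE = %.4f\n",
              x$metrics$test$n, x$metrics$test$r2, x$metrics$test$rmse))
  invisible(x)
}

#' @export
summary.rich_ann <- function(object, ...) {
  print(object)
  cat(sprintf("  final training loss (MSE): %.5f over %d epochs\n",
              utils::tail(object$loss, 1), length(object$loss)))
  npar <- sum(vapply(object$weights, function(w)
    length(w$W) + length(w$b), numeric(1)))
  cat(sprintf("  parameters: %d; dropout %.2g (training only)\n",
              as.integer(npar), object$config$dropout))
  invisible(object)
}

#' @export
coef.rich_ann <- function(object, ...) object$weights

#' Predict from a fitted richness network
#'
#' Deterministic forward pass with dropout disabled.
#'
#' @param object a `rich_ann`
#' @param newdata data.frame or matrix with the model's feature columns;
#'   omitted = the training table
#' @param ... unused
#' @return numeric predictions on the scaled response
#' @export
predict.rich_ann <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else {
    if (is.matrix(newdata)) {
      if (is.null(colnames(newdata))) {
        if (ncol(newdata) != length(object$feature_names))
          stop("newdata has ", ncol(newdata), " columns; model expects ",
               length(object$feature_names))
        colnames(newdata) <- object$feature_names
      }
      newdata
    } else as.data.frame(newdata)
  }
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss))
    stop("newdata is missing model features: ", paste(miss, collapse = ", "))
  X <- as.matrix(X[, object$feature_names, drop = FALSE])
  .mlp_forward(object$weights, X)
}

#' @export
fitted.rich_ann <- function(object, ...)
  predict(object)[object$split$train]

#' @export
residuals.rich_ann <- function(object, scope = c("train", "test", "all"),
                               ...) {
  scope <- match.arg(scope)
  idx <- switch(scope, train = object$split$train,
                test = object$split$test,
                all = seq_along(object$y))
  object$y[idx] - predict(object)[idx]
}

#' @export
plot.rich_ann <- function(x, scope = c("test", "train"), ...) {
  scope <- match.arg(scope)
  idx <- if (scope == "test") x$split$test else x$split$train
  obs <- x$y[idx]
  pred <- predict(x)[idx]
  graphics::plot(pred, obs, xlab = "predicted (scaled response)",
                 ylab = "observed (scaled response)",
                 main = sprintf("%s set, R2 = %.3f", scope,
                                evaluate(x, scope = scope)$r2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Fit metrics of a model on a data scope
#'
#' @param object a `rich_ann`
#' @param data optional table to evaluate on (defaults to the fit table)
#' @param scope `"test"`, `"train"` or `"all"` rows of the fit table
#'   (ignored when `data` is given)
#' @param ... unused
#' @return list with `r2` (1 - SSE/SST), `rmse`, `n` and `scope`
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @export
evaluate.rich_ann <- function(object, data = NULL,
                              scope = c("test", "train", "all"), ...) {
  scope <- match.arg(scope)
  if (!is.null(data)) {
    xy <- .design_matrix(object$formula, data)
    obs <- xy$y
    pred <- predict(object, xy$X)
    scope <- "newdata"
  } else {
    idx <- switch(scope, train = object$split$train,
                  test = object$split$test, all = seq_along(object$y))
    obs <- object$y[idx]
    pred <- predict(object)[idx]
  }
  if (length(obs) == 0) stop("no rows in requested scope")
  sst <- sum((obs - mean(obs))^2)
  sse <- sum((obs - pred)^2)
  if (sst == 0) stop("zero-variance response: R2 undefined")
  list(r2 = 1 - sse / sst, rmse = sqrt(mean((obs - pred)^2)),
       n = length(obs), scope = scope)
}

#' Cross-validated hyperparameter selection
#'
#' k-fold cross validation over the training rows of the split: for each
#' candidate configuration, the network is refitted on k-1 folds and
#' scored (RMSE) on the held-out fold. Selection minimises the mean fold
#' RMSE; ties (within 1e-8) are broken by smaller fold-RMSE variance, then
#' fewer nodes, then candidate order. Both statistics are reported.
#'
#' @param data feature table
#' @param configs list of [ann_config()] candidates
#' @param k number of folds (default 5)
#' @param split optional outer [split_train_test()]; defaults to an 80/20
#'   split seeded from the first candidate
#' @param seed seed for the fold assignment
#' @param formula model formula
#' @return list of class `rw_cv`: `selected` (the chosen config),
#'   `selected_index`, `summary` (per-config mean/variance of fold RMSE)
#'   and `folds` (per-config, per-fold metrics)
#' @export
cross_validate <- function(data, configs, k = 5, split = NULL, seed = 1L,
                           formula = response ~ .) {
  if (k < 2) stop("`k` must be >= 2")
  if (inherits(configs, "rw_ann_config")) configs <- list(configs)
  xy <- .design_matrix(formula, data)
  if (is.null(split))
    split <- split_train_test(nrow(xy$X), 0.8, configs[[1]]$seed)
  rows <- split$train
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(k), length(rows)))
  fold_rmse <- matrix(NA_real_, length(configs), k)
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (f in seq_len(k)) {
      tr <- rows[fold_id != f]
      te <- rows[fold_id == f]
      fit <- .mlp_train(xy$X[tr, , drop = FALSE], xy$y[tr], cfg)
      pred <- .mlp_forward(fit$weights, xy$X[te, , drop = FALSE])
      fold_rmse[ci, f] <- sqrt(mean((xy$y[te] - pred)^2))
    }
  }
  mean_rmse <- rowMeans(fold_rmse)
  var_rmse <- apply(fold_rmse, 1, stats::var)
  nodes <- vapply(configs, function(cfg)
    cfg$hidden_layers * cfg$nodes_per_layer, numeric(1))
  ord <- order(round(mean_rmse / 1e-8), round(var_rmse / 1e-8), nodes,
               seq_along(configs))
  sel <- ord[1]
  structure(list(selected = configs[[sel]], selected_index = sel,
                 summary = data.frame(config = seq_along(configs),
                                      mean_rmse = mean_rmse,
                                      var_rmse = var_rmse, nodes = nodes),
                 folds = fold_rmse, fold_id = fold_id, split = split),
            class = "rw_cv")
}

#' @export
print.rw_cv <- function(x, ...) {
  cat(sprintf("<rw_cv> %d candidate configs, %d folds; selected #%d\n",
              nrow(x$summary), ncol(x$folds), x$selected_index))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write model predictions back onto the grid
#'
#' @param model a `rich_ann`
#' @param table the feature table (rows carry `cell_id`)
#' @param grid the grid (defaults to the table's)
#' @return an `rw_layer`; cells without a table row are `NA`
#' @export
predict_surface <- function(model, table, grid = attr(table, "grid")) {
  if (is.null(grid)) stop("`grid` must be supplied")
  v <- rep(NA_real_, n_cells(grid))
  v[table$cell_id] <- predict(model, table)
  rw_layer(v, grid, "predicted_response")
}
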