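#' Training protocol for the boosted trial-level models
#'
#' Classification models train on binary log loss for up to `max_epochs`
#' boosting rounds (default 10000) with early stopping after 100 rounds
#' without improvement on a held-out validation split; regression models use
#' the l2 loss over up to 1000 rounds with the same stopping rule. Metrics
#' are reported with 5-fold cross-validation. Training is single-threaded
#' and seeded, so fits are bit-reproducible.
#'
#' @param objective `"binary"` (log loss) or `"regression"` (l2).
#' @param max_epochs maximum boosting rounds.
#' @param early_stopping_rounds rounds without validation improvement before
#'   stopping.
#' @param n_folds cross-validation folds.
#' @param valid_fraction fraction of each training fold held out to drive
#'   early stopping.
#' @param params named list of booster hyperparameters (depth, learning
#'   rate, regularization, ...).
#' @param seed integer seed for fold assignment and training.
#' @return an object of class `train_protocol`.
#' @export
train_protocol <- function(objective = c("binary", "regression"),
                           max_epochs = NULL,
                           early_stopping_rounds = 100,
                           n_folds = 5,
                           valid_fraction = 0.2,
                           params = list(max_depth = 3, eta = 0.1,
                                         lambda = 1, subsample = 1),
                           seed = 1) {
  objective <- match.arg(objective)
  if (is.null(max_epochs))
    max_epochs <- if (objective == "binary") 10000 else 1000
  stopifnot(max_epochs >= 1, early_stopping_rounds >= 1, n_folds >= 2,
            valid_fraction > 0, valid_fraction < 1)
  structure(list(objective = objective, max_epochs = max_epochs,
                 early_stopping_rounds = early_stopping_rounds,
                 n_folds = n_folds, valid_fraction = valid_fraction,
                 params = params, seed = seed),
            class = "train_protocol")
}

.xgb_params <- function(protocol) {
  c(list(objective = if (protocol$objective == "binary") "binary:logistic"
         else "reg:squarederror",
         eval_metric = if (protocol$objective == "binary") "logloss"
         else "rmse",
         nthread = 1, seed = protocol$seed),
    protocol$params)
}

.logloss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Balanced accuracy (mean of per-class recalls)
#' @param y 0/1 labels; @param yhat 0/1 predictions.
#' @export
balanced_accuracy <- function(y, yhat) {
  mean(c(mean(yhat[y == 1] == 1), mean(yhat[y == 0] == 0)), na.rm = TRUE)
}

# stratified (classification) or plain fold assignment
.make_folds <- function(y, n_folds, stratify) {
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      rows <- sample(which(y == cl))
      fold[rows] <- rep_len(seq_len(n_folds), length(rows))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

# fit one booster with early stopping on an inner validation split, then
# refit at the chosen round count so the stored trees are exactly the model
.fit_booster <- function(x, y, protocol) {
  stratify <- protocol$objective == "binary"
  n <- length(y)
  vf <- protocol$valid_fraction
  if (stratify) {
    val <- unlist(lapply(unique(y), function(cl) {
      rows <- which(y == cl)
      sample(rows, max(1, round(vf * length(rows))))
    }))
  } else val <- sample.int(n, max(1, round(vf * n)))
  tr <- setdiff(seq_len(n), val)
  pars <- .xgb_params(protocol)
  dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
  dva <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = y[val])
  m0 <- xgboost::xgb.train(params = pars, data = dtr,
                           nrounds = protocol$max_epochs,
                           evals = list(val = dva),
                           early_stopping_rounds = protocol$early_stopping_rounds,
                           verbose = 0)
  ev <- attributes(m0)$evaluation_log[[2]]
  best <- which.min(ev)
  dall <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = pars, data = dall, nrounds = best, verbose = 0)
}

#' Cross-validated boosted model fit
#'
#' Fits the model under the protocol with stratified (classification) or
#' plain (regression) 5-fold cross-validation. Within each training fold a
#' validation split drives early stopping; the fold model is then refit on
#' the full training fold at the selected round count and scored on the
#' held-out test fold. A final model is fit on all rows for attribution.
#'
#' @param ft a `feature_table` (see [build_features()]).
#' @param protocol a [train_protocol()].
#' @return an object of class `gbm_report`: per-fold and mean train/test
#'   metrics (log loss, accuracy, balanced accuracy for classification; MSE
#'   for regression), the fold assignment, the per-fold boosters, and the
#'   final booster.
#' @export
crossval_fit <- function(ft, protocol = train_protocol()) {
  stopifnot(inherits(ft, "feature_table"), inherits(protocol, "train_protocol"))
  x <- ft$x; y <- ft$y
  if (!nrow(x)) stop("empty feature table")
  if (protocol$objective == "binary" && !all(y %in% c(0, 1)))
    stop("binary objective requires 0/1 labels")
  set.seed(protocol$seed)
  stratify <- protocol$objective == "binary"
  fold <- .make_folds(y, protocol$n_folds, stratify)
  if (stratify && any(tapply(y, fold, function(v) length(unique(v))) < 2))
    stop("stratification error: a fold holds a single class")

  rows <- vector("list", protocol$n_folds)
  fold_models <- vector("list", protocol$n_folds)
  for (k in seq_len(protocol$n_folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    m <- .fit_booster(x[tr, , drop = FALSE], y[tr], protocol)
    fold_models[[k]] <- m
    p_tr <- predict(m, x[tr, , drop = FALSE])
    p_te <- predict(m, x[te, , drop = FALSE])
    if (protocol$objective == "binary") {
      rows[[k]] <- data.frame(
        fold = k,
        train_logloss = .logloss(y[tr], p_tr),
        test_logloss = .logloss(y[te], p_te),
        train_accuracy = mean((p_tr > 0.5) == y[tr]),
        test_accuracy = mean((p_te > 0.5) == y[te]),
        train_balanced_accuracy = balanced_accuracy(y[tr], as.numeric(p_tr > 0.5)),
        test_balanced_accuracy = balanced_accuracy(y[te], as.numeric(p_te > 0.5)))
    } else {
      rows[[k]] <- data.frame(
        fold = k,
        train_mse = mean((p_tr - y[tr])^2),
        test_mse = mean((p_te - y[te])^2))
    }
  }
  metrics <- do.call(rbind, rows)
  final <- .fit_booster(x, y, protocol)
  means <- as.list(colMeans(metrics[-1]))
  structure(list(protocol = protocol, feature_names = colnames(x),
                 metrics = metrics, means = means, fold = fold,
                 fold_models = fold_models, model = final,
                 x = x, y = y, meta = ft$meta,
                 model_name = ft$spec$model_name),
            class = "gbm_report")
}

#' @export
print.gbm_report <- function(x, ...) {
  cat(sprintf("gbm_report (%s, %s): %d rows, %d features, %d folds\n",
              x$model_name, x$protocol$objective, nrow(x$x),
              ncol(x$x), x$protocol$n_folds))
  if (x$protocol$objective == "binary")
    cat(sprintf("  mean test accuracy %.4f, balanced accuracy %.4f\n",
                x$means$test_accuracy, x$means$test_balanced_accuracy))
  else
    cat(sprintf("  mean train MSE %.4f, test MSE %.4f\n",
                x$means$train_mse, x$means$test_mse))
  invisible(x)
}

#' Shuffled-label noise floor
#'
#' Destroys the label--feature relationship by permuting the label vector,
#' refits the model with the hyperparameters held constant, and records the
#' held-out metric, repeating `n_shuffles` times. The resulting distribution
#' is the score a model of this capacity achieves on structure-free data. A
#' fixed stratified 80/20 split is used for every shuffle, and the
#' unshuffled baseline is fit on the same split.
#'
#' @param ft a `feature_table`.
#' @param protocol a [train_protocol()].
#' @param n_shuffles number of label permutations.
#' @param seed integer seed.
#' @return list with `baseline` (unshuffled test metric), `floor` (vector of
#'   shuffled test metrics), and their means; metric is MSE for regression,
#'   log loss for classification.
#' @export
noise_floor <- function(ft, protocol = train_protocol("regression"),
                        n_shuffles = 1000, seed = protocol$seed) {
  if (n_shuffles < 1) stop("invalid argument: n_shuffles must be >= 1")
  set.seed(seed)
  x <- ft$x; y <- ft$y
  n <- length(y)
  stratify <- protocol$objective == "binary"
  te <- if (stratify) {
    unlist(lapply(unique(y), function(cl) {
      rows <- which(y == cl); sample(rows, max(1, round(0.2 * length(rows))))
    }))
  } else sample.int(n, round(0.2 * n))
  tr <- setdiff(seq_len(n), te)
  score <- function(yy) {
    m <- .fit_booster(x[tr, , drop = FALSE], yy[tr], protocol)
    p <- predict(m, x[te, , drop = FALSE])
    if (protocol$objective == "binary") .logloss(yy[te], p)
    else mean((p - yy[te])^2)
  }
  baseline <- score(y)
  floor <- vapply(seq_len(n_shuffles), function(i) score(sample(y)), 0)
  list(baseline = baseline, floor = floor, floor_mean = mean(floor),
       metric = if (protocol$objective == "binary") "logloss" else "mse")
}

#' Grid search over booster hyperparameters
#'
#' Evaluates every combination in `space` (or a seeded random subset of
#' `budget` combinations) by cross-validated objective -- log loss for
#' classification, MSE for regression -- and returns the protocol updated
#' with the winning configuration.
#'
#' @param ft a `feature_table`.
#' @param protocol a [train_protocol()].
#' @param space named list of candidate hyperparameter values.
#' @param budget maximum configurations to evaluate; `0` returns the
#'   protocol defaults with a warning.
#' @return list with `protocol` (updated), `best` (winning configuration)
#'   and `results` (objective per configuration).
#' @export
tune_hyperparameters <- function(ft, protocol, space, budget = Inf) {
  if (length(space) == 0 || any(!vapply(space, length, 0L)))
    stop("configuration error: empty search space")
  if (budget == 0) {
    warning("budget = 0: returning protocol defaults")
    return(list(protocol = protocol, best = protocol$params,
                results = NULL))
  }
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  set.seed(protocol$seed)
  if (nrow(grid) > budget)
    grid <- grid[sample.int(nrow(grid), budget), , drop = FALSE]
  objective <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- protocol
    p$params[names(grid)] <- as.list(grid[i, , drop = FALSE])
    rep_i <- crossval_fit(ft, p)
    objective[i] <- if (p$objective == "binary") rep_i$means$test_logloss
      else rep_i$means$test_mse
  }
  best_i <- which.min(objective)
  best <- as.list(grid[best_i, , drop = FALSE])
  protocol$params[names(best)] <- best
  list(protocol = protocol, best = protocol$params,
       results = cbind(grid, objective = objective))
}
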