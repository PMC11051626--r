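#' Parse a fitted booster into double-precision tree structures
#'
#' Extracts every tree (children, split features and thresholds, node
#' covers, leaf values) together with the base margin, so that raw margins
#' and Shapley values can be computed in double precision from the stored
#' model.
#'
#' @param model an `xgb.Booster` or a `gbm_report`.
#' @return list with `trees`, `b0` (base margin), `feature_names`,
#'   `objective`.
#' @keywords internal
parse_booster <- function(model) {
  if (inherits(model, "gbm_report")) model <- model$model
  stopifnot(inherits(model, "xgb.Booster"))
  j <- jsonlite::fromJSON(rawToChar(xgboost::xgb.save.raw(model,
                                                          raw_format = "json")))
  objective <- j$learner$learner_train_param$objective
  if (is.null(objective)) objective <- j$learner$objective$name
  bs <- as.numeric(j$learner$learner_model_param$base_score)
  b0 <- if (identical(objective, "binary:logistic")) stats::qlogis(bs) else bs
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  fn <- j$learner$feature_names
  if (is.null(fn)) fn <- setdiff(unique(dt$Feature), "Leaf")
  trees <- lapply(split(dt, dt$Tree), function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    id2pos <- stats::setNames(seq_len(nrow(tr)), tr$ID)
    leaf <- tr$Feature == "Leaf"
    list(feat = ifelse(leaf, NA_integer_, match(tr$Feature, fn)),
         # the dump prints floats with round-trip precision; snapping back
         # to float32 recovers the stored thresholds and leaf values exactly
         split = .snap_f32(tr$Split),
         yes = ifelse(leaf, NA_integer_, id2pos[tr$Yes]),
         no = ifelse(leaf, NA_integer_, id2pos[tr$No]),
         missing = ifelse(leaf, NA_integer_, id2pos[tr$Missing]),
         cover = tr$Cover,
         value = ifelse(leaf, .snap_f32(tr$Gain), NA_real_))
  })
  list(trees = trees, b0 = b0, feature_names = fn, objective = objective)
}

# snap values to float32, the precision at which the booster stores data
# and thresholds, so split routing matches the fitted model exactly
.snap_f32 <- function(x) {
  v <- readBin(writeBin(as.numeric(x), raw(), size = 4L), what = "double",
               n = length(x), size = 4L)
  if (is.matrix(x)) {
    v <- matrix(v, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  v
}

# raw margin of the parsed model, computed in double precision
.margin_one_tree <- function(tree, x) {
  n <- nrow(x)
  out <- numeric(n)
  rec <- function(nd, rows) {
    f <- tree$feat[nd]
    if (is.na(f)) { out[rows] <<- out[rows] + tree$value[nd]; return(invisible()) }
    v <- x[rows, f]
    na <- is.na(v)
    go_yes <- !na & v < tree$split[nd]
    go_no <- !na & !go_yes
    if (any(na)) rec(tree$missing[nd], rows[na])
    if (any(go_yes)) rec(tree$yes[nd], rows[go_yes])
    if (any(go_no)) rec(tree$no[nd], rows[go_no])
  }
  rec(1L, seq_len(n))
  out
}

#' Raw model output (margin) in double precision
#'
#' Log-odds for classifiers, predicted seconds for the regression models.
#'
#' @param model an `xgb.Booster`, `gbm_report`, or parsed booster.
#' @param x numeric feature matrix.
#' @export
predict_margin <- function(model, x) {
  pm <- if (is.list(model) && !is.null(model$trees)) model else parse_booster(model)
  x <- .snap_f32(x)
  pm$b0 + Reduce(`+`, lapply(pm$trees, .margin_one_tree, x = x))
}

# cover-conditional expectation of one tree for every known-feature subset.
# Rows are collapsed to unique split-decision patterns first; `codes` holds,
# per used feature, the bin of each pattern among that feature's thresholds
# (NA = value missing).
.tree_subset_values <- function(tree, used, thr, codes, n_pat) {
  u <- length(used)
  vals <- vector("list", 2^u)
  for (mask in 0:(2^u - 1)) {
    known <- used[bitwAnd(mask, bitwShiftL(1L, seq_len(u) - 1L)) != 0L]
    out <- numeric(n_pat)
    rec <- function(nd, rows, w) {
      f <- tree$feat[nd]
      if (is.na(f)) { out[rows] <<- out[rows] + w * tree$value[nd]; return(invisible()) }
      if (f %in% known) {
        k <- match(f, used)
        code <- codes[rows, k]
        jpos <- match(tree$split[nd], thr[[k]])
        na <- is.na(code)
        go_yes <- !na & code <= jpos
        go_no <- !na & !go_yes
        if (any(na)) rec(tree$missing[nd], rows[na], w)
        if (any(go_yes)) rec(tree$yes[nd], rows[go_yes], w)
        if (any(go_no)) rec(tree$no[nd], rows[go_no], w)
      } else {
        cl <- tree$cover[tree$yes[nd]]; cr <- tree$cover[tree$no[nd]]
        rec(tree$yes[nd], rows, w * cl / (cl + cr))
        rec(tree$no[nd], rows, w * cr / (cl + cr))
      }
    }
    rec(1L, seq_len(n_pat), 1)
    vals[[mask + 1L]] <- out
  }
  vals
}

#' Exact Shapley attribution for a boosted tree model
#'
#' Computes, in double precision, the exact Shapley values of the
#' path-dependent (cover-weighted) conditional-expectation game defined by
#' the fitted trees: features outside the conditioning set are sent down
#' both children of a split in proportion to training cover. Per tree, only
#' the features that tree actually splits on can carry credit (dummy
#' players), so the per-tree game is solved by exact enumeration over that
#' tree's used-feature subsets and summed across trees (linearity). The row
#' sums plus the expected value reproduce the raw model output exactly, and
#' features never used by the model receive exactly 0.
#'
#' For classifiers the values are in log-odds; for the reaction-time and
#' release-time regressions they are in seconds.
#'
#' @param model an `xgb.Booster` or `gbm_report`.
#' @param x feature matrix to attribute (defaults to the report's training
#'   matrix).
#' @param max_used trees splitting on more than this many distinct features
#'   abort (enumeration is `2^used`); the protocol default depth keeps this
#'   small.
#' @return an object of class `shap_result`: list with `values` (rows =
#'   observations, columns = features), `expected_value`, `margin` (raw
#'   model output per row), and `units`.
#' @export
shap_attribution <- function(model, x = NULL, max_used = 12) {
  if (inherits(model, "gbm_report")) {
    if (is.null(x)) x <- model$x
    model <- model$model
  }
  if (is.null(x)) stop("x is required when model is a raw booster")
  if (!inherits(model, "xgb.Booster")) stop("unsupported model: need a tree ensemble")
  pm <- parse_booster(model)
  x <- .snap_f32(x)
  n <- nrow(x)
  M <- length(pm$feature_names)
  phi <- matrix(0, n, M, dimnames = list(NULL, pm$feature_names))
  expected <- pm$b0
  for (tree in pm$trees) {
    used <- sort(unique(tree$feat[!is.na(tree$feat)]))
    u <- length(used)
    if (u == 0) { expected <- expected + tree$value[1]; next }
    if (u > max_used)
      stop("feasibility error: a tree uses ", u, " features (> max_used)")
    thr <- lapply(used, function(f)
      sort(unique(tree$split[!is.na(tree$feat) & tree$feat == f])))
    # bin observations by this tree's thresholds; identical bins follow
    # identical paths, so Shapley values are computed once per pattern
    codes <- matrix(NA_integer_, n, u)
    for (k in seq_len(u))
      codes[, k] <- findInterval(x[, used[k]], thr[[k]]) + 1L
    codes0 <- codes; codes0[is.na(codes0)] <- 0L
    base_k <- vapply(seq_len(u), function(k) max(codes0[, k]) + 1L, 0L)
    mult <- cumprod(c(1, base_k[-u]))
    key <- as.vector(codes0 %*% mult)
    pat_rows <- match(key, unique(key))
    pat_codes <- codes[!duplicated(key), , drop = FALSE]
    n_pat <- nrow(pat_codes)
    vals <- .tree_subset_values(tree, used, thr, pat_codes, n_pat)
    expected <- expected + vals[[1]][1]
    fw <- factorial(0:u)
    for (k in seq_len(u)) {
      bit <- bitwShiftL(1L, k - 1L)
      phi_k <- numeric(n_pat)
      for (mask in 0:(2^u - 1)) {
        if (bitwAnd(mask, bit) != 0L) next
        s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(u - 1))) != 0L)
        w <- fw[s + 1] * fw[u - s] / fw[u + 1]
        phi_k <- phi_k + w * (vals[[mask + bit + 1L]] - vals[[mask + 1L]])
      }
      phi[, used[k]] <- phi[, used[k]] + phi_k[pat_rows]
    }
  }
  structure(list(values = phi, expected_value = expected,
                 margin = expected + rowSums(phi),
                 units = if (identical(pm$objective, "binary:logistic"))
                   "log-odds" else "seconds"),
            class = "shap_result")
}

#' @export
print.shap_result <- function(x, ...) {
  cat(sprintf("shap_result: %d observations x %d features (%s), E[f] = %.4f\n",
              nrow(x$values), ncol(x$values), x$units, x$expected_value))
  imp <- sort(colMeans(abs(x$values)), decreasing = TRUE)
  cat("  mean |SHAP|:", paste(sprintf("%s=%.3f", names(imp)[seq_len(min(5, length(imp)))],
                                      imp[seq_len(min(5, length(imp)))]),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Brute-force Shapley oracle by global subset enumeration
#'
#' Verification oracle for [shap_attribution()]: enumerates all `2^M`
#' feature subsets of the whole model, evaluating each subset's value as the
#' cover-weighted conditional expectation over every tree (features outside
#' the subset descend both children weighted by training cover), and
#' combines differences with the standard Shapley weights
#' `|S|! (M - |S| - 1)! / M!`. Exponential in the number of features;
#' refuses more than `max_features`.
#'
#' @param model an `xgb.Booster` or `gbm_report`.
#' @param x a single observation (named numeric vector or 1-row matrix).
#' @param max_features feasibility bound on `M`.
#' @return list with `phi` (named per-feature values) and `expected_value`.
#' @export
brute_force_shapley <- function(model, x, max_features = 12) {
  if (inherits(model, "gbm_report")) model <- model$model
  j <- jsonlite::fromJSON(rawToChar(xgboost::xgb.save.raw(model,
                                                          raw_format = "json")))
  objective <- j$learner$learner_train_param$objective
  if (is.null(objective)) objective <- j$learner$objective$name
  bs <- as.numeric(j$learner$learner_model_param$base_score)
  b0 <- if (identical(objective, "binary:logistic")) stats::qlogis(bs) else bs
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  dt$Split <- .snap_f32(dt$Split)
  dt$Gain <- ifelse(dt$Feature == "Leaf", .snap_f32(dt$Gain), dt$Gain)
  fn <- j$learner$feature_names
  if (is.matrix(x)) x <- x[1, ]
  if (is.null(names(x))) names(x) <- fn
  x <- stats::setNames(.snap_f32(x), names(x))
  M <- length(fn)
  if (M > max_features)
    stop("feasibility error: ", M, " features exceed max_features")

  tree_exp <- function(tr, id, known) {
    row <- tr[tr$ID == id, ]
    if (row$Feature == "Leaf") return(row$Gain)
    if (row$Feature %in% known) {
      xv <- x[[row$Feature]]
      nxt <- if (is.na(xv)) row$Missing
        else if (xv < row$Split) row$Yes else row$No
      return(tree_exp(tr, nxt, known))
    }
    cl <- tr$Cover[tr$ID == row$Yes]; cr <- tr$Cover[tr$ID == row$No]
    (cl * tree_exp(tr, row$Yes, known) + cr * tree_exp(tr, row$No, known)) /
      (cl + cr)
  }
  trees <- split(dt, dt$Tree)
  value_of <- function(known)
    b0 + sum(vapply(trees, function(tr) tree_exp(tr, tr$ID[1], known), 0))

  masks <- 0:(2^M - 1)
  vals <- vapply(masks, function(m)
    value_of(fn[bitwAnd(m, bitwShiftL(1L, 0:(M - 1))) != 0L]), 0)
  fw <- factorial(0:M)
  phi <- stats::setNames(numeric(M), fn)
  for (i in seq_len(M)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (m in masks) {
      if (bitwAnd(m, bit) != 0L) next
      s <- sum(bitwAnd(m, bitwShiftL(1L, 0:(M - 1))) != 0L)
      w <- fw[s + 1] * fw[M - s] / fw[M + 1]
      phi[i] <- phi[i] + w * (vals[m + bit + 1L] - vals[m + 1L])
    }
  }
  list(phi = phi, expected_value = vals[1])
}

# score under which permutation importance is a drop (higher = better)
.perm_score <- function(metric, y, pred) {
  switch(metric,
         accuracy = mean((pred > 0.5) == y),
         balanced_accuracy = balanced_accuracy(y, as.numeric(pred > 0.5)),
         logloss = -.logloss(y, pred),
         mse = -mean((pred - y)^2),
         stop("configuration error: unknown metric ", metric))
}

#' Permutation feature importance
#'
#' The decrease in a model score when a single feature column is randomly
#' permuted on held-out data: a score of 0.1 for a model with 70% accuracy
#' reflects a drop to 60% accuracy. Implemented from first principles;
#' importance is averaged over `n_repeats` independent permutations and
#' reported with its standard deviation.
#'
#' For a `gbm_report` the held-out data are the cross-validation test folds,
#' scored by each fold's own model. A bare prediction `function(x)` (or
#' booster) with explicit `x`, `y` is also accepted.
#'
#' @param object a `gbm_report`, `xgb.Booster`, or prediction function.
#' @param x,y evaluation data (required unless `object` is a `gbm_report`).
#' @param metric `"accuracy"`, `"balanced_accuracy"`, `"logloss"` or
#'   `"mse"`; defaults to accuracy for classifiers and MSE for regressions.
#' @param n_repeats permutations per feature.
#' @param seed integer seed.
#' @return data frame with `feature`, `importance` (mean score drop), `sd`,
#'   `n_repeats`, ordered by decreasing importance.
#' @export
permutation_importance <- function(object, x = NULL, y = NULL, metric = NULL,
                                   n_repeats = 10, seed = 1) {
  stopifnot(n_repeats >= 1)
  set.seed(seed)
  if (inherits(object, "gbm_report")) {
    if (is.null(metric))
      metric <- if (object$protocol$objective == "binary") "accuracy" else "mse"
    if (metric %in% c("accuracy", "balanced_accuracy") &&
        object$protocol$objective != "binary")
      stop("configuration error: classification metric on a regression model")
    splits <- lapply(seq_along(object$fold_models), function(k) {
      te <- which(object$fold == k)
      list(predict_fn = local({ m <- object$fold_models[[k]]
                                function(xx) predict(m, xx) }),
           x = object$x[te, , drop = FALSE], y = object$y[te])
    })
  } else {
    if (is.null(x) || is.null(y)) stop("x and y are required")
    if (is.null(metric)) metric <- "accuracy"
    predict_fn <- if (is.function(object)) object
      else function(xx) predict(object, xx)
    splits <- list(list(predict_fn = predict_fn, x = x, y = y))
  }
  feats <- colnames(splits[[1]]$x)
  base <- vapply(splits, function(s)
    .perm_score(metric, s$y, s$predict_fn(s$x)), 0)
  res <- lapply(seq_along(feats), function(fi) {
    drops <- unlist(lapply(seq_along(splits), function(si) {
      s <- splits[[si]]
      vapply(seq_len(n_repeats), function(r) {
        xp <- s$x
        xp[, fi] <- xp[sample.int(nrow(xp)), fi]
        base[si] - .perm_score(metric, s$y, s$predict_fn(xp))
      }, 0)
    }))
    data.frame(feature = feats[fi], importance = mean(drops),
               sd = stats::sd(drops), n_repeats = n_repeats)
  })
  out <- do.call(rbind, res)
  attr(out, "baseline") <- mean(base)
  attr(out, "metric") <- metric
  out[order(-out$importance), ]
}

#' Cumulative gain importance curve and elbow selection
#'
#' Features ranked by total split gain (summed over every tree in which the
#' feature is used), with the cumulative fraction of total gain. The elbow
#' rule retains the smallest prefix of features reaching a threshold
#' fraction of total gain (default 0.95).
#'
#' @param model an `xgb.Booster` or `gbm_report`.
#' @return data frame `feature`, `gain`, `cumulative` (fractions of total
#'   gain, descending); zero rows with a warning for a model with no splits.
#' @export
cumulative_gain_curve <- function(model) {
  if (inherits(model, "gbm_report")) model <- model$model
  imp <- tryCatch(xgboost::xgb.importance(model = model),
                  error = function(e) NULL)
  if (is.null(imp) || nrow(imp) == 0) {
    warning("model has no splits; empty gain curve")
    return(data.frame(feature = character(0), gain = numeric(0),
                      cumulative = numeric(0)))
  }
  data.frame(feature = imp$Feature, gain = imp$Gain,
             cumulative = cumsum(imp$Gain))
}

#' @rdname cumulative_gain_curve
#' @param curve output of `cumulative_gain_curve()`.
#' @param threshold cumulative-gain fraction to reach.
#' @return `elbow_select`: character vector of retained features.
#' @export
elbow_select <- function(curve, threshold = 0.95) {
  if (!nrow(curve)) return(character(0))
  keep <- seq_len(which(curve$cumulative >= threshold - 1e-12)[1])
  curve$feature[keep]
}

#' Per-observation dependence records for SHAP plots
#'
#' Tidy records (feature value, SHAP value, optional color-feature value,
#' group) behind partial-dependence / violin displays of how a feature's
#' impact varies across its values, other features, and subjects.
#' Categorical codes are decoded back to their level labels.
#'
#' @param shap a `shap_result`.
#' @param ft the `feature_table` the SHAP values were computed on.
#' @param feature feature whose SHAP values to extract.
#' @param color_feature optional second feature whose raw value colors each
#'   record.
#' @param groups optional group filter (values of `ft$groups` to keep).
#' @export
dependence_data <- function(shap, ft, feature, color_feature = NULL,
                            groups = NULL) {
  feats <- colnames(shap$values)
  if (!feature %in% feats) stop("schema error: unknown feature ", feature)
  if (!is.null(color_feature) && !color_feature %in% feats)
    stop("schema error: unknown feature ", color_feature)
  decode <- function(nm) {
    v <- ft$x[, nm]
    meta <- ft$meta[[match(nm, vapply(ft$meta, `[[`, "", "feature"))]]
    if (!is.null(meta$levels) && meta$type == "categorical")
      meta$levels[v + 1] else v
  }
  out <- data.frame(feature_value = decode(feature),
                    shap_value = shap$values[, feature],
                    group = ft$groups %||% NA)
  if (!is.null(color_feature)) out$color_value <- decode(color_feature)
  if (!is.null(groups)) out <- out[out$group %in% groups, , drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
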