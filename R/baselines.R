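# decode an integer-coded feature table back into a model frame of factors
# and numerics (identical rows/columns to what the booster consumed)
.as_model_frame <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  df <- as.data.frame(ft$x)
  for (meta in ft$meta) {
    nm <- meta$feature
    if (identical(meta$type, "categorical"))
      df[[nm]] <- factor(meta$levels[df[[nm]] + 1], levels = meta$levels)
    else if (identical(meta$type, "flag"))
      df[[nm]] <- df[[nm]] > 0.5
  }
  df$.y <- ft$y
  df$.group <- ft$groups
  df
}

# reference levels follow the published convention: male talker, lowest F0,
# left side
.set_references <- function(df) {
  for (nm in c("talker", "side", "target_f0", "trial_f0")) {
    if (nm %in% names(df) && is.factor(df[[nm]])) {
      ref <- switch(nm, talker = "male", side = "left",
                    sort(levels(df[[nm]]))[1])
      if (ref %in% levels(df[[nm]])) df[[nm]] <- stats::relevel(df[[nm]], ref)
    }
  }
  df
}

.check_convergence <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  bad <- grepl("failed to converge", msgs, ignore.case = TRUE)
  if (any(bad))
    stop("convergence error: ", paste(msgs[bad], collapse = "; "))
  invisible(TRUE)
}

#' Mixed-effects baseline on a boosted-model feature table
#'
#' Fits the traditional counterpart of a boosted model on the *same*
#' feature table: a binomial GLMM (logit link) for trial outcomes or a
#' Gaussian LMM (identity link) for reaction times, with a per-ferret
#' random intercept and the same 5-fold cross-validation. Held-out
#' predictions use the estimated intercepts of the (seen) groups.
#' Fixed-effect p-values are Wald z for the GLMM and Satterthwaite t for
#' the LMM.
#'
#' @param ft a `feature_table` from [build_features()] -- the identical
#'   object the booster consumes.
#' @param family `"binomial"` or `"gaussian"` (defaults to the label type).
#' @param n_folds cross-validation folds.
#' @param fold optional fold assignment (to share folds with a booster).
#' @param seed integer seed for fold assignment.
#' @return an object of class `baseline_report`: fixed-effect coefficient
#'   table, random-intercept variance, CV metrics, reference levels, and
#'   the full-data fit.
#' @export
fit_glmm_outcome <- function(ft, family = NULL, n_folds = 5, fold = NULL,
                             seed = 1) {
  df <- .set_references(.as_model_frame(ft))
  if (is.null(family))
    family <- if (all(ft$y %in% c(0, 1))) "binomial" else "gaussian"
  if (is.null(df$.group)) stop("group column (ferret) is required")
  preds <- setdiff(names(df), c(".y", ".group", "ferret_id"))
  fml <- stats::as.formula(paste(".y ~", paste(preds, collapse = " + "),
                                 "+ (1 | .group)"))
  fit_one <- function(d) {
    if (family == "binomial")
      lme4::glmer(fml, d, family = stats::binomial("logit"),
                  control = lme4::glmerControl(calc.derivs = FALSE))
    else
      lmerTest::lmer(fml, d, REML = TRUE)
  }
  full <- suppressMessages(fit_one(df))
  .check_convergence(full)
  co <- as.data.frame(stats::coef(summary(full)))
  names(co)[1:2] <- c("estimate", "se")
  co$p_value <- co[[ncol(co)]]
  co <- data.frame(term = rownames(co), co[c("estimate", "se", "p_value")],
                   row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(full))
  ranef_var <- vc$vcov[vc$grp == ".group"][1]

  set.seed(seed)
  if (is.null(fold))
    fold <- .make_folds(ft$y, n_folds, stratify = family == "binomial")
  rows <- lapply(seq_len(n_folds), function(k) {
    d_tr <- df[fold != k, , drop = FALSE]
    d_te <- df[fold == k, , drop = FALSE]
    m <- suppressMessages(fit_one(d_tr))
    p_tr <- stats::predict(m, d_tr, type = "response",
                           allow.new.levels = TRUE)
    p_te <- stats::predict(m, d_te, type = "response",
                           allow.new.levels = TRUE)
    if (family == "binomial")
      data.frame(fold = k,
                 train_accuracy = mean((p_tr > 0.5) == d_tr$.y),
                 test_accuracy = mean((p_te > 0.5) == d_te$.y),
                 train_balanced_accuracy =
                   balanced_accuracy(d_tr$.y, as.numeric(p_tr > 0.5)),
                 test_balanced_accuracy =
                   balanced_accuracy(d_te$.y, as.numeric(p_te > 0.5)))
    else
      data.frame(fold = k, train_mse = mean((p_tr - d_tr$.y)^2),
                 test_mse = mean((p_te - d_te$.y)^2))
  })
  metrics <- do.call(rbind, rows)
  refs <- vapply(df[setdiff(preds, ".group")], function(v)
    if (is.factor(v)) levels(v)[1] else NA_character_, "")
  structure(list(coefficients = co, ranef_var = ranef_var,
                 metrics = metrics, means = as.list(colMeans(metrics[-1])),
                 family = family, references = refs[!is.na(refs)],
                 fold = fold, fit = full),
            class = "baseline_report")
}

#' @export
print.baseline_report <- function(x, ...) {
  cat(sprintf("baseline_report (%s): %d fixed effects, ranef var %.4f\n",
              x$family, nrow(x$coefficients), x$ranef_var))
  for (nm in names(x$means))
    cat(sprintf("  mean %s = %.4f\n", nm, x$means[[nm]]))
  invisible(x)
}

#' Ordinary least squares on the word-timing matrix
#'
#' The linear counterpart of the boosted release-time model. Linear models
#' cannot consume missing values natively, so absent-word cells are imputed
#' to a constant beyond any trial duration and paired with per-word absence
#' indicator columns. Words absent from every trial are dropped with a
#' warning, as are columns eliminated by rank deficiency.
#'
#' @param ft a word-timing `feature_table` from
#'   [build_word_timing_matrix()].
#' @param n_folds cross-validation folds.
#' @param fold optional fold assignment shared with the booster.
#' @param impute_value onset value standing in for "absent" (s).
#' @param seed integer seed.
#' @return a `baseline_report` with per-word coefficients and CV MSE.
#' @export
fit_ols_response_time <- function(ft, n_folds = 5, fold = NULL,
                                  impute_value = 20, seed = 1) {
  x <- ft$x; y <- ft$y
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning("all-sentinel columns dropped: ",
            paste(colnames(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  absent <- is.na(x)
  xi <- x
  xi[absent] <- impute_value
  ind <- absent[, colSums(absent) > 0, drop = FALSE] * 1
  if (ncol(ind))
    colnames(ind) <- paste0(colnames(absent)[colSums(absent) > 0], "_absent")
  design <- cbind(xi, ind)
  df <- data.frame(.y = y, design, check.names = FALSE)

  set.seed(seed)
  if (is.null(fold)) fold <- .make_folds(y, n_folds, stratify = FALSE)
  full <- stats::lm(.y ~ ., df)
  dropped <- names(which(is.na(stats::coef(full))))
  if (length(dropped))
    warning("rank-deficient design; dropped: ",
            paste(dropped, collapse = ", "))
  co <- as.data.frame(stats::coef(summary(full)))
  co <- data.frame(term = rownames(co), estimate = co[[1]], se = co[[2]],
                   p_value = co[[4]], row.names = NULL)
  rows <- lapply(seq_len(n_folds), function(k) {
    m <- stats::lm(.y ~ ., df[fold != k, , drop = FALSE])
    p_tr <- suppressWarnings(stats::predict(m, df[fold != k, , drop = FALSE]))
    p_te <- suppressWarnings(stats::predict(m, df[fold == k, , drop = FALSE]))
    data.frame(fold = k, train_mse = mean((p_tr - y[fold != k])^2),
               test_mse = mean((p_te - y[fold == k])^2))
  })
  metrics <- do.call(rbind, rows)
  structure(list(coefficients = co, ranef_var = NA_real_,
                 metrics = metrics, means = as.list(colMeans(metrics[-1])),
                 family = "gaussian-ols", references = character(0),
                 fold = fold, fit = full),
            class = "baseline_report")
}
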