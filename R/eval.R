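#' SVM tuning configuration
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost Positive regularization constant C (upper bound on the dual
#'   coefficients; larger values penalize margin violations more).
#' @param gamma Positive RBF width in `K(x, x') = exp(-gamma * ||x - x'||^2)`;
#'   ignored for the linear kernel. Defaults follow the settings used for the
#'   StepSVM runs (RBF, C = 10, gamma = 1).
#' @return A list of class `"tuning_config"`.
#' @export
tuning_config <- function(kernel = c("rbf", "linear"), cost = 10, gamma = 1) {
  kernel <- match.arg(kernel)
  if (!is.numeric(cost) || cost <= 0) stop_config("cost must be > 0")
  if (kernel == "rbf" && (!is.numeric(gamma) || gamma <= 0)) {
    stop_config("gamma must be > 0 for the rbf kernel")
  }
  structure(list(kernel = kernel, cost = cost, gamma = gamma),
            class = "tuning_config")
}

#' Evaluation protocol: train/test split and cross-validation folds
#'
#' @param test_fraction Fraction of rows held out for testing (default 0.2);
#'   0 disables the held-out split.
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling the split and fold assignment.
#' @param stratified Stratify split and folds by outcome (default `TRUE`).
#' @return A list of class `"eval_protocol"`.
#' @export
eval_protocol <- function(test_fraction = 0.2, n_folds = 10, seed = 1L,
                          stratified = TRUE) {
  if (test_fraction < 0 || test_fraction >= 1) {
    stop_config("test_fraction must be in [0, 1)")
  }
  if (!is_count(n_folds) || n_folds < 2) stop_config("n_folds must be >= 2")
  structure(list(test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "eval_protocol")
}

#' Confusion counts and classification accuracy
#'
#' `accuracy()` implements `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn Nonnegative counts of true positives, true negatives,
#'   false positives and false negatives.
#' @return `confusion_counts()` returns a named numeric vector of class
#'   `"confusion_counts"`; `accuracy()` a proportion in `[0, 1]`.
#' @examples
#' accuracy(confusion_counts(tp = 3, tn = 4, fp = 2, fn = 1)) # 0.7
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  x <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(x < 0)) stop_config("confusion counts must be nonnegative")
  structure(x, class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param counts A `confusion_counts` object (or named vector with elements
#'   `tp`, `tn`, `fp`, `fn`).
#' @export
accuracy <- function(counts) {
  total <- sum(counts[c("tp", "tn", "fp", "fn")])
  if (!is.finite(total) || total == 0) {
    stop_config("accuracy is undefined for zero evaluated subjects")
  }
  unname((counts[["tp"]] + counts[["tn"]]) / total)
}

classification_metric <- function(pred, truth,
                                  criterion = c("accuracy", "sensitivity",
                                                "specificity")) {
  criterion <- match.arg(criterion)
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  switch(criterion,
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
         specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

#' Concordance statistic (C-statistic / AUC)
#'
#' The probability that a randomly chosen positive subject receives a
#' higher score than a randomly chosen negative subject, with ties counted
#' one half — the normalized Mann-Whitney U statistic, computed via
#' midranks.
#'
#' @param scores Numeric model scores (any rank-equivalent of the fitted
#'   probability, e.g. the linear predictor).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return A proportion in `[0, 1]`.
#' @examples
#' c_statistic(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
c_statistic <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_config("c_statistic is undefined unless both classes are present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- feature encoding ------------------------------------------------------

get_meta <- function(data, variables = NULL) {
  meta <- attr(data, "variable_meta")
  outcome <- attr(data, "outcome") %||% "remission"
  if (is.null(meta)) {
    meta <- infer_meta(data, setdiff(names(data), c("ID", outcome)))
  }
  if (!is.null(variables)) {
    missing_v <- setdiff(variables, meta$name)
    if (length(missing_v)) {
      stop_config("unknown variables: ", paste(missing_v, collapse = ", "))
    }
    meta <- meta[match(variables, meta$name), , drop = FALSE]
  }
  meta
}

# Expand a set of variables into a numeric design matrix. Categorical and
# cluster-id variables are one-hot encoded over the levels observed in
# `data`; every other kind contributes its single numeric column.
# `scale_col` flags the columns to be standardized with training statistics.
encode_features <- function(data, meta) {
  cols <- list(); scale_col <- logical(0); var_of_col <- character(0)
  for (i in seq_len(nrow(meta))) {
    v <- meta$name[i]; kind <- meta$kind[i]
    col <- data[[v]]
    if (kind %in% c("categorical", "cluster-id")) {
      lev <- sort(unique(col))
      for (l in lev) {
        cols[[paste0(v, ".", l)]] <- as.numeric(col == l)
        scale_col <- c(scale_col, FALSE)
        var_of_col <- c(var_of_col, v)
      }
    } else {
      cols[[v]] <- as.numeric(col)
      scale_col <- c(scale_col, kind %in% c("continuous", "ordinal"))
      var_of_col <- c(var_of_col, v)
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, scale_col = scale_col, var_of_col = var_of_col)
}

# Standardize flagged columns by training-row statistics (sd 0 -> 1).
scale_by_train <- function(Xtr, Xte, scale_col) {
  if (any(scale_col)) {
    mu <- colMeans(Xtr[, scale_col, drop = FALSE])
    sd <- apply(Xtr[, scale_col, drop = FALSE], 2, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    Xtr[, scale_col] <- sweep(sweep(Xtr[, scale_col, drop = FALSE], 2, mu),
                              2, sd, "/")
    if (!is.null(Xte)) {
      Xte[, scale_col] <- sweep(sweep(Xte[, scale_col, drop = FALSE], 2, mu),
                                2, sd, "/")
    }
  }
  list(train = Xtr, test = Xte)
}

fit_svm <- function(X, y, tuning) {
  e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
             kernel = if (tuning$kernel == "rbf") "radial" else "linear",
             cost = tuning$cost, gamma = tuning$gamma, scale = FALSE)
}

# ---- folds and cross-validation -------------------------------------------

# Fold ids for rows of `y` (assumed in canonical order), stratified by class
# when requested.
make_folds <- function(y, n_folds, seed, stratified = TRUE) {
  n <- length(y)
  if (n < n_folds) stop_config("fewer rows than folds")
  folds <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(n_folds), n))
    }
  })
  folds
}

# Core CV loop over a pre-encoded design matrix.
cv_over_folds <- function(X, y, folds, tuning, scale_col,
                          criterion = "accuracy") {
  vals <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L) {
      stop_config("a training fold contains a single outcome class; ",
                  "use a stratified protocol")
    }
    sc <- scale_by_train(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                         scale_col)
    fit <- fit_svm(sc$train, ytr, tuning)
    pred <- as.integer(as.character(stats::predict(fit, sc$test)))
    classification_metric(pred, y[!tr], criterion)
  }, numeric(1))
  mean(vals)
}

# Shared evaluation context: canonical ordering, full encoding, fold ids.
# Built once per dataset and reused across the many candidate subsets a
# selection run scores, so that every candidate is judged on identical folds.
build_eval_context <- function(data, protocol, variables = NULL,
                               outcome = NULL) {
  outcome <- outcome %||% attr(data, "outcome") %||% "remission"
  meta <- get_meta(data, variables)
  df <- as.data.frame(data)
  y <- df[[outcome]]
  if (is.null(y)) stop_config("outcome column '", outcome, "' not found")
  if (length(unique(y)) < 2L) {
    stop_config("both outcome classes must be present")
  }
  ord <- canonical_order(df[, c(meta$name, outcome), drop = FALSE])
  df <- df[ord, , drop = FALSE]
  y <- y[ord]
  enc <- encode_features(df, meta)
  folds <- make_folds(y, protocol$n_folds, protocol$seed, protocol$stratified)
  list(meta = meta, y = y, X = enc$X, scale_col = enc$scale_col,
       var_of_col = enc$var_of_col, folds = folds, outcome = outcome)
}

cv_subset <- function(ctx, features, tuning, criterion = "accuracy") {
  keep <- ctx$var_of_col %in% features
  cv_over_folds(ctx$X[, keep, drop = FALSE], ctx$y, ctx$folds, tuning,
                ctx$scale_col[keep], criterion)
}

#' Cross-validated SVM accuracy of a feature subset
#'
#' Fits the delegated SVM solver on each training fold (features one-hot
#' encoded where categorical, continuous features standardized with
#' training-fold statistics) and returns the mean fold metric. Folds are
#' stratified by outcome, seeded, and keyed on a canonical row ordering so
#' the value does not depend on the incoming row order.
#'
#' @param data Dataset (data frame; outcome column taken from the
#'   `"outcome"` attribute, default `"remission"`).
#' @param features Nonempty character vector of predictor names.
#' @param tuning A [tuning_config()].
#' @param protocol An [eval_protocol()].
#' @param criterion Fold metric: `"accuracy"` (default), `"sensitivity"` or
#'   `"specificity"`.
#' @return Mean fold metric, a proportion in `[0, 1]`.
#' @export
cv_accuracy <- function(data, features, tuning = tuning_config(),
                        protocol = eval_protocol(),
                        criterion = "accuracy") {
  if (length(features) == 0) stop_config("features must be nonempty")
  ctx <- build_eval_context(data, protocol)
  cv_subset(ctx, features, tuning, criterion)
}

#' Canonical hyperparameter grid
#'
#' Grids are enumerated in a documented canonical order — linear before RBF,
#' then ascending cost, then ascending gamma — which is also the tie-break
#' order used by [tune_svm()].
#'
#' @param kernels,costs,gammas Values to cross.
#' @return A list of [tuning_config()] objects.
#' @export
svm_grid <- function(kernels = c("linear", "rbf"), costs = c(0.1, 1, 10),
                     gammas = 1) {
  grid <- list()
  for (k in kernels[order(match(kernels, c("linear", "rbf")))]) {
    for (C in sort(costs)) {
      if (k == "linear") {
        grid[[length(grid) + 1L]] <- tuning_config("linear", C)
      } else {
        for (g in sort(gammas)) {
          grid[[length(grid) + 1L]] <- tuning_config("rbf", C, g)
        }
      }
    }
  }
  grid
}

#' Select SVM hyperparameters by cross-validation
#'
#' Returns the grid point minimizing the cross-validated mean squared error
#' of the 0/1 predictions. For binary labels and hard predictions the MSE
#' equals the misclassification rate, so this is equivalent to maximizing
#' [cv_accuracy()]. Ties are broken by grid order (first minimum wins).
#'
#' @inheritParams cv_accuracy
#' @param grid Nonempty list of [tuning_config()] objects, e.g. from
#'   [svm_grid()].
#' @return The selected [tuning_config()], with attributes `"cv_mse"` and
#'   `"cv_accuracy"`.
#' @export
tune_svm <- function(data, features, grid, protocol = eval_protocol()) {
  if (length(grid) == 0) stop_config("tuning grid must be nonempty")
  ctx <- build_eval_context(data, protocol)
  acc <- vapply(grid, function(tc) cv_subset(ctx, features, tc), numeric(1))
  mse <- 1 - acc
  best <- which.min(mse)   # first minimum: canonical tie-break
  out <- grid[[best]]
  attr(out, "cv_mse") <- mse[best]
  attr(out, "cv_accuracy") <- acc[best]
  out
}

# Subset a dataset preserving its metadata attributes.
subset_rows <- function(data, idx) {
  out <- as.data.frame(data)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "variable_meta") <- attr(data, "variable_meta")
  attr(out, "outcome") <- attr(data, "outcome")
  class(out) <- class(data)
  out
}

#' Stratified train/test split
#'
#' Splits the rows into disjoint, exhaustive train and test parts,
#' stratified by outcome, with the overall test size equal to
#' `round(n * test_fraction)` (per-class sizes by largest remainder).
#'
#' @inheritParams cv_accuracy
#' @return A list with elements `train`, `test` (datasets) and `train_idx`,
#'   `test_idx` (row indices into `data`).
#' @export
split_train_test <- function(data, protocol = eval_protocol()) {
  outcome <- attr(data, "outcome") %||% "remission"
  y <- as.data.frame(data)[[outcome]]
  n <- length(y)
  k <- round(n * protocol$test_fraction)
  if (k < 1 || k >= n) stop_config("test_fraction yields an empty part")
  classes <- sort(unique(y))
  if (protocol$stratified && length(classes) == 2L) {
    n_cl <- table(factor(y, levels = classes))
    exact <- k * as.numeric(n_cl) / n
    base <- floor(exact)
    rem <- k - sum(base)
    if (rem > 0) {
      add <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
      base[add] <- base[add] + 1
    }
    test_idx <- integer(0)
    with_seed(protocol$seed, {
      for (i in seq_along(classes)) {
        idx <- which(y == classes[i])
        test_idx <- c(test_idx, sample(idx, base[i]))
      }
    })
  } else {
    test_idx <- with_seed(protocol$seed, sample.int(n, k))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  train <- subset_rows(data, train_idx)
  test <- subset_rows(data, test_idx)
  if (length(unique(train[[outcome]])) < 2L ||
      length(unique(test[[outcome]])) < 2L) {
    stop_config("split left a part with a single outcome class; ",
                "increase n or adjust test_fraction")
  }
  list(train = train, test = test, train_idx = train_idx, test_idx = test_idx)
}
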