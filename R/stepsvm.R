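#' Candidate-model counts of the stepwise SVM search
#'
#' `count_stage_candidates()` gives the number of candidate models scored at
#' one stage of the forward search over `m` candidate predictors: the first
#' stage evaluates all unordered pairs, `choose(m, 2)`; each later stage `s`
#' evaluates the `m - s` variables not yet selected. With `m = 26` the
#' stages evaluate 325, 24, 23 and 22 candidates.
#'
#' `count_total_models()` gives the total number of model fits each strategy
#' needs for a full (uncapped) run: `choose(m, 2) + (m - 2) * (m - 1) / 2`
#' for the stepwise SVM, `m * (m + 1) / 2` for stepwise logistic regression,
#' and `m` for SVM-RFE.
#'
#' @param m Number of candidate predictors (>= 2).
#' @param stage Stage index: 1 selects the initial pair, stage `s >= 2`
#'   selects variable `s + 1`.
#' @return An integer count.
#' @examples
#' count_stage_candidates(26, 1) # 325
#' count_total_models(26, "svm_rfe") # 26
#' @export
count_stage_candidates <- function(m, stage) {
  if (!is_count(m) || m < 2) stop_config("m must be an integer >= 2")
  if (!is_count(stage) || stage < 1) stop_config("stage must be >= 1")
  if (stage > m - 1) {
    stop_config("stage ", stage, " exceeds the available variables (m = ", m, ")")
  }
  if (stage == 1) choose(m, 2) else m - stage
}

#' @rdname count_stage_candidates
#' @param method One of `"stepsvm"`, `"stepwise_logistic"`, `"svm_rfe"`.
#' @export
count_total_models <- function(m, method = c("stepsvm", "stepwise_logistic",
                                             "svm_rfe")) {
  method <- match.arg(method)
  if (!is_count(m) || m < 2) stop_config("m must be an integer >= 2")
  switch(method,
         stepsvm = choose(m, 2) + (m - 2) * (m - 1) / 2,
         stepwise_logistic = m * (m + 1) / 2,
         svm_rfe = m)
}

# Candidate variable pool: roster order of `variables` (or all predictors).
candidate_pool <- function(data, variables = NULL, outcome = NULL) {
  outcome <- outcome %||% attr(data, "outcome") %||% "remission"
  meta <- get_meta(data, variables)
  setdiff(meta$name, outcome)
}

#' Exhaustive best-pair initialization
#'
#' Scores all `choose(m, 2)` unordered variable pairs by cross-validated SVM
#' accuracy (or sensitivity/specificity) and returns the best one. Pairs are
#' enumerated in canonical roster order, and a strictly-greater comparison
#' is used, so ties resolve to the earliest pair in that order.
#'
#' @inheritParams cv_accuracy
#' @param variables Candidate predictors (default: all roster predictors).
#' @return A list with `pair` (character 2-vector), `value` (criterion of
#'   the chosen pair), `n_evaluated` (number of candidate models scored) and
#'   `scores` (data frame of every pair's criterion).
#' @export
select_best_pair <- function(data, variables = NULL,
                             tuning = tuning_config(),
                             protocol = eval_protocol(),
                             criterion = "accuracy") {
  vars <- candidate_pool(data, variables)
  if (length(vars) < 2) stop_config("need at least 2 candidate variables")
  ctx <- build_eval_context(data, protocol, variables = vars)
  best_pair_ctx(ctx, vars, tuning, criterion)
}

best_pair_ctx <- function(ctx, vars, tuning, criterion) {
  m <- length(vars)
  pairs <- utils::combn(m, 2)
  scores <- numeric(ncol(pairs))
  best <- -Inf; best_pair <- NULL
  for (j in seq_len(ncol(pairs))) {
    p <- vars[pairs[, j]]
    scores[j] <- cv_subset(ctx, p, tuning, criterion)
    if (scores[j] > best) {        # strict: earliest canonical pair wins ties
      best <- scores[j]; best_pair <- p
    }
  }
  list(pair = best_pair, value = best, n_evaluated = ncol(pairs),
       scores = data.frame(var1 = vars[pairs[1, ]], var2 = vars[pairs[2, ]],
                           value = scores, stringsAsFactors = FALSE))
}

#' One forward-selection step
#'
#' Scores every not-yet-selected variable appended to the current set and
#' returns the best addition, or no addition when the best candidate does
#' not strictly improve on `current_value` (the stopping rule).
#'
#' @inheritParams select_best_pair
#' @param current Character vector of already-selected variables.
#' @param current_value Criterion value of the current set; `-Inf` accepts
#'   any candidate.
#' @return A list with `variable` (the addition, or `NA` if none improves),
#'   `value`, `improved` (logical), `n_evaluated` and `scores`.
#' @export
forward_step <- function(data, current, current_value = -Inf,
                         variables = NULL, tuning = tuning_config(),
                         protocol = eval_protocol(), criterion = "accuracy") {
  vars <- candidate_pool(data, variables)
  if (length(current) == 0) stop_config("current must be nonempty")
  ctx <- build_eval_context(data, protocol, variables = vars)
  forward_step_ctx(ctx, vars, current, current_value, tuning, criterion)
}

forward_step_ctx <- function(ctx, vars, current, current_value, tuning,
                             criterion) {
  remaining <- setdiff(vars, current)   # roster order preserved
  if (length(remaining) == 0) {
    return(list(variable = NA_character_, value = current_value,
                improved = FALSE, n_evaluated = 0L, scores = NULL,
                exhausted = TRUE))
  }
  scores <- vapply(remaining, function(v) {
    cv_subset(ctx, c(current, v), tuning, criterion)
  }, numeric(1))
  best <- which.max(scores)             # first maximum: canonical tie-break
  improved <- scores[best] > current_value
  list(variable = if (improved) remaining[best] else NA_character_,
       value = if (improved) unname(scores[best]) else current_value,
       improved = improved, n_evaluated = length(remaining),
       scores = data.frame(variable = remaining, value = unname(scores),
                           stringsAsFactors = FALSE),
       exhausted = FALSE)
}

#' Stepwise support vector machine model selection
#'
#' Forward model selection driven by cross-validated SVM performance: all
#' variable pairs are scored exhaustively, the best pair is kept, then one
#' variable is added at a time (each remaining variable scored in turn)
#' while the criterion strictly increases, up to `max_size` variables.
#' Selection is performed on the training portion of a stratified
#' `1 - test_fraction` / `test_fraction` split; the final model is refitted
#' on the whole training portion and also evaluated on the held-out rows.
#'
#' @param x A dataset: the formula method takes `outcome ~ predictors`
#'   (`.` expands to all predictors); the data frame method selects among
#'   all roster predictors by default.
#' @param ... Passed between methods.
#' @param data Data frame for the formula method (attributes
#'   `"variable_meta"`/`"outcome"` honoured, see [generate_hierarchy()]).
#' @param outcome Outcome column name (default from the dataset attribute,
#'   falling back to `"remission"`); must be binary 0/1.
#' @param variables Candidate predictors; default all roster predictors.
#' @param max_size Maximum number of selected variables (default 5).
#' @param tuning [tuning_config()]; default RBF kernel with C = 10,
#'   gamma = 1. With `retune = TRUE` the hyperparameters are re-selected by
#'   [tune_svm()] over `tuning_grid` before the search instead.
#' @param protocol [eval_protocol()]; the criterion is 10-fold CV on the
#'   training portion by default.
#' @param criterion `"accuracy"` (default), `"sensitivity"` or
#'   `"specificity"`.
#' @param retune Re-tune hyperparameters on the training data before the
#'   search (default `FALSE`: fixed settings are used throughout, as in the
#'   reference protocol).
#' @param tuning_grid Grid for `retune = TRUE`; default [svm_grid()].
#' @return An object of class `"stepsvm"`: a list with `selected` (ordered
#'   variables), `steps` (per-stage data frame: variables added, criterion
#'   value, candidates evaluated), `stopped_reason` (`"no_improvement"`,
#'   `"max_size"` or `"exhausted"`), `cv_value` (criterion of the final
#'   set), `test_accuracy` and `test_confusion` (held-out evaluation, `NA`
#'   if `test_fraction = 0`), `n_evaluated` (total candidate models scored),
#'   the fitted final SVM and the tuning/protocol used. Methods: `print`,
#'   `summary`, `plot`, `predict`.
#' @examples
#' d <- generate_hierarchy(hierarchy_config(n_hospitals = 5,
#'                                          doctors_per_hospital = c(2, 3),
#'                                          patients_per_doctor = c(8, 15),
#'                                          seed = 7),
#'                         default_effects())
#' fit <- stepsvm(d, variables = c("CancerStage", "mobility", "FamilyHx",
#'                                 "Age", "BMI"),
#'                max_size = 3, protocol = eval_protocol(n_folds = 5, seed = 7))
#' print(fit)
#' @export
stepsvm <- function(x, ...) UseMethod("stepsvm")

#' @rdname stepsvm
#' @export
stepsvm.formula <- function(x, data, ...) {
  mf <- stats::terms(x, data = data)
  outcome <- as.character(attr(mf, "variables"))[2]
  vars <- attr(mf, "term.labels")
  stepsvm.data.frame(data, outcome = outcome, variables = vars, ...)
}

#' @rdname stepsvm
#' @export
stepsvm.data.frame <- function(x, outcome = NULL, variables = NULL,
                               max_size = 5, tuning = tuning_config(),
                               protocol = eval_protocol(),
                               criterion = "accuracy", retune = FALSE,
                               tuning_grid = svm_grid(), ...) {
  if (!is_count(max_size) || max_size < 2) stop_config("max_size must be >= 2")
  outcome <- outcome %||% attr(x, "outcome") %||% "remission"
  attr(x, "outcome") <- outcome
  vars <- candidate_pool(x, variables, outcome)
  if (length(vars) < 2) stop_config("need at least 2 candidate variables")

  if (protocol$test_fraction > 0) {
    sp <- split_train_test(x, protocol)
    train <- sp$train; test <- sp$test
  } else {
    train <- x; test <- NULL
  }
  if (retune) tuning <- tune_svm(train, vars, tuning_grid, protocol)

  ctx <- build_eval_context(train, protocol, variables = vars,
                            outcome = outcome)
  first <- best_pair_ctx(ctx, vars, tuning, criterion)
  selected <- first$pair
  value <- first$value
  steps <- data.frame(step = 1L, added = paste(first$pair, collapse = "+"),
                      value = value, n_candidates = first$n_evaluated,
                      stringsAsFactors = FALSE)
  stopped <- "max_size"
  while (length(selected) < max_size) {
    st <- forward_step_ctx(ctx, vars, selected, value, tuning, criterion)
    if (isTRUE(st$exhausted)) { stopped <- "exhausted"; break }
    steps <- rbind(steps, data.frame(
      step = nrow(steps) + 1L,
      added = if (st$improved) st$variable else NA_character_,
      value = st$value, n_candidates = st$n_evaluated,
      stringsAsFactors = FALSE))
    if (!st$improved) { stopped <- "no_improvement"; break }
    selected <- c(selected, st$variable)
    value <- st$value
  }

  # refit on the full training portion, evaluate on the held-out rows
  meta_sel <- get_meta(train, selected)
  enc <- encode_features(as.data.frame(train), meta_sel)
  sc <- scale_by_train(enc$X, NULL, enc$scale_col)
  final_fit <- fit_svm(sc$train, as.data.frame(train)[[outcome]], tuning)
  encoder <- list(meta = meta_sel, train_data = as.data.frame(train),
                  scale_col = enc$scale_col)

  test_accuracy <- NA_real_; test_confusion <- NULL
  if (!is.null(test)) {
    pred <- predict_encoded(final_fit, encoder, as.data.frame(test))
    truth <- as.data.frame(test)[[outcome]]
    test_confusion <- confusion_counts(
      tp = sum(pred == 1 & truth == 1), tn = sum(pred == 0 & truth == 0),
      fp = sum(pred == 1 & truth == 0), fn = sum(pred == 0 & truth == 1))
    test_accuracy <- accuracy(test_confusion)
  }

  structure(list(
    selected = selected, steps = steps, stopped_reason = stopped,
    cv_value = value, criterion = criterion,
    test_accuracy = test_accuracy, test_confusion = test_confusion,
    n_evaluated = sum(steps$n_candidates),
    tuning = tuning, protocol = protocol, outcome = outcome,
    candidates = vars, fit = final_fit, encoder = encoder,
    n_train = nrow(train), n_test = if (is.null(test)) 0L else nrow(test)),
    class = "stepsvm")
}

# Encode new data with the training-data level set and scaling and predict
# 0/1 labels.
predict_encoded <- function(fit, encoder, newdata) {
  enc_tr <- encode_features(encoder$train_data, encoder$meta)
  enc_new <- encode_features_as(newdata, encoder$meta, colnames(enc_tr$X))
  sc <- scale_by_train(enc_tr$X, enc_new, enc_tr$scale_col)
  as.integer(as.character(stats::predict(fit, sc$test)))
}

# Encode `newdata` onto a fixed training column layout; unseen categorical
# levels map to all-zero dummy blocks.
encode_features_as <- function(newdata, meta, template_cols) {
  X <- matrix(0, nrow(newdata), length(template_cols),
              dimnames = list(NULL, template_cols))
  for (i in seq_len(nrow(meta))) {
    v <- meta$name[i]; kind <- meta$kind[i]
    col <- newdata[[v]]
    if (kind %in% c("categorical", "cluster-id")) {
      pref <- paste0(v, ".")
      for (cn in template_cols[startsWith(template_cols, pref)]) {
        lev <- substring(cn, nchar(pref) + 1)
        X[, cn] <- as.numeric(as.character(col) == lev)
      }
    } else {
      X[, v] <- as.numeric(col)
    }
  }
  X
}

#' @export
print.stepsvm <- function(x, ...) {
  cat("Stepwise SVM selection (", x$tuning$kernel, " kernel, C = ",
      x$tuning$cost,
      if (x$tuning$kernel == "rbf") paste0(", gamma = ", x$tuning$gamma),
      ")\n", sep = "")
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("CV %s of final set: %.4f (stopped: %s)\n",
              x$criterion, x$cv_value, x$stopped_reason))
  if (!is.na(x$test_accuracy)) {
    cat(sprintf("Held-out test accuracy: %.4f (n_test = %d)\n",
                x$test_accuracy, x$n_test))
  }
  invisible(x)
}

#' @export
summary.stepsvm <- function(object, ...) {
  print(object)
  cat("\nSelection path (", object$n_evaluated,
      " candidate models evaluated):\n", sep = "")
  print(object$steps, row.names = FALSE)
  invisible(object)
}

#' @export
predict.stepsvm <- function(object, newdata, ...) {
  predict_encoded(object$fit, object$encoder, as.data.frame(newdata))
}

#' @export
plot.stepsvm <- function(x, ...) {
  ok <- !is.na(x$steps$added)
  graphics::plot(x$steps$step[ok], x$steps$value[ok], type = "b", pch = 19,
                 xlab = "selection step", ylab = paste("CV", x$criterion),
                 main = "StepSVM selection trajectory", ...)
  graphics::text(x$steps$step[ok], x$steps$value[ok],
                 labels = x$steps$added[ok], pos = 1, cex = 0.7)
  invisible(x)
}
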