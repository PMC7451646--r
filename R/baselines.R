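#' SVM recursive feature elimination
#'
#' Backward elimination with a linear-kernel SVM: at each iteration the SVM
#' is refitted on the surviving variables, each variable is scored by the
#' squared weight of its encoded column(s) in the fitted weight vector
#' (summed over a categorical variable's one-hot block), and the
#' lowest-scoring variable is removed, until none remain. The selected
#' variables are the `k` eliminated last, reported most-important-first.
#' Elimination is run on the training portion of the protocol's split; the
#' top-`k` model is then refitted and evaluated by cross-validation on the
#' training portion and by accuracy on the held-out rows, matching the
#' protocol used for [stepsvm()].
#'
#' @inheritParams stepsvm.data.frame
#' @param data Dataset (data frame with metadata attributes, or plain data
#'   frame with a `remission` column).
#' @param k Number of variables to select (default 5).
#' @param tuning [tuning_config()] with `kernel = "linear"` (the weight
#'   vector is undefined for the RBF kernel); default C = 0.1.
#' @return An object of class `"svm_rfe"`: `elimination_order` (first
#'   eliminated first), `selected` (top-`k`, most important first),
#'   `ranking_scores` (squared-weight score at each variable's elimination),
#'   `cv_accuracy` and `test_accuracy` of the refitted top-`k` model.
#' @export
svm_rfe <- function(data, k = 5, tuning = tuning_config("linear", cost = 0.1),
                    protocol = eval_protocol(), outcome = NULL,
                    variables = NULL) {
  if (tuning$kernel != "linear") {
    stop_config("svm_rfe requires the linear kernel: ",
                "the ranking weight vector is undefined otherwise")
  }
  outcome <- outcome %||% attr(data, "outcome") %||% "remission"
  attr(data, "outcome") <- outcome
  vars <- candidate_pool(data, variables, outcome)
  if (!is_count(k) || k < 1 || k > length(vars)) {
    stop_config("k must be between 1 and the number of candidate variables")
  }

  if (protocol$test_fraction > 0) {
    sp <- split_train_test(data, protocol)
    train <- sp$train; test <- sp$test
  } else {
    train <- data; test <- NULL
  }

  df <- as.data.frame(train)
  y <- df[[outcome]]
  meta <- get_meta(train, vars)
  surviving <- vars
  eliminated <- character(0)
  elim_scores <- numeric(0)
  while (length(surviving) > 0) {
    if (length(surviving) == 1L) {
      eliminated <- c(eliminated, surviving)
      elim_scores <- c(elim_scores, NA_real_)
      break
    }
    enc <- encode_features(df, meta[match(surviving, meta$name), ,
                                    drop = FALSE])
    sc <- scale_by_train(enc$X, NULL, enc$scale_col)
    fit <- fit_svm(sc$train, y, tuning)
    w <- crossprod(fit$coefs, fit$SV)[1, ]           # weight vector
    score <- vapply(surviving, function(v) {
      sum(w[enc$var_of_col == v]^2)
    }, numeric(1))
    # lowest score eliminated; ties resolved toward the later roster
    # variable so earlier-roster variables survive longer
    worst <- max(which(score == min(score)))
    eliminated <- c(eliminated, surviving[worst])
    elim_scores <- c(elim_scores, unname(score[worst]))
    surviving <- surviving[-worst]
  }

  selected <- rev(eliminated)[seq_len(k)]   # last eliminated first
  cv_acc <- cv_subset(build_eval_context(train, protocol, variables = vars,
                                         outcome = outcome),
                      selected, tuning)

  test_accuracy <- NA_real_
  if (!is.null(test)) {
    meta_sel <- meta[match(selected, meta$name), , drop = FALSE]
    enc <- encode_features(df, meta_sel)
    sc <- scale_by_train(enc$X, NULL, enc$scale_col)
    fit <- fit_svm(sc$train, y, tuning)
    encoder <- list(meta = meta_sel, train_data = df, scale_col = enc$scale_col)
    pred <- predict_encoded(fit, encoder, as.data.frame(test))
    truth <- as.data.frame(test)[[outcome]]
    test_accuracy <- mean(pred == truth)
  }

  structure(list(elimination_order = eliminated,
                 ranking_scores = elim_scores,
                 selected = selected, k = k,
                 cv_accuracy = cv_acc, test_accuracy = test_accuracy,
                 tuning = tuning, protocol = protocol,
                 candidates = vars, outcome = outcome),
            class = "svm_rfe")
}

#' @export
print.svm_rfe <- function(x, ...) {
  cat("SVM-RFE (linear kernel, C =", x$tuning$cost, ")\n")
  cat("Selected top", x$k, ":", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("CV accuracy of top-%d model: %.4f", x$k, x$cv_accuracy))
  if (!is.na(x$test_accuracy)) {
    cat(sprintf("; held-out test accuracy: %.4f", x$test_accuracy))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.svm_rfe <- function(object, ...) {
  print(object)
  cat("\nElimination order (first eliminated first):\n")
  print(data.frame(order = seq_along(object$elimination_order),
                   variable = object$elimination_order,
                   score_at_elimination = object$ranking_scores),
        row.names = FALSE)
  invisible(object)
}

#' Stepwise logistic regression scored by the C-statistic
#'
#' Conventional stepwise selection for a binary outcome: forward addition
#' with backward checks driven by AIC on ordinary (aggregate-data) logistic
#' regression fits, capped at `max_size` selected variables. Predictors
#' enter as single numeric columns (categorical and ordinal variables
#' through their integer codes, cluster identifiers through their arbitrary
#' integer labels), the conventional aggregate-data treatment. The final
#' model's concordance statistic is computed on the full data from the
#' linear predictor via [c_statistic()].
#'
#' @inheritParams svm_rfe
#' @param max_size Maximum number of selected variables (default 5).
#' @return An object of class `"step_logistic"`: `selected` (entry order of
#'   the surviving variables), `path` (data frame of add/drop actions and
#'   the AIC after each), `c_statistic`, and the final `glm` fit.
#' @export
stepwise_logistic <- function(data, max_size = 5, outcome = NULL,
                              variables = NULL) {
  if (!is_count(max_size) || max_size < 1) stop_config("max_size must be >= 1")
  outcome <- outcome %||% attr(data, "outcome") %||% "remission"
  vars <- candidate_pool(data, variables, outcome)
  df <- as.data.frame(data)[, c(vars, outcome)]
  y <- df[[outcome]]
  if (length(unique(y)) < 2L) stop_config("both classes must be present")

  fit_aic <- function(members) {
    f <- stats::as.formula(paste(
      outcome, "~", if (length(members)) paste(members, collapse = "+") else "1"))
    fit <- tryCatch(
      suppressWarnings(stats::glm(f, family = stats::binomial(), data = df)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(list(fit = NULL, aic = Inf))
    list(fit = fit, aic = stats::AIC(fit))
  }

  current <- character(0)
  cur <- fit_aic(current)
  path <- data.frame(action = "start", variable = NA_character_,
                     aic = cur$aic, stringsAsFactors = FALSE)
  repeat {
    best_aic <- cur$aic; best_action <- NULL
    if (length(current) < max_size) {
      for (v in setdiff(vars, current)) {
        cand <- fit_aic(c(current, v))
        if (is.infinite(cand$aic) && !is.null(cand$fit)) next
        if (is.infinite(cand$aic)) {
          warning("candidate fit failed for ", v, "; skipped", call. = FALSE)
          next
        }
        if (cand$aic < best_aic) {
          best_aic <- cand$aic
          best_action <- list(type = "add", var = v, res = cand)
        }
      }
    }
    for (v in current) {
      cand <- fit_aic(setdiff(current, v))
      if (cand$aic < best_aic) {
        best_aic <- cand$aic
        best_action <- list(type = "drop", var = v, res = cand)
      }
    }
    if (is.null(best_action)) break
    current <- if (best_action$type == "add") c(current, best_action$var)
               else setdiff(current, best_action$var)
    cur <- best_action$res
    path <- rbind(path, data.frame(action = best_action$type,
                                   variable = best_action$var,
                                   aic = best_aic, stringsAsFactors = FALSE))
  }

  cstat <- if (length(current)) {
    c_statistic(stats::predict(cur$fit, type = "link"), y)
  } else 0.5

  structure(list(selected = current, path = path, c_statistic = cstat,
                 fit = cur$fit, aic = cur$aic, outcome = outcome,
                 candidates = vars, max_size = max_size),
            class = "step_logistic")
}

#' @export
print.step_logistic <- function(x, ...) {
  cat("Stepwise logistic regression (AIC, forward with backward checks)\n")
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("Final AIC: %.2f; C-statistic: %.4f\n", x$aic, x$c_statistic))
  invisible(x)
}

#' @export
summary.step_logistic <- function(object, ...) {
  print(object)
  cat("\nPath:\n")
  print(object$path, row.names = FALSE)
  invisible(object)
}
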