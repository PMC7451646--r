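#' Run the three-strategy simulation benchmark
#'
#' For each repetition a fresh hierarchical dataset is generated under
#' derived per-repetition seeds, and four selectors are run on it:
#' [stepsvm()] (RBF kernel), [svm_rfe()] at each cost in `rfe_costs`, and
#' [stepwise_logistic()]. All selectors within a repetition see the same
#' dataset; the two SVM strategies share the same train/test split and fold
#' seed. Recorded per repetition: realized sample size, each method's
#' selected variables in order, and its performance (held-out test accuracy
#' for the SVM strategies, full-data C-statistic for the logistic model).
#'
#' The default profile is scaled down for desk use (10 repetitions, 10
#' hospitals with 4-6 doctors of 5-15 patients each); pass
#' `hierarchy = hierarchy_config()` and `n_reps = 100` for a full-scale run.
#'
#' @param n_reps Number of repetitions (>= 1).
#' @param hierarchy [hierarchy_config()] for the generator (the `seed` field
#'   is overridden per repetition).
#' @param effects [effect_spec()] shared by all repetitions.
#' @param master_seed Master seed from which all per-repetition seeds are
#'   derived.
#' @param max_size Selection size cap shared by all methods (default 5).
#' @param stepsvm_tuning,rfe_costs Tuning for the SVM strategies: default
#'   RBF C = 10, gamma = 1 for StepSVM and linear C in `c(0.1, 10)` for
#'   SVM-RFE.
#' @param n_folds,test_fraction Evaluation protocol shared by the SVM
#'   strategies.
#' @param out_dir Optional directory for per-repetition JSON result files;
#'   existing valid files are loaded instead of recomputed, making an
#'   interrupted run resumable with identical results.
#' @param verbose Print a progress line per repetition.
#' @return An object of class `"svmsel_benchmark"`: `selections` (data frame
#'   with columns `rep`, `method`, `position`, `variable`), `performance`
#'   (`rep`, `method`, `metric`, `value`), `sizes` (realized n per rep),
#'   `failures`, plus the configuration. More than 10\% failed repetitions
#'   aborts. Methods: `print`, [frequency_table()],
#'   [summarize_performance()], [write_benchmark_report()].
#' @export
run_benchmark <- function(n_reps = 10,
                          hierarchy = hierarchy_config(
                            n_hospitals = 10,
                            doctors_per_hospital = c(4, 6),
                            patients_per_doctor = c(5, 15)),
                          effects = default_effects(),
                          master_seed = 1L,
                          max_size = 5,
                          stepsvm_tuning = tuning_config("rbf", 10, 1),
                          rfe_costs = c(0.1, 10),
                          n_folds = 10, test_fraction = 0.2,
                          out_dir = NULL, verbose = FALSE) {
  if (!is_count(n_reps) || n_reps < 1) stop_config("n_reps must be >= 1")
  gen_seeds <- derive_seeds(master_seed, n_reps, stream = 1L)
  eval_seeds <- derive_seeds(master_seed, n_reps, stream = 2L)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  methods <- c("stepsvm", paste0("svm_rfe_C", rfe_costs), "stepwise_logistic")
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_file <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("rep_%03d.json", r))
    } else NULL
    if (!is.null(rep_file) && file.exists(rep_file)) {
      rec <- tryCatch(jsonlite::read_json(rep_file, simplifyVector = TRUE),
                      error = function(e) NULL)
      if (!is.null(rec) && identical(rec$master_seed, as.integer(master_seed))) {
        reps[[r]] <- rec
        if (verbose) message("rep ", r, ": loaded from ", rep_file)
        next
      }
    }
    rec <- run_one_rep(r, gen_seeds[r], eval_seeds[r], hierarchy, effects,
                       max_size, stepsvm_tuning, rfe_costs, n_folds,
                       test_fraction, master_seed)
    if (verbose) {
      message(sprintf("rep %d: seed %d, n = %s", r, gen_seeds[r],
                      rec$n %||% "failed"))
    }
    if (!is.null(rep_file)) {
      jsonlite::write_json(rec, rep_file, auto_unbox = TRUE, digits = NA)
    }
    reps[[r]] <- rec
  }

  failed <- vapply(reps, function(x) isTRUE(x$failed), logical(1))
  if (sum(failed) > 0.1 * n_reps) {
    stop_config(sum(failed), " of ", n_reps, " repetitions failed (> 10%)")
  }

  selections <- do.call(rbind, lapply(which(!failed), function(r) {
    do.call(rbind, lapply(methods, function(mth) {
      sel <- reps[[r]]$selections[[mth]]
      if (is.null(sel) || !length(sel)) return(NULL)
      data.frame(rep = r, method = mth, position = seq_along(sel),
                 variable = sel, stringsAsFactors = FALSE)
    }))
  }))
  performance <- do.call(rbind, lapply(which(!failed), function(r) {
    perf <- reps[[r]]$performance
    data.frame(rep = r, method = names(perf),
               metric = ifelse(names(perf) == "stepwise_logistic",
                               "c_statistic", "accuracy"),
               value = as.numeric(unlist(perf)),
               stringsAsFactors = FALSE)
  }))
  rownames(selections) <- rownames(performance) <- NULL

  structure(list(
    n_reps = n_reps, methods = methods, max_size = max_size,
    master_seed = as.integer(master_seed),
    selections = selections, performance = performance,
    sizes = vapply(reps, function(x) as.numeric(x$n %||% NA), numeric(1)),
    failures = which(failed), reps = reps,
    hierarchy = hierarchy, effects = effects),
    class = "svmsel_benchmark")
}

run_one_rep <- function(r, gen_seed, eval_seed, hierarchy, effects, max_size,
                        stepsvm_tuning, rfe_costs, n_folds, test_fraction,
                        master_seed) {
  tryCatch({
    hierarchy$seed <- gen_seed
    d <- generate_hierarchy(hierarchy, effects)
    protocol <- eval_protocol(test_fraction = test_fraction,
                              n_folds = n_folds, seed = eval_seed)
    selections <- list(); performance <- list()

    fit_s <- stepsvm(d, max_size = max_size, tuning = stepsvm_tuning,
                     protocol = protocol)
    selections$stepsvm <- fit_s$selected
    performance$stepsvm <- fit_s$test_accuracy

    for (C in rfe_costs) {
      fit_r <- svm_rfe(d, k = max_size,
                       tuning = tuning_config("linear", cost = C),
                       protocol = protocol)
      nm <- paste0("svm_rfe_C", C)
      selections[[nm]] <- fit_r$selected
      performance[[nm]] <- fit_r$test_accuracy
    }

    fit_l <- stepwise_logistic(d, max_size = max_size)
    selections$stepwise_logistic <- fit_l$selected
    performance$stepwise_logistic <- fit_l$c_statistic

    list(rep = r, master_seed = as.integer(master_seed),
         gen_seed = gen_seed, eval_seed = eval_seed, n = nrow(d),
         selections = selections, performance = performance, failed = FALSE)
  }, error = function(e) {
    warning("repetition ", r, " failed: ", conditionMessage(e), call. = FALSE)
    list(rep = r, master_seed = as.integer(master_seed), failed = TRUE,
         reason = conditionMessage(e))
  })
}

#' Selection-frequency table of a benchmark method
#'
#' Counts how often each variable was selected at each position 1..max_size
#' across repetitions, plus the cumulative variant (selected at or before
#' each position).
#'
#' @param report An `svmsel_benchmark` from [run_benchmark()].
#' @param method One of `report$methods`.
#' @return A list with matrices `counts` and `cumulative`
#'   (variable x position).
#' @export
frequency_table <- function(report, method) {
  stopifnot(inherits(report, "svmsel_benchmark"))
  if (!method %in% report$methods) {
    stop_config("unknown method '", method, "'; available: ",
                paste(report$methods, collapse = ", "))
  }
  sel <- report$selections[report$selections$method == method, , drop = FALSE]
  vars <- sort(unique(report$selections$variable))
  counts <- matrix(0L, length(vars), report$max_size,
                   dimnames = list(vars, paste0("pos", seq_len(report$max_size))))
  if (nrow(sel)) {
    tab <- table(factor(sel$variable, levels = vars),
                 factor(sel$position, levels = seq_len(report$max_size)))
    counts[] <- as.integer(tab)
  }
  cumulative <- t(apply(counts, 1, cumsum))
  dimnames(cumulative) <- dimnames(counts)
  list(counts = counts, cumulative = cumulative)
}

#' Per-method performance summary
#'
#' @param report An `svmsel_benchmark` from [run_benchmark()].
#' @return A data frame with one row per method: `metric`, `mean`, `sd`,
#'   `min`, `max`, `n`. Methods with no successful repetition are omitted
#'   with a warning.
#' @export
summarize_performance <- function(report) {
  stopifnot(inherits(report, "svmsel_benchmark"))
  out <- do.call(rbind, lapply(report$methods, function(mth) {
    v <- report$performance$value[report$performance$method == mth]
    v <- v[is.finite(v)]
    if (!length(v)) {
      warning("no successful repetitions for ", mth, call. = FALSE)
      return(NULL)
    }
    data.frame(method = mth,
               metric = report$performance$metric[
                 report$performance$method == mth][1],
               mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.svmsel_benchmark <- function(x, ...) {
  cat("Simulation benchmark:", x$n_reps, "repetitions, methods:",
      paste(x$methods, collapse = ", "), "\n")
  cat("Realized n: ", paste(range(x$sizes, na.rm = TRUE), collapse = "-"),
      if (length(x$failures)) paste0(" (", length(x$failures), " failed)"),
      "\n", sep = "")
  print(summarize_performance(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.svmsel_benchmark <- function(x, ...) {
  perf <- x$performance
  graphics::boxplot(value ~ method, data = perf,
                    ylab = "accuracy / C-statistic", las = 2, ...)
  invisible(x)
}

#' Write a benchmark report to CSV/JSON files
#'
#' Writes `selections_<method>.csv`, `frequency_<method>.csv` (counts with a
#' cumulative block), `performance.csv` and `summary.json` under `dir`.
#'
#' @param report An `svmsel_benchmark`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (mth in report$methods) {
    sel <- report$selections[report$selections$method == mth, , drop = FALSE]
    utils::write.csv(sel, file.path(dir, paste0("selections_", mth, ".csv")),
                     row.names = FALSE)
    ft <- frequency_table(report, mth)
    utils::write.csv(
      data.frame(variable = rownames(ft$counts), ft$counts,
                 cumulative = ft$cumulative, check.names = FALSE),
      file.path(dir, paste0("frequency_", mth, ".csv")), row.names = FALSE)
  }
  utils::write.csv(report$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_reps = report$n_reps, master_seed = report$master_seed,
         summary = summarize_performance(report)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a benchmark configuration file
#'
#' Reads a YAML or JSON file mirroring the [hierarchy_config()],
#' [effect_spec()] and [run_benchmark()] fields: top-level keys `hierarchy`
#' (`n_hospitals`, `doctors_per_hospital`, `patients_per_doctor`), `effects`
#' (`fixed_effects` map, `intercept`, `sd_doctor`, `sd_hospital`), and
#' optionally `n_reps`, `max_size`, `n_folds`, `test_fraction`.
#'
#' @param path File path (`.yaml`/`.yml` requires the yaml package).
#' @return A named list of arguments accepted by [run_benchmark()].
#' @export
read_benchmark_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- list()
  if (!is.null(raw$hierarchy)) {
    h <- raw$hierarchy
    out$hierarchy <- hierarchy_config(
      n_hospitals = h$n_hospitals %||% 35,
      doctors_per_hospital = unlist(h$doctors_per_hospital %||% c(8, 15)),
      patients_per_doctor = unlist(h$patients_per_doctor %||% c(2, 40)),
      seed = h$seed %||% 1L)
  }
  if (!is.null(raw$effects)) {
    e <- raw$effects
    out$effects <- effect_spec(
      fixed_effects = unlist(e$fixed_effects %||% list()),
      intercept = e$intercept %||% 0,
      sd_doctor = e$sd_doctor %||% 0,
      sd_hospital = e$sd_hospital %||% 0)
  }
  for (f in c("n_reps", "max_size", "n_folds", "test_fraction",
              "master_seed")) {
    if (!is.null(raw[[f]])) out[[f]] <- raw[[f]]
  }
  out
}
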