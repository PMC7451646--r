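# Fixtures and independent oracles shared across the test files.
# All fixtures are generated in code under fixed seeds; nothing is stored.

# Planted-signal logistic data: the first `length(betas)` standard-normal
# predictors carry the outcome signal, the remaining `n_noise` are pure
# noise. Variables are named V01, V02, ...
make_planted <- function(n, betas = c(2.5, 2.0, 1.8), n_noise = 7, seed = 1) {
  p <- length(betas) + n_noise
  d <- stepsvm:::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    lp <- X[, seq_along(betas), drop = FALSE] %*% betas
    cbind(as.data.frame(X), remission = rbinom(n, 1, plogis(lp)))
  })
  names(d)[1:p] <- sprintf("V%02d", 1:p)
  d
}

# Near-deterministic staircase signal over the first five of `m` predictors,
# with decreasing coefficients so each forward addition keeps improving the
# cross-validated accuracy: used to drive the selection all the way to the
# size cap.
make_staircase <- function(n = 300, m = 26, seed = 11) {
  d <- stepsvm:::with_seed(seed, {
    X <- matrix(rnorm(n * m), n, m)
    lp <- 2.2 * X[, 1] + 1.8 * X[, 2] + 1.4 * X[, 3] + 1.1 * X[, 4] +
      0.9 * X[, 5]
    cbind(as.data.frame(X), remission = as.integer(lp + rnorm(n, 0, 0.3) > 0))
  })
  names(d)[1:m] <- sprintf("V%02d", 1:m)
  d
}

# Small hierarchical dataset for fast structural tests.
tiny_hdp <- function(seed = 1, effects = default_effects()) {
  generate_hierarchy(
    hierarchy_config(n_hospitals = 5, doctors_per_hospital = c(2, 3),
                     patients_per_doctor = c(5, 10), seed = seed),
    effects)
}

# All-pairs brute-force concordance oracle (double loop; ties count half).
brute_cstat <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Independent SVM-RFE re-implementation for continuous-only data frames:
# re-fits a linear SVM from scratch on the survivors at every elimination,
# ranks by squared weights, removes the minimum (ties toward the
# later-listed variable). Uses e1071 directly, standardizing once up front
# (equivalent for continuous columns since per-column statistics do not
# depend on which other columns survive).
rfe_oracle <- function(df, outcome = "remission", cost = 0.1) {
  vars <- setdiff(names(df), outcome)
  X <- scale(as.matrix(df[vars]))
  y <- factor(df[[outcome]], levels = c(0, 1))
  surviving <- vars
  eliminated <- character(0)
  while (length(surviving) > 1) {
    fit <- e1071::svm(x = X[, surviving, drop = FALSE], y = y,
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)[1, ]
    score <- w[surviving]^2
    worst <- max(which(score == min(score)))
    eliminated <- c(eliminated, surviving[worst])
    surviving <- surviving[-worst]
  }
  c(eliminated, surviving)
}

# Brute-force best pair: enumerate all pairs in canonical order through the
# public cv_accuracy operation and keep the first maximum.
brute_best_pair <- function(data, vars, tuning, protocol) {
  best <- -Inf; best_pair <- NULL
  for (i in seq_len(length(vars) - 1)) {
    for (j in seq((i + 1), length(vars))) {
      v <- cv_accuracy(data, c(vars[i], vars[j]), tuning, protocol)
      if (v > best) { best <- v; best_pair <- c(vars[i], vars[j]) }
    }
  }
  list(pair = best_pair, value = best)
}
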