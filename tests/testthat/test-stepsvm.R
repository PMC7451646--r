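test_that("stage candidate counts follow choose(m,2) then m - s", {
  expect_equal(count_stage_candidates(26, 1), 325)
  expect_equal(count_stage_candidates(26, 2), 24)
  expect_equal(count_stage_candidates(26, 3), 23)
  expect_equal(count_stage_candidates(26, 4), 22)
  expect_equal(count_stage_candidates(3, 1), 3)
  expect_equal(count_stage_candidates(3, 2), 1)
  expect_error(count_stage_candidates(1, 1), ">= 2")
  expect_error(count_stage_candidates(3, 3), "exceeds")
})

test_that("total work counts per strategy follow the closed forms", {
  expect_equal(count_total_models(26, "svm_rfe"), 26)
  expect_equal(count_total_models(26, "stepwise_logistic"), 351)
  expect_equal(count_total_models(26, "stepsvm"), 325 + 300)
  expect_equal(count_total_models(2, "stepsvm"), 1)
  # from m = 5 on, the stepwise SVM does the most work and RFE the least
  for (m in 5:12) {
    expect_gt(count_total_models(m, "stepsvm"),
              count_total_models(m, "stepwise_logistic"))
    expect_gt(count_total_models(m, "stepwise_logistic"),
              count_total_models(m, "svm_rfe"))
  }
})

test_that("select_best_pair finds a planted interaction pair", {
  # outcome is the XOR of V01 and V02; V03..V05 are noise, so no other pair
  # can beat the planted one under an RBF kernel
  d <- stepsvm:::with_seed(21, {
    X <- matrix(rnorm(250 * 5), 250, 5)
    y <- as.integer(xor(X[, 1] > 0, X[, 2] > 0))
    flip <- runif(250) < 0.05
    y[flip] <- 1 - y[flip]
    d <- cbind(as.data.frame(X), remission = y)
    names(d)[1:5] <- sprintf("V%02d", 1:5)
    d
  })
  res <- select_best_pair(d, tuning = tuning_config("rbf", 10, 1),
                          protocol = eval_protocol(test_fraction = 0,
                                                   seed = 2))
  expect_setequal(res$pair, c("V01", "V02"))
  expect_equal(res$n_evaluated, choose(5, 2))
  expect_equal(nrow(res$scores), choose(5, 2))
  expect_equal(res$value, max(res$scores$value))
})

test_that("select_best_pair handles m = 2 and duplicated-column ties", {
  d2 <- make_planted(120, betas = c(2), n_noise = 1, seed = 5)
  res <- select_best_pair(d2, protocol = eval_protocol(seed = 1))
  expect_setequal(res$pair, c("V01", "V02"))
  expect_equal(res$n_evaluated, 1L)
  # exact duplicate informative columns: ties resolved to the earliest
  # canonical pair, reproducibly
  dd <- stepsvm:::with_seed(8, {
    x <- rnorm(150)
    data.frame(A = x, B = x, C = rnorm(150),
               remission = rbinom(150, 1, plogis(3 * x)))
  })
  r1 <- select_best_pair(dd, protocol = eval_protocol(seed = 4))
  r2 <- select_best_pair(dd, protocol = eval_protocol(seed = 4))
  expect_identical(r1$pair, r2$pair)
  # (A, C) and (B, C) have identical scores; (A, C) is canonically first
  sc <- r1$scores
  vAC <- sc$value[sc$var1 == "A" & sc$var2 == "C"]
  vBC <- sc$value[sc$var1 == "B" & sc$var2 == "C"]
  expect_equal(vAC, vBC)
  if (r1$value == vAC) expect_true("A" %in% r1$pair)
})

test_that("forward_step adds the planted third variable and stops on noise", {
  d <- make_planted(400, betas = c(2.5, 2.0, 1.8), n_noise = 5, seed = 9)
  st <- forward_step(d, current = c("V01", "V02"), current_value = -Inf,
                     protocol = eval_protocol(test_fraction = 0, seed = 3))
  expect_equal(st$variable, "V03")
  expect_equal(st$n_evaluated, 6L)
  expect_true(st$improved)
  # perfectly separable current set: nothing can strictly improve on 1.0
  ds <- stepsvm:::with_seed(5, {
    y <- rep(0:1, each = 100)
    data.frame(x1 = rnorm(200) + 6 * y, x2 = rnorm(200), x3 = rnorm(200),
               remission = y)
  })
  cur <- cv_accuracy(ds, c("x1", "x2"), tuning_config("linear", 1),
                     eval_protocol(seed = 1))
  expect_equal(cur, 1.0)
  st2 <- forward_step(ds, c("x1", "x2"), current_value = cur,
                      tuning = tuning_config("linear", 1),
                      protocol = eval_protocol(seed = 1))
  expect_false(st2$improved)
  expect_true(is.na(st2$variable))
  # exhausted pool
  st3 <- forward_step(ds, c("x1", "x2", "x3"), current_value = 1,
                      tuning = tuning_config("linear", 1),
                      protocol = eval_protocol(seed = 1))
  expect_true(st3$exhausted)
  expect_equal(st3$n_evaluated, 0L)
})

test_that("stepsvm paths strictly increase, respect the cap, and are
           reproducible", {
  d <- make_planted(300, betas = c(2.5, 2.0), n_noise = 4, seed = 14)
  pr <- eval_protocol(seed = 6)
  fit2 <- stepsvm(d, max_size = 2, protocol = pr)
  expect_s3_class(fit2, "stepsvm")
  expect_length(fit2$selected, 2)
  expect_equal(fit2$stopped_reason, "max_size")
  expect_equal(nrow(fit2$steps), 1)

  fit <- stepsvm(d, max_size = 5, protocol = pr)
  vals <- fit$steps$value[!is.na(fit$steps$added)]
  expect_true(all(diff(vals) > 0))
  expect_lte(length(fit$selected), 5)
  expect_true(fit$stopped_reason %in%
                c("no_improvement", "max_size", "exhausted"))
  refit <- stepsvm(d, max_size = 5, protocol = pr)
  expect_identical(fit$selected, refit$selected)
  expect_identical(fit$steps, refit$steps)
  expect_identical(fit$test_accuracy, refit$test_accuracy)
})

test_that("selection is invariant to predictor column order", {
  d <- make_planted(250, betas = c(2.5, 2.0), n_noise = 4, seed = 17)
  pr <- eval_protocol(seed = 2)
  fit <- stepsvm(d, max_size = 3, protocol = pr)
  dperm <- d[, c(stepsvm:::with_seed(1, sample(setdiff(names(d), "remission"))),
                 "remission")]
  fitp <- stepsvm(dperm, max_size = 3, protocol = pr)
  expect_setequal(fit$selected, fitp$selected)
  expect_equal(fit$cv_value, fitp$cv_value)
})

test_that("formula interface and predictions work", {
  d <- make_planted(250, betas = c(2.5, 2.0), n_noise = 3, seed = 19)
  fit <- stepsvm(remission ~ V01 + V02 + V03 + V04 + V05, data = d,
                 max_size = 3, protocol = eval_protocol(seed = 5))
  expect_true(all(fit$selected %in% sprintf("V%02d", 1:5)))
  p <- predict(fit, d)
  expect_true(all(p %in% c(0, 1)))
  expect_gt(mean(p == d$remission), 0.7)
  expect_output(summary(fit), "Selection path")
})

test_that("per-subset re-tuning mode runs and records its choice", {
  d <- make_planted(150, betas = c(2.5, 2.0), n_noise = 2, seed = 23)
  fit <- stepsvm(d, max_size = 2, retune = TRUE,
                 tuning_grid = svm_grid(c("linear", "rbf"),
                                        costs = c(1, 10), gammas = 1),
                 protocol = eval_protocol(seed = 3, n_folds = 5))
  expect_s3_class(fit, "stepsvm")
  expect_true(fit$tuning$kernel %in% c("linear", "rbf"))
})
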