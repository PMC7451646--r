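test_that("accuracy follows (TP + TN) / total and its symmetries", {
  expect_equal(accuracy(confusion_counts(5, 5, 0, 0)), 1.0)
  expect_equal(accuracy(confusion_counts(0, 0, 5, 5)), 0.0)
  expect_equal(accuracy(confusion_counts(3, 4, 2, 1)), 0.7)
  # invariant under swapping the roles of the two classes
  for (i in 1:20) {
    x <- stepsvm:::with_seed(i, sample(0:10, 4, replace = TRUE))
    if (sum(x) == 0) next
    a <- accuracy(confusion_counts(x[1], x[2], x[3], x[4]))
    b <- accuracy(confusion_counts(x[2], x[1], x[4], x[3]))
    expect_equal(a, b)
  }
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "undefined")
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("c_statistic matches the all-pairs definition", {
  expect_equal(c_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(c_statistic(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # exhaustive enumeration over the 4 positive-negative pairs: 3 concordant
  expect_equal(c_statistic(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(c_statistic(1:4, c(1, 1, 1, 1)), "both classes")
  # property: midrank formula equals brute force on random instances
  for (i in 1:30) {
    stepsvm:::with_seed(1000 + i, {
      n <- sample(4:50, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- round(rnorm(n), 1)  # rounding forces ties
      expect_equal(c_statistic(s, y), brute_cstat(s, y))
    })
  }
})

test_that("split_train_test is an exact, stratified, seeded partition", {
  d <- make_planted(100, seed = 4)
  pr <- eval_protocol(test_fraction = 0.2, seed = 9)
  sp <- split_train_test(d, pr)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:100)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  # stratification keeps both classes in both parts
  expect_setequal(unique(sp$train$remission), c(0, 1))
  expect_setequal(unique(sp$test$remission), c(0, 1))
  # class balance of the test part matches the data within rounding
  expect_lt(abs(mean(sp$test$remission) - mean(d$remission)), 0.05)
  sp2 <- split_train_test(d, pr)
  expect_identical(sp$test_idx, sp2$test_idx)
  sp3 <- split_train_test(d, eval_protocol(test_fraction = 0.2, seed = 10))
  expect_false(identical(sp$test_idx, sp3$test_idx))
  expect_error(split_train_test(d, eval_protocol(test_fraction = 0.001)),
               "empty")
})

test_that("cv_accuracy is seeded, bounded by the majority class, and exact
           on separable data", {
  # majority behavior: uninformative features, 90% majority class
  d0 <- stepsvm:::with_seed(2, data.frame(
    x1 = rnorm(200), x2 = rnorm(200),
    remission = rep(c(0, 1), c(180, 20))))
  a <- cv_accuracy(d0, c("x1", "x2"), tuning_config("rbf", 10, 1),
                   eval_protocol(seed = 3))
  expect_gt(a, 0.8)
  # linearly separable with margin: every fold classifies perfectly
  ds <- stepsvm:::with_seed(5, {
    y <- rep(0:1, each = 100)
    data.frame(x1 = rnorm(200) + 6 * y, x2 = rnorm(200), remission = y)
  })
  expect_equal(cv_accuracy(ds, c("x1", "x2"), tuning_config("linear", 1),
                           eval_protocol(seed = 1)), 1.0)
  # seeded determinism
  d <- make_planted(150, seed = 6)
  a1 <- cv_accuracy(d, c("V01", "V02"), protocol = eval_protocol(seed = 2))
  a2 <- cv_accuracy(d, c("V01", "V02"), protocol = eval_protocol(seed = 2))
  expect_identical(a1, a2)
  expect_error(cv_accuracy(d, character(0)), "nonempty")
})

test_that("cv_accuracy does not depend on the incoming row order", {
  d <- tiny_hdp(seed = 8)
  pr <- eval_protocol(seed = 13, n_folds = 5)
  a1 <- cv_accuracy(d, c("CancerStage", "mobility", "DID"), protocol = pr)
  perm <- stepsvm:::with_seed(99, sample(nrow(d)))
  dp <- stepsvm:::subset_rows(d, perm)
  a2 <- cv_accuracy(dp, c("CancerStage", "mobility", "DID"), protocol = pr)
  expect_identical(a1, a2)
})

test_that("tune_svm minimizes CV mean squared error with first-wins ties", {
  # singleton grid
  d <- make_planted(120, seed = 3)
  g1 <- list(tuning_config("linear", 0.5))
  t1 <- tune_svm(d, c("V01", "V02"), g1)
  expect_equal(t1, g1[[1]], ignore_attr = TRUE)
  expect_error(tune_svm(d, "V01", list()), "nonempty")
  # XOR interaction: the linear kernel is near chance, the RBF is not
  dx <- stepsvm:::with_seed(9, {
    x1 <- rnorm(300); x2 <- rnorm(300)
    data.frame(x1 = x1, x2 = x2,
               remission = as.integer(xor(x1 > 0, x2 > 0)))
  })
  tc <- tune_svm(dx, c("x1", "x2"),
                 svm_grid(c("linear", "rbf"), costs = c(0.1, 10), gammas = 1),
                 eval_protocol(seed = 1))
  expect_equal(tc$kernel, "rbf")
  expect_gt(attr(tc, "cv_accuracy"), 0.8)
  # tie-break: on separable data both costs reach CV MSE 0; earlier wins
  ds <- stepsvm:::with_seed(5, {
    y <- rep(0:1, each = 100)
    data.frame(x1 = rnorm(200) + 6 * y, remission = y)
  })
  tie <- tune_svm(ds, "x1", svm_grid("linear", costs = c(1, 10)),
                  eval_protocol(seed = 1))
  expect_equal(tie$cost, 1)
  # identity used by the tuner: MSE of hard 0/1 predictions = 1 - accuracy
  expect_equal(attr(tie, "cv_mse"), 1 - attr(tie, "cv_accuracy"))
})

test_that("unstratified folds that lose a class raise a protocol error", {
  # a single positive guarantees one training fold misses the class
  d <- stepsvm:::with_seed(1, data.frame(
    x1 = rnorm(40), remission = rep(c(1, 0), c(1, 39))))
  expect_error(
    cv_accuracy(d, "x1", protocol = eval_protocol(seed = 4, n_folds = 10,
                                                  stratified = FALSE)),
    "stratified")
})
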