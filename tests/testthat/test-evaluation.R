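test_that("train/test split honors the round-half-up size contract", {
  tab <- data.frame(yellow_pct = runif(4366), brown_pct = runif(4366),
                    rating = rep(1:5, length.out = 4366))
  sp <- split_train_test(tab, 0.75, seed = 1)
  expect_equal(nrow(sp$train), 3275)   # floor(0.75 * 4366 + 0.5)
  expect_equal(nrow(sp$test), 1091)
  expect_equal(nrow(sp$train) + nrow(sp$test), 4366)
  # disjoint and exhaustive
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)

  small <- tab[1:4, ]
  sp4 <- split_train_test(small, 0.75, seed = 1)
  expect_equal(nrow(sp4$train), 3)
  expect_equal(nrow(sp4$test), 1)

  expect_identical(split_train_test(tab, 0.75, seed = 9),
                   split_train_test(tab, 0.75, seed = 9))
  expect_error(split_train_test(tab, 1.2), class = "idc_invalid_input")
})

test_that("stratified splits preserve class proportions and total size", {
  tab <- generate_feature_table(n = 997, seed = 3)
  sp <- split_train_test(tab, 0.75, seed = 3, stratify = TRUE)
  expect_equal(nrow(sp$train), floor(0.75 * 997 + 0.5))
  for (r in 1:5) {
    n_r <- sum(tab$rating == r)
    n_tr <- sum(sp$train$rating == r)
    expect_lt(abs(n_tr - 0.75 * n_r), 1.5)
  }
})

test_that("confusion matrices count actual x predicted pairs", {
  cm <- confusion_matrix(c(1, 1), c(1, 2), classes = 1:2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 0L), 2, 2,
               dimnames = list(actual = 1:2, predicted = 1:2)))
  perfect <- confusion_matrix(1:5, 1:5, classes = 1:5)
  expect_true(all(diag(as.matrix(perfect)) == 1))
  expect_equal(sum(as.matrix(perfect)), 5)
  expect_error(confusion_matrix(1:3, 1:2), class = "idc_invalid_input")

  set.seed(11)
  for (i in 1:200) {
    a <- sample(1:5, 30, replace = TRUE)
    p <- sample(1:5, 30, replace = TRUE)
    expect_equal(unname(unclass(confusion_matrix(a, p, classes = 1:5))),
                 oracle_confusion(a, p, 1:5))
  }
})

test_that("accuracy, per-class accuracy and MPCA match hand arithmetic", {
  cm <- matrix(c(8, 5, 2, 5), 2, 2)  # rows actual: [[8,2],[5,5]]
  expect_equal(accuracy(cm), 65)
  expect_equal(unname(per_class_accuracy(cm)), c(0.8, 0.5))
  expect_equal(mpca(cm), 65)

  diag_cm <- diag(c(3, 7, 2))
  expect_equal(accuracy(diag_cm), 100)
  expect_equal(mpca(diag_cm), 100)
  off <- matrix(c(0, 3, 4, 0), 2, 2)
  expect_equal(accuracy(off), 0)

  # empty class row: undefined entry, excluded from the MPCA mean
  holed <- rbind(c(5, 0), c(0, 0))
  expect_warning(pca <- per_class_accuracy(holed), "undefined")
  expect_true(is.na(pca[2]))
  expect_equal(suppressWarnings(mpca(holed)), 100)
})

test_that("MPCA resists the imbalance that inflates accuracy", {
  # dominant class 1 carries accuracy; class 2 is mostly wrong
  cm <- rbind(c(95, 5), c(8, 2))
  expect_gt(accuracy(cm), 88)
  expect_lt(mpca(cm), accuracy(cm))
})

test_that("the cost matrix is |i - j| with the 4x ratio on the extremes", {
  w <- build_cost_matrix(5)
  expect_equal(w[1, 2], 1)
  expect_equal(w[1, 5], 4)
  expect_equal(w[1, 5] / w[1, 2], 4)
  expect_true(all(diag(as.matrix(w)) == 0))
  expect_equal(as.matrix(w), t(as.matrix(w)))
})

test_that("misclassification cost matches its definition and oracle", {
  w <- build_cost_matrix(5)
  expect_identical(misclassification_cost(diag(c(20, 20, 20, 20, 20)), w), 0)
  one_15 <- matrix(0, 5, 5); one_15[1, 5] <- 1
  expect_equal(misclassification_cost(one_15, w), 4)

  set.seed(5)
  for (i in 1:100) {
    cm <- matrix(rpois(25, 3), 5, 5)
    if (sum(cm) == 0) next
    expect_equal(misclassification_cost(cm, w), oracle_cost(cm, w))
  }
})

test_that("metric identities hold on random confusion matrices", {
  w <- build_cost_matrix(5)
  set.seed(6)
  for (i in 1:50) {
    cm <- matrix(rpois(25, 2), 5, 5)
    if (sum(cm) == 0) next
    expect_equal(accuracy(cm), oracle_accuracy(cm))
    expect_equal(suppressWarnings(mpca(cm)), oracle_mpca(cm))
    # zero cost iff perfectly diagonal
    expect_identical(misclassification_cost(cm, w) == 0,
                     sum(cm) == sum(diag(cm)))
    # cost per observation is invariant to replicating every count
    expect_equal(misclassification_cost(cm * 3, w),
                 misclassification_cost(cm, w))
    # MPCA equals accuracy when row sums are equal
    bal <- matrix(rpois(25, 4), 5, 5)
    bal <- bal + (max(rowSums(bal)) - rowSums(bal)) %o% c(1, 0, 0, 0, 0)
    if (all(rowSums(bal) > 0)) {
      expect_equal(mpca(bal), accuracy(bal))
    }
  }
})

test_that("cross-validation is reproducible and exact on separable data", {
  tab <- separable_table(n_per_class = 30)
  cv1 <- cross_validate(tab, "ct", k = 10, repeats = 2, seed = 4)
  cv2 <- cross_validate(tab, "ct", k = 10, repeats = 2, seed = 4)
  expect_identical(cv1, cv2)
  expect_gte(cv1$mean_cv_mpca, 99)
  expect_lte(cv1$mean_cv_cost, 0.01)
  expect_equal(nrow(cv1$folds), 20)

  # leave-one-out boundary case runs
  tiny <- separable_table(n_per_class = 4)
  loo <- cross_validate(tiny, "lda", k = nrow(tiny), repeats = 1, seed = 1)
  expect_true(is.finite(loo$mean_cv_error))
  expect_error(cross_validate(tiny, "lda", k = 100),
               class = "idc_invalid_input")
})

test_that("the benchmark table has the conventional report shape", {
  tab <- separable_table(n_per_class = 30)
  rep <- evaluate_models(tab, kinds = c("ct", "lda"), seed = 2,
                         cv = TRUE, k = 5, repeats = 1)
  expect_equal(rep$algorithm, c("ct", "lda"))
  expect_named(rep, c("algorithm", "accuracy", "mpca", "cv_mpca",
                      "cv_error", "interpretability", "cost"))
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 100))
  expect_gte(rep$accuracy[1], 99)
  path <- withr::local_tempfile(fileext = ".csv")
  write_evaluation_report(rep, csv_path = path)
  back <- read.csv(path)
  expect_equal(back$algorithm, rep$algorithm)
})
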