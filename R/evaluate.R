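#' Random train/test split
#'
#' Splits a table into disjoint, exhaustive train and test subsets. The
#' train size is `floor(train_fraction * N + 0.5)` (round half-up). With
#' `stratify = TRUE` the same rounding is applied per rating class and
#' the per-class counts are then adjusted (largest-remainder) so the
#' total train size still matches the unstratified contract.
#'
#' @param table data.frame; stratification uses its `rating` column.
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param seed integer RNG seed; the same seed reproduces the partition.
#' @param stratify preserve class proportions across the split?
#' @return list with data.frames `train` and `test`.
#' @export
split_train_test <- function(table, train_fraction = 0.75, seed = 1,
                             stratify = FALSE) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    idc_error("idc_invalid_input", "table must be a non-empty data.frame")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    idc_error("idc_invalid_input", "train_fraction must be in (0, 1)")
  }
  n <- nrow(table)
  n_train <- floor(train_fraction * n + 0.5)
  idx <- with_seed(seed, {
    if (!stratify) {
      sample.int(n, n_train)
    } else {
      cls <- table$rating
      targets_raw <- train_fraction * tabulate_by(cls)
      k <- floor(targets_raw + 0.5)
      # largest-remainder fix-up so sum(k) == n_train
      diff <- n_train - sum(k)
      if (diff != 0) {
        rem <- targets_raw - floor(targets_raw)
        ord <- order(rem, decreasing = diff > 0)
        adj <- names(k)[ord][seq_len(abs(diff))]
        k[adj] <- k[adj] + sign(diff)
      }
      unlist(lapply(names(k), function(cl) {
        pool <- which(cls == cl)
        pool[sample.int(length(pool), k[[cl]])]
      }), use.names = FALSE)
    }
  })
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

tabulate_by <- function(cls) {
  tab <- table(cls)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts observations whose actual class is `i` and
#' predicted class is `j` (rows = actual, columns = predicted).
#'
#' @param actual,predicted equal-length class label vectors.
#' @param classes class labels fixing the matrix dimensions; defaults to
#'   the sorted union of the observed labels.
#' @return integer matrix of class `idc_confusion`.
#' @export
confusion_matrix <- function(actual, predicted,
                             classes = sort(unique(c(actual, predicted)))) {
  if (length(actual) != length(predicted)) {
    idc_error("idc_invalid_input",
              "actual and predicted must have equal length")
  }
  a <- factor(actual, levels = classes)
  p <- factor(predicted, levels = classes)
  if (any(is.na(a)) || any(is.na(p))) {
    idc_error("idc_invalid_input", "labels outside the class set")
  }
  m <- unclass(table(actual = a, predicted = p))
  structure(matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m)),
            class = "idc_confusion")
}

#' Overall accuracy from a confusion matrix
#'
#' `100 * trace / N`: the percentage of observations on the diagonal.
#'
#' @param cm a square count matrix (rows = actual).
#' @return percentage in `[0, 100]`.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  100 * sum(diag(cm)) / sum(cm)
}

#' Per-class accuracy from a confusion matrix
#'
#' Entry `i` is `cm[i, i] / rowsum(i)`: the fraction of class-`i`
#' observations predicted as class `i`. Classes with no observations
#' (zero row sum) are undefined and returned as `NA` with a warning.
#'
#' @param cm a square count matrix (rows = actual).
#' @return numeric vector of fractions (one per class, `NA` when
#'   undefined).
#' @export
per_class_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    warning("classes with no observations: per-class accuracy undefined for ",
            paste(rownames(cm)[rs == 0], collapse = ", "), call. = FALSE)
  }
  out <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  stats::setNames(out, rownames(cm))
}

#' Mean per-class accuracy (MPCA)
#'
#' `100 *` mean of the defined per-class accuracies. Less sensitive than
#' overall accuracy to class imbalance: the dominant class cannot carry
#' the statistic.
#'
#' @param cm a square count matrix (rows = actual).
#' @return percentage in `[0, 100]`.
#' @export
mpca <- function(cm) {
  pca <- per_class_accuracy(cm)
  100 * mean(pca, na.rm = TRUE)
}

#' Linear misclassification cost matrix
#'
#' Weights `w[i, j] = |i - j|` on the rating scale: predicting 5 for an
#' actual 1 costs 4 times as much as predicting 2, and the diagonal is
#' free.
#'
#' @param n number of classes (default 5).
#' @return `n x n` numeric matrix of class `idc_cost_matrix`.
#' @export
build_cost_matrix <- function(n = 5) {
  i <- seq_len(n)
  structure(abs(outer(i, i, "-")), dimnames = list(i, i),
            class = "idc_cost_matrix")
}

#' Average misclassification cost
#'
#' `sum(cm * w) / N`: each confusion count weighted by its cost, averaged
#' over all observations. Zero exactly when the confusion matrix is
#' diagonal (100% accuracy).
#'
#' @param cm confusion matrix (rows = actual).
#' @param w cost matrix of the same shape (see [build_cost_matrix()]).
#' @return nonnegative scalar cost.
#' @export
misclassification_cost <- function(cm, w = build_cost_matrix(nrow(as.matrix(cm)))) {
  cm <- as.matrix(cm); w <- as.matrix(w)
  if (!all(dim(cm) == dim(w))) {
    idc_error("idc_invalid_input", "confusion and cost matrices must match")
  }
  n <- sum(cm)
  if (n == 0) {
    idc_error("idc_invalid_input", "empty confusion matrix")
  }
  sum(cm * w) / n
}

#' Repeated k-fold cross-validation
#'
#' Each repeat shuffles the rows (repeat `r` is seeded `seed + r`) and
#' partitions them into `k` contiguous folds; each fold is held out once.
#' Reported metrics are averaged over all `k * repeats` held-out folds:
#' MPCA (undefined classes excluded within a fold), Eq.-style
#' misclassification cost, and the plain misclassification error rate.
#'
#' @param table labeled feature table (`yellow_pct`, `brown_pct`,
#'   `rating`).
#' @param kind classifier kind (see [idc_train()]).
#' @param k number of folds (`N >= k`); `k = N` is leave-one-out.
#' @param repeats number of shuffled repeats.
#' @param seed integer base seed.
#' @param ... further arguments to [idc_train()].
#' @return list with `mean_cv_mpca`, `mean_cv_cost`, `mean_cv_error`
#'   (all scalars) and `folds` (per-fold data.frame).
#' @export
cross_validate <- function(table, kind, k = 10, repeats = 10, seed = 1, ...) {
  n <- nrow(table)
  if (n < k) {
    idc_error("idc_invalid_input", "need at least k rows for k folds")
  }
  classes <- sort(unique(table$rating))
  w <- build_cost_matrix(length(classes))
  rows <- list()
  for (r in seq_len(repeats)) {
    perm <- with_seed(seed + r, sample.int(n))
    fold_id <- cut(seq_len(n), breaks = k, labels = FALSE)
    for (f in seq_len(k)) {
      test_idx <- perm[fold_id == f]
      train <- table[-test_idx, , drop = FALSE]
      test <- table[test_idx, , drop = FALSE]
      model <- idc_train(train, kind = kind, seed = seed + r, ...)
      pred <- predict(model, test)
      cm <- confusion_matrix(test$rating, pred, classes = classes)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, fold = f,
        mpca = suppressWarnings(mpca(cm)),
        cost = misclassification_cost(cm, w),
        error = 1 - sum(diag(as.matrix(cm))) / sum(cm))
    }
  }
  folds <- do.call(rbind, rows)
  list(mean_cv_mpca = mean(folds$mpca),
       mean_cv_cost = mean(folds$cost),
       mean_cv_error = mean(folds$error),
       folds = folds)
}

#' Benchmark several classifiers on one labeled table
#'
#' Train/test evaluation plus (optionally) repeated k-fold
#' cross-validation for each kind, reported in the conventional benchmark
#' shape: algorithm, test accuracy, test MPCA, cross-validated MPCA, an
#' empty interpretability annotation column (a human judgment, to be
#' filled in by the analyst after inspecting the population canopy
#' graphs), and the cost metric.
#'
#' @param table labeled feature table.
#' @param kinds character vector of classifier kinds.
#' @param train_fraction,seed split parameters (see
#'   [split_train_test()]).
#' @param cv run cross-validation? (the slow part)
#' @param k,repeats cross-validation parameters.
#' @param ... further arguments to [idc_train()].
#' @return data.frame with one row per kind.
#' @export
evaluate_models <- function(table, kinds = idc_kinds, train_fraction = 0.75,
                            seed = 1, cv = TRUE, k = 10, repeats = 10, ...) {
  sp <- split_train_test(table, train_fraction, seed = seed)
  classes <- sort(unique(table$rating))
  w <- build_cost_matrix(length(classes))
  out <- lapply(kinds, function(kind) {
    model <- idc_train(sp$train, kind = kind, seed = seed, ...)
    pred <- predict(model, sp$test)
    cm <- confusion_matrix(sp$test$rating, pred, classes = classes)
    cvres <- if (cv) {
      cross_validate(table, kind, k = k, repeats = repeats, seed = seed, ...)
    } else {
      list(mean_cv_mpca = NA_real_, mean_cv_error = NA_real_)
    }
    data.frame(algorithm = kind,
               accuracy = accuracy(cm),
               mpca = suppressWarnings(mpca(cm)),
               cv_mpca = cvres$mean_cv_mpca,
               cv_error = cvres$mean_cv_error,
               interpretability = NA_character_,
               cost = misclassification_cost(cm, w))
  })
  do.call(rbind, out)
}

#' Write an evaluation report
#'
#' Saves the benchmark table both as CSV (one row per algorithm:
#' Algorithm, Accuracy, MPCA, Cross-validated MPCA, Interpretability,
#' Cost metric) and, optionally, as JSON.
#'
#' @param report data.frame from [evaluate_models()].
#' @param csv_path,json_path output paths (`NULL` to skip one).
#' @return invisibly, the report.
#' @export
write_evaluation_report <- function(report, csv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}
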