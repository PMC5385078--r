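#' Susceptibility group of a rating
#'
#' Ratings 1 and 2 form the low-susceptibility group, rating 3 the
#' medium group, and ratings 4 and 5 the high group. This fixed partition
#' drives the two-step hierarchical classifier.
#'
#' @param rating integer vector of ratings in 1--5.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
group_of <- function(rating) {
  rating <- as.integer(rating)
  if (any(is.na(rating)) || any(rating < 1L | rating > 5L)) {
    idc_error("idc_invalid_input", "ratings must be integers in 1..5")
  }
  factor(c("low", "low", "medium", "high", "high")[rating],
         levels = c("low", "medium", "high"))
}

idc_kinds <- c("ct", "rf", "nb", "lda", "qda", "svm", "knn", "gmmb",
               "hier_svm_svm", "hier_lda_svm")

# Normalize a feature input to a 2-column data.frame (yellow_pct, brown_pct)
feature_frame <- function(x) {
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is.data.frame(x)) {
    idc_error("idc_invalid_input", "features must be a data.frame or matrix")
  }
  if (!all(c("yellow_pct", "brown_pct") %in% names(x))) {
    if (ncol(x) >= 2L) {
      names(x)[1:2] <- c("yellow_pct", "brown_pct")
    } else {
      idc_error("idc_invalid_input",
                "features need columns yellow_pct and brown_pct")
    }
  }
  x[, c("yellow_pct", "brown_pct")]
}

#' Train an IDC severity classifier
#'
#' Fits a rating classifier on the two canopy discoloration features
#' (Y%, B%). Flat kinds: `"ct"` (classification tree), `"rf"` (random
#' forest), `"nb"` (naive Bayes), `"lda"`, `"qda"`, `"svm"` (multi-class
#' RBF SVM on standardized features), `"knn"` (deterministic k-nearest
#' neighbors), `"gmmb"` (per-class Gaussian mixtures combined through the
#' Bayes rule with empirical priors). Hierarchical kinds fit a Step-A
#' group model (low = ratings 1--2, medium = 3, high = 4--5) with SVM
#' (`"hier_svm_svm"`) or LDA (`"hier_lda_svm"`), then binary SVMs that
#' resolve 1 vs 2 within the low group and 4 vs 5 within the high group;
#' the medium group maps directly to rating 3.
#'
#' Whenever a probability, vote or posterior tie occurs, the lowest
#' rating wins (a conservative severity call).
#'
#' @param data data.frame with columns `yellow_pct`, `brown_pct` and
#'   `rating` (integers 1--5), e.g. from [generate_feature_table()].
#' @param kind one of `r paste0('"', idc_kinds, '"', collapse = ", ")`.
#' @param knn_k neighbors for `"knn"`.
#' @param rf_ntree trees for `"rf"`.
#' @param gmm_G mixture components per class for `"gmmb"`.
#' @param class_weights optional named weights passed to weight-aware
#'   backends (SVM, tree); `NULL` trains on the data as-is.
#' @param seed integer seed; fits are deterministic given the seed.
#' @return an object of class `idc_model` with [predict.idc_model()],
#'   [print.idc_model()], [summary.idc_model()] and [plot.idc_model()]
#'   methods.
#' @export
idc_train <- function(data, kind = "hier_svm_svm", knn_k = 5L,
                      rf_ntree = 100L, gmm_G = 2L, class_weights = NULL,
                      seed = 1) {
  kind <- match.arg(kind, idc_kinds)
  x <- feature_frame(data)
  if (!"rating" %in% names(data)) {
    idc_error("idc_invalid_input", "data must contain a rating column")
  }
  yr <- as.integer(data$rating)
  if (any(!is.finite(as.matrix(x))) || any(is.na(yr))) {
    idc_error("idc_invalid_input", "features and ratings must be finite")
  }
  if (any(yr < 1L | yr > 5L)) {
    idc_error("idc_invalid_input", "ratings must be in 1..5")
  }
  if (length(unique(yr)) < 2L) {
    idc_error("idc_invalid_input",
              "training data contain a single class; need at least two")
  }
  fit <- if (startsWith(kind, "hier_")) {
    fit_hierarchical(x, yr, stepA = if (kind == "hier_svm_svm") "svm" else "lda",
                     class_weights = class_weights, seed = seed)
  } else {
    fit_flat(x, yr, kind, knn_k = knn_k, rf_ntree = rf_ntree,
             gmm_G = gmm_G, class_weights = class_weights, seed = seed)
  }
  structure(list(kind = kind, fit = fit,
                 classes = sort(unique(yr)),
                 n_train = nrow(x), seed = seed,
                 hyper = list(knn_k = knn_k, rf_ntree = rf_ntree,
                              gmm_G = gmm_G, class_weights = class_weights),
                 train_data = if (kind == "knn") list(x = as.matrix(x), y = yr)
                              else NULL),
            class = "idc_model")
}

fit_flat <- function(x, yr, kind, knn_k, rf_ntree, gmm_G, class_weights,
                     seed) {
  y <- factor(yr, levels = sort(unique(yr)))
  df <- data.frame(x, .rating = y)
  switch(kind,
    ct = {
      parms <- if (!is.null(class_weights))
        list(prior = class_weights / sum(class_weights)) else NULL
      if (is.null(parms)) {
        rpart::rpart(.rating ~ yellow_pct + brown_pct, data = df,
                     method = "class")
      } else {
        rpart::rpart(.rating ~ yellow_pct + brown_pct, data = df,
                     method = "class", parms = parms)
      }
    },
    rf = with_seed(seed,
      randomForest::randomForest(x = x, y = y, ntree = rf_ntree)),
    nb = e1071::naiveBayes(x = x, y = y),
    lda = MASS::lda(.rating ~ yellow_pct + brown_pct, data = df),
    qda = MASS::qda(.rating ~ yellow_pct + brown_pct, data = df),
    svm = with_seed(seed,
      e1071::svm(.rating ~ yellow_pct + brown_pct, data = df,
                 kernel = "radial", scale = TRUE,
                 class.weights = class_weights)),
    knn = list(k = as.integer(knn_k)),
    gmmb = fit_gmmb(x, yr, gmm_G)
  )
}

fit_gmmb <- function(x, yr, gmm_G) {
  classes <- sort(unique(yr))
  dens <- lapply(classes, function(r) {
    xi <- as.matrix(x[yr == r, , drop = FALSE])
    g <- min(gmm_G, max(1L, nrow(xi) %/% 3L))
    fit <- NULL
    while (is.null(fit) && g >= 1L) {
      fit <- tryCatch(
        suppressWarnings(mclust::densityMclust(xi, G = g, plot = FALSE,
                                               verbose = FALSE)),
        error = function(e) NULL)
      g <- g - 1L
    }
    if (is.null(fit)) {
      idc_error("idc_invalid_input",
                sprintf("cannot fit a mixture for rating %d", r))
    }
    fit
  })
  list(classes = classes, dens = dens,
       priors = as.numeric(table(factor(yr, levels = classes))) / length(yr))
}

fit_hierarchical <- function(x, yr, stepA, class_weights, seed) {
  grp <- group_of(yr)
  grp_present <- droplevels(grp)
  dfA <- data.frame(x, .grp = grp_present)
  modelA <- if (nlevels(grp_present) < 2L) {
    list(constant = levels(grp_present))
  } else if (stepA == "svm") {
    with_seed(seed, e1071::svm(.grp ~ yellow_pct + brown_pct, data = dfA,
                               kernel = "radial", scale = TRUE,
                               class.weights = class_weights))
  } else {
    MASS::lda(.grp ~ yellow_pct + brown_pct, data = dfA)
  }

  fit_branch <- function(grp_name, members) {
    rows <- grp == grp_name
    if (!any(rows)) {
      warning(sprintf(
        "no training data in the %s susceptibility group; branch falls back to rating %d",
        grp_name, min(members)), call. = FALSE)
      return(list(constant = min(members)))
    }
    labs <- yr[rows]
    if (length(unique(labs)) < 2L) {
      return(list(constant = unique(labs)))
    }
    dfB <- data.frame(x[rows, , drop = FALSE],
                      .rating = factor(labs, levels = sort(unique(labs))))
    with_seed(seed, e1071::svm(.rating ~ yellow_pct + brown_pct, data = dfB,
                               kernel = "radial", scale = TRUE))
  }
  list(stepA_kind = stepA, modelA = modelA,
       low = fit_branch("low", c(1L, 2L)),
       high = fit_branch("high", c(4L, 5L)))
}

# which.max over columns ordered by ascending rating -> lowest rating on ties
pick_lowest_max <- function(post, classes) {
  stopifnot(ncol(post) == length(classes))
  classes[max.col(post, ties.method = "first")]
}

predict_knn <- function(model, newx) {
  tr <- model$train_data
  k <- min(model$fit$k, nrow(tr$x))
  classes <- model$classes
  apply(newx, 1, function(p) {
    d <- (tr$x[, 1] - p[1])^2 + (tr$x[, 2] - p[2])^2
    nn <- order(d)[seq_len(k)]   # order() breaks distance ties by index
    votes <- tabulate(match(tr$y[nn], classes), nbins = length(classes))
    classes[which.max(votes)]    # first max -> lowest rating on vote ties
  })
}

predict_gmmb <- function(fit, newx) {
  ll <- vapply(seq_along(fit$classes), function(i) {
    log(fit$priors[i]) +
      mclust::dens(fit$dens[[i]]$modelName, data = newx,
                   parameters = fit$dens[[i]]$parameters, logarithm = TRUE)
  }, numeric(nrow(newx)))
  ll <- matrix(ll, nrow = nrow(newx))
  pick_lowest_max(ll, fit$classes)
}

predict_flat <- function(model, newx) {
  fit <- model$fit
  nd <- as.data.frame(newx)
  names(nd) <- c("yellow_pct", "brown_pct")
  switch(model$kind,
    ct = {
      p <- predict(fit, nd, type = "prob")
      pick_lowest_max(p, as.integer(colnames(p)))
    },
    rf = {
      p <- predict(fit, nd, type = "vote", norm.votes = FALSE)
      pick_lowest_max(p, as.integer(colnames(p)))
    },
    nb = {
      p <- predict(fit, nd, type = "raw")
      pick_lowest_max(p, as.integer(colnames(p)))
    },
    lda = ,
    qda = {
      p <- predict(fit, nd)$posterior
      pick_lowest_max(p, as.integer(colnames(p)))
    },
    svm = as.integer(as.character(predict(fit, nd))),
    knn = predict_knn(model, as.matrix(newx)),
    gmmb = predict_gmmb(fit, as.matrix(newx))
  )
}

predict_branch <- function(branch, nd) {
  if (!is.null(branch$constant)) {
    rep(as.integer(branch$constant[1]), nrow(nd))
  } else {
    as.integer(as.character(predict(branch, nd)))
  }
}

predict_hier <- function(model, newx) {
  fit <- model$fit
  nd <- as.data.frame(newx)
  names(nd) <- c("yellow_pct", "brown_pct")
  grp <- if (!is.null(fit$modelA$constant)) {
    rep(fit$modelA$constant[1], nrow(nd))
  } else if (fit$stepA_kind == "svm") {
    as.character(predict(fit$modelA, nd))
  } else {
    as.character(predict(fit$modelA, nd)$class)
  }
  out <- integer(nrow(nd))
  out[grp == "medium"] <- 3L
  if (any(grp == "low")) {
    out[grp == "low"] <- predict_branch(fit$low, nd[grp == "low", , drop = FALSE])
  }
  if (any(grp == "high")) {
    out[grp == "high"] <- predict_branch(fit$high, nd[grp == "high", , drop = FALSE])
  }
  out
}

#' Ground-truth rating rule wrapped as a classifier
#'
#' Wraps [bayes_rating()] in the `idc_model` interface so the planted
#' ground-truth rule can be queried, plotted and mapped as a population
#' canopy graph exactly like a trained classifier.
#'
#' @param b_necrosis brown threshold passed to [bayes_rating()].
#' @return an `idc_model` of kind `"bayes"`.
#' @export
bayes_model <- function(b_necrosis = 15) {
  structure(list(kind = "bayes", fit = list(b_necrosis = b_necrosis),
                 classes = 1:5, n_train = 0L, seed = NA_integer_,
                 hyper = list(), train_data = NULL),
            class = "idc_model")
}

#' Predict severity ratings
#'
#' @param object an `idc_model`.
#' @param newdata data.frame or matrix with `yellow_pct` and `brown_pct`
#'   columns (or two unnamed columns in that order).
#' @param ... unused.
#' @return integer vector of predicted ratings, one per row (empty input
#'   gives an empty vector).
#' @export
predict.idc_model <- function(object, newdata, ...) {
  newx <- feature_frame(newdata)
  if (nrow(newx) == 0L) return(integer(0))
  if (object$kind == "bayes") {
    return(as.integer(bayes_rating(newx$yellow_pct, newx$brown_pct,
                                   object$fit$b_necrosis)))
  }
  if (startsWith(object$kind, "hier_")) {
    predict_hier(object, newx)
  } else {
    as.integer(predict_flat(object, newx))
  }
}

#' Step-A susceptibility group predictions of a hierarchical model
#'
#' @param object a hierarchical `idc_model`.
#' @param newdata as in [predict.idc_model()].
#' @return factor of groups with levels `low`, `medium`, `high`.
#' @export
predict_group <- function(object, newdata) {
  stopifnot(inherits(object, "idc_model"),
            startsWith(object$kind, "hier_"))
  newx <- feature_frame(newdata)
  if (nrow(newx) == 0L) {
    return(factor(character(0), levels = c("low", "medium", "high")))
  }
  fit <- object$fit
  nd <- as.data.frame(newx)
  names(nd) <- c("yellow_pct", "brown_pct")
  grp <- if (!is.null(fit$modelA$constant)) {
    rep(fit$modelA$constant[1], nrow(nd))
  } else if (fit$stepA_kind == "svm") {
    as.character(predict(fit$modelA, nd))
  } else {
    as.character(predict(fit$modelA, nd)$class)
  }
  factor(grp, levels = c("low", "medium", "high"))
}

#' @export
print.idc_model <- function(x, ...) {
  cat(sprintf("IDC severity classifier (%s), trained on %d observations, classes {%s}\n",
              x$kind, x$n_train, paste(x$classes, collapse = ",")))
  invisible(x)
}

#' Summarize an IDC classifier on a labeled table
#'
#' @param object an `idc_model`.
#' @param data optional labeled feature table; when supplied, the summary
#'   reports the confusion matrix, accuracy, MPCA and misclassification
#'   cost on it.
#' @param ... unused.
#' @return a list of class `summary.idc_model`.
#' @export
summary.idc_model <- function(object, data = NULL, ...) {
  out <- list(kind = object$kind, n_train = object$n_train,
              classes = object$classes)
  if (!is.null(data)) {
    pred <- predict(object, data)
    cm <- confusion_matrix(data$rating, pred, classes = 1:5)
    out$confusion <- cm
    out$accuracy <- accuracy(cm)
    out$mpca <- suppressWarnings(mpca(cm))
    out$cost <- misclassification_cost(cm, build_cost_matrix(5))
  }
  structure(out, class = "summary.idc_model")
}

#' @export
print.summary.idc_model <- function(x, ...) {
  cat(sprintf("IDC severity classifier: %s (n_train = %d)\n", x$kind,
              x$n_train))
  if (!is.null(x$confusion)) {
    cat(sprintf("accuracy %.1f%%, MPCA %.1f%%, misclassification cost %.4f\n",
                x$accuracy, x$mpca, x$cost))
    print(unclass(x$confusion))
  }
  invisible(x)
}

#' Plot an IDC classifier as its population canopy graph
#'
#' @param x an `idc_model`.
#' @param step grid step in percent (see [population_canopy_graph()]).
#' @param ... passed to [plot.idc_pcg()].
#' @export
plot.idc_model <- function(x, step = 1, ...) {
  plot(population_canopy_graph(x, step = step), ...)
}

#' Save / load a classifier (versioned)
#'
#' @param model an `idc_model`.
#' @param path file path (RDS).
#' @return `read_model` returns the `idc_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "idc_model"))
  saveRDS(list(format = "idcscore-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "idcscore-model")) {
    idc_error("idc_invalid_input", "not an idcscore model file")
  }
  x$model
}
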