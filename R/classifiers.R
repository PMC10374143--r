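# Classifier adapters. Every adapter is a list with three elements:
#   name          display name
#   fit(data)     train on a labeled dataset (feature columns + y)
#   predict_prob(model, newdata)  minority-class probability per row
# The study machinery only ever talks to this contract; the underlying
# fits come from rpart, class, e1071, randomForest and nnet.

adapter <- function(name, fit, predict_prob) {
  structure(list(name = name, fit = fit, predict_prob = predict_prob),
            class = "classifier_adapter")
}

#' @export
print.classifier_adapter <- function(x, ...) {
  cat(sprintf("<classifier_adapter: %s>\n", x$name))
  invisible(x)
}

model_frame <- function(data) {
  df <- as.data.frame(feature_matrix(data))
  df$.y <- factor(data$y, levels = sort(unique(data$y)))
  df
}

prob_of_minority <- function(prob_matrix, y_train) {
  pos <- as.character(minority_label(y_train))
  if (pos %in% colnames(prob_matrix)) prob_matrix[, pos] else prob_matrix[, ncol(prob_matrix)]
}

#' Decision-tree classifier adapter
#'
#' A CART tree (rpart) behind the fit/predict-probability contract used
#' throughout the study machinery.
#'
#' @param maxdepth Maximum tree depth (`Inf` = unrestricted, capped at
#'   rpart's limit of 30).
#' @param minbucket Minimum observations in a leaf.
#' @param cp Cost-complexity parameter. The default 0 grows an unpruned
#'   tree and leaves capacity control to `maxdepth`/`minbucket`, which is
#'   what the cross-validated grid tunes; set a positive value to prune.
#' @return A classifier adapter (list with `fit` and `predict_prob`).
#' @family classifiers
#' @export
classifier_tree <- function(maxdepth = 30, minbucket = 1, cp = 0) {
  adapter(
    "DT",
    fit = function(data) {
      df <- model_frame(data)
      list(
        fit = rpart::rpart(.y ~ ., data = df, method = "class",
                           control = rpart::rpart.control(
                             maxdepth = min(maxdepth, 30), minbucket = minbucket,
                             minsplit = 3 * minbucket, cp = cp, xval = 0
                           )),
        y = data$y
      )
    },
    predict_prob = function(model, newdata) {
      p <- predict(model$fit, as.data.frame(feature_matrix(newdata)), type = "prob")
      prob_of_minority(p, model$y)
    }
  )
}

#' k-nearest-neighbor classifier adapter
#'
#' @param k Number of neighbors.
#' @family classifiers
#' @export
classifier_knn <- function(k = 5) {
  adapter(
    "KNN",
    fit = function(data) {
      list(X = feature_matrix(data), y = data$y, k = min(k, nrow(data)))
    },
    predict_prob = function(model, newdata) {
      pos <- minority_label(model$y)
      nn <- nn_indices(feature_matrix(newdata), model$X, k = model$k,
                       exclude_self = FALSE)
      apply(nn, 1L, function(ii) mean(model$y[ii] == pos))
    }
  )
}

#' Linear support-vector-machine adapter
#'
#' Linear-kernel SVM (e1071) with Platt-scaled probabilities.
#'
#' @param cost Soft-margin cost parameter.
#' @family classifiers
#' @export
classifier_svm_linear <- function(cost = 1) {
  adapter(
    "SVM",
    fit = function(data) {
      df <- model_frame(data)
      list(
        fit = e1071::svm(.y ~ ., data = df, kernel = "linear", cost = cost,
                         probability = TRUE),
        y = data$y
      )
    },
    predict_prob = function(model, newdata) {
      pred <- predict(model$fit, as.data.frame(feature_matrix(newdata)),
                      probability = TRUE)
      prob_of_minority(attr(pred, "probabilities"), model$y)
    }
  )
}

#' Random-forest classifier adapter
#'
#' @param ntree Number of trees.
#' @family classifiers
#' @export
classifier_forest <- function(ntree = 200) {
  adapter(
    "RF",
    fit = function(data) {
      df <- model_frame(data)
      list(
        fit = randomForest::randomForest(.y ~ ., data = df, ntree = ntree),
        y = data$y
      )
    },
    predict_prob = function(model, newdata) {
      p <- predict(model$fit, as.data.frame(feature_matrix(newdata)), type = "prob")
      prob_of_minority(p, model$y)
    }
  )
}

#' Feed-forward neural-network adapter
#'
#' Single-hidden-layer network (nnet) with weight decay.
#'
#' @param size Hidden units.
#' @param decay Weight decay.
#' @param maxit Training iterations.
#' @family classifiers
#' @export
classifier_nnet <- function(size = 5, decay = 1e-3, maxit = 200) {
  adapter(
    "NN",
    fit = function(data) {
      df <- model_frame(data)
      list(
        fit = nnet::nnet(.y ~ ., data = df, size = size, decay = decay,
                         maxit = maxit, trace = FALSE),
        y = data$y
      )
    },
    predict_prob = function(model, newdata) {
      p <- predict(model$fit, as.data.frame(feature_matrix(newdata)), type = "raw")
      pos <- as.character(minority_label(model$y))
      lev <- levels(factor(model$y, levels = sort(unique(model$y))))
      # nnet's raw output is P(second level)
      if (pos == lev[2]) as.vector(p) else 1 - as.vector(p)
    }
  )
}

#' Default decision-tree tuning grid
#'
#' The grid searched by 3-fold cross-validation when tuning the tree
#' classifier: maximum depth in \{3, 5, 10, unrestricted\} and minimum
#' leaf size in \{1, 5, 10\}.
#'
#' @return A tibble of parameter combinations.
#' @export
tree_tuning_grid <- function() {
  tidyr::expand_grid(maxdepth = c(3, 5, 10, 30), minbucket = c(1, 5, 10))
}

#' Tune a decision tree by stratified cross-validated grid search
#'
#' Fits every grid row with `cv_folds` stratified folds, scores held-out
#' predictions with [auprc()], and returns the adapter configured with
#' the best parameters (ties break toward the earlier grid row).
#'
#' @param data Training data.
#' @param grid Tibble of `maxdepth` / `minbucket` combinations.
#' @param cv_folds Number of folds.
#' @param seed Optional integer seed (fold assignment).
#' @return A list: `adapter` (tuned [classifier_tree()]), `params`
#'   (best grid row), `cv_auprc`.
#' @export
tune_tree <- function(data, grid = tree_tuning_grid(), cv_folds = 3, seed = NULL) {
  check_binary_labels(data)
  pos <- minority_label(data$y)
  with_seed_or_not(seed, {
    folds <- stratified_folds(data$y, cv_folds)
    scores <- purrr::pmap_dbl(grid, function(maxdepth, minbucket) {
      learner <- classifier_tree(maxdepth = maxdepth, minbucket = minbucket)
      prob <- rep(NA_real_, nrow(data))
      for (f in seq_len(cv_folds)) {
        test_idx <- which(folds == f)
        train <- data[-test_idx, , drop = FALSE]
        if (length(unique(train$y)) < 2L) {
          prob[test_idx] <- mean(train$y == pos)
          next
        }
        model <- learner$fit(train)
        prob[test_idx] <- learner$predict_prob(model, data[test_idx, , drop = FALSE])
      }
      if (length(unique(data$y)) < 2L) return(NA_real_)
      auprc(prob, as.numeric(data$y == pos))
    })
    best <- which.max(scores)
    list(
      adapter = classifier_tree(
        maxdepth = grid$maxdepth[best],
        minbucket = grid$minbucket[best]
      ),
      params = grid[best, ],
      cv_auprc = scores[best]
    )
  })
}
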