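# Filtering (hybrid) methods: SMOTE to balance, then a cleaning pass that
# may delete both original and synthetic rows. Provenance tags survive the
# cleaning so synthetic deletions are countable.

#' Iterative-partitioning filter (IPF)
#'
#' Splits the rows into `n_partitions` folds, trains one decision-tree
#' learner per fold, and removes every row misclassified by more than
#' half of the learners; repeats until three consecutive iterations each
#' remove less than 1\% of the current rows (or `max_clean_iters`).
#' A degenerate (single-class) fold draw is re-drawn once, then the
#' filter errors.
#'
#' @param data Labeled dataset.
#' @param n_partitions Number of folds / ensemble members.
#' @param max_clean_iters Hard cap on cleaning iterations.
#' @param seed Optional integer seed.
#' @return A [`resample_result`][new_resample_result] with attribute
#'   `removal_fractions`: the per-iteration fraction of rows removed.
#' @family filters
#' @export
ipf_filter <- function(data, n_partitions = 9, max_clean_iters = 25, seed = NULL) {
  check_binary_labels(data)
  src <- if (".source" %in% names(data)) data$.source else rep("original", nrow(data))
  with_seed_or_not(seed, {
    current <- data
    current$.source <- src
    fractions <- numeric()
    low_streak <- 0L
    for (it in seq_len(max_clean_iters)) {
      n <- nrow(current)
      folds <- draw_ipf_folds(current$y, n_partitions)
      votes_wrong <- rep(0L, n)
      for (f in sort(unique(folds))) {
        fit_rows <- which(folds == f)
        model <- fit_tree_hard(current[fit_rows, , drop = FALSE])
        pred <- predict_tree_hard(model, current)
        votes_wrong <- votes_wrong + as.integer(pred != current$y)
      }
      drop <- which(votes_wrong > n_partitions / 2)
      fractions <- c(fractions, length(drop) / n)
      low_streak <- if (length(drop) / n < 0.01) low_streak + 1L else 0L
      if (length(drop) > 0L) current <- current[-drop, , drop = FALSE]
      if (low_streak >= 3L) break
      if (nrow(current) < n_partitions || length(unique(current$y)) < 2L) break
    }
    out <- new_resample_result(current, data, "IPF")
    attr(out, "removal_fractions") <- fractions
    out
  })
}

# Fold assignment for IPF: random equal-size partition, re-drawn once if
# any fold is single-class (when a two-class fold is feasible at all).
draw_ipf_folds <- function(y, n_partitions) {
  n_partitions <- min(n_partitions, length(y))
  for (attempt in 1:2) {
    folds <- sample(rep_len(seq_len(n_partitions), length(y)))
    bad <- any(vapply(seq_len(n_partitions), function(f) {
      length(unique(y[folds == f])) < 2L
    }, logical(1)))
    if (!bad) return(folds)
    feasible <- min(table(y)) >= n_partitions
    if (!feasible) return(folds) # single-class folds unavoidable; learner handles it
  }
  abort("ipf_filter: could not draw partitions with both classes after a re-draw")
}

# Minimal hard-label tree learner for the IPF ensemble (class predictions
# only; falls back to the constant class on single-class folds).
fit_tree_hard <- function(train) {
  if (length(unique(train$y)) < 2L) {
    return(list(constant = train$y[1]))
  }
  df <- as.data.frame(feature_matrix(train))
  df$.y <- factor(train$y)
  # partitions are small (n / n_partitions rows), so the usual minsplit
  # default would leave every tree at its root
  list(fit = rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 4, minbucket = 2, xval = 0
                          )))
}

predict_tree_hard <- function(model, newdata) {
  if (!is.null(model$constant)) {
    return(rep(model$constant, nrow(newdata)))
  }
  df <- as.data.frame(feature_matrix(newdata))
  cls <- predict(model$fit, df, type = "class")
  out <- as.character(cls)
  if (is.numeric(newdata$y)) as.numeric(out) else out
}

#' SMOTE followed by a cleaning pass
#'
#' Applies [smote()] to full balance, then cleans the oversampled space:
#' `"tomek"` removes both members of every Tomek link, `"enn"` applies
#' ENN editing to both classes, `"ipf"` runs the iterative-partitioning
#' filter. Synthetic rows keep their `.source = "synthetic"` tag, so
#' deletions of synthetic points are visible in the result counts.
#'
#' @inheritParams smote
#' @param cleaner One of `"tomek"`, `"enn"`, `"ipf"`.
#' @param smote_params Named list overriding the SMOTE defaults
#'   (`k`, `target_ratio`).
#' @param cleaner_params Named list passed to the cleaner
#'   (e.g. `k` for ENN, `n_partitions` for IPF).
#' @family filters
#' @export
smote_then_clean <- function(data, cleaner = c("tomek", "enn", "ipf"),
                             smote_params = list(), cleaner_params = list(),
                             seed = NULL) {
  cleaner <- match.arg(cleaner)
  method <- c(tomek = "SMOTE-TL", enn = "SMOTE-ENN", ipf = "SMOTE-IPF")[[cleaner]]
  with_seed_or_not(seed, {
    sm <- do.call(smote, c(list(data = data), smote_params))
    oversampled <- sm$data
    cleaned <- switch(cleaner,
      tomek = {
        links <- find_tomek_links(oversampled)
        drop <- unique(c(links$i, links$j))
        if (length(drop)) oversampled[-drop, , drop = FALSE] else oversampled
      },
      enn = {
        res <- do.call(enn_edit, c(
          list(data = oversampled, edit_class = "all"), cleaner_params
        ))
        res$data
      },
      ipf = {
        res <- do.call(ipf_filter, c(list(data = oversampled), cleaner_params))
        res$data
      }
    )
    out <- new_resample_result(cleaned, data, method)
    # added = synthetic rows created by SMOTE; removed counts must reflect
    # deletions of ORIGINAL rows relative to the input, while synthetic
    # deletions show up as (created - surviving synthetic).
    pos <- minority_label(data$y)
    created <- sm$added
    surviving_synth <- cleaned[cleaned$.source == "synthetic", ]
    out$added <- created
    out$synthetic_removed <- created - c(
      minority = sum(surviving_synth$y == pos),
      majority = sum(surviving_synth$y != pos)
    )
    out
  })
}
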