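# Undersampling methods: all return subsets of the input rows (no new
# points are ever created). Distances are Euclidean on the feature
# columns; neighbor ties break toward the lower row index.

keep_rows_result <- function(data, keep_idx, method) {
  out <- data[sort(unique(keep_idx)), ]
  if (!".source" %in% names(out)) out$.source <- "original"
  new_resample_result(out, data, method)
}

#' Random undersampling
#'
#' Drops majority rows uniformly at random without replacement until the
#' minority/majority count ratio reaches `target_ratio`. Minority rows
#' are never removed.
#'
#' @inheritParams random_oversample
#' @family undersamplers
#' @export
random_undersample <- function(data, target_ratio = 1, seed = NULL) {
  check_binary_labels(data)
  cs <- class_split(data)
  if (length(cs$min_idx) == 0L || length(cs$maj_idx) == 0L) {
    abort("random_undersample: both classes must be non-empty")
  }
  n_keep <- min(
    length(cs$maj_idx),
    as.integer(round_half_up(length(cs$min_idx) / target_ratio))
  )
  with_seed_or_not(seed, {
    kept_maj <- if (n_keep < length(cs$maj_idx)) {
      sample(cs$maj_idx, n_keep)
    } else {
      cs$maj_idx
    }
    keep_rows_result(data, c(cs$min_idx, kept_maj), "Random Undersampling")
  })
}

#' NearMiss-3 undersampling
#'
#' Two-stage heuristic undersampling of the majority class. Stage 1
#' retains, for every minority row, its `m_keep` nearest majority rows
#' (union over minority rows). Stage 2 ranks the retained majority rows
#' by their average distance to their `n_dist` nearest minority rows and
#' keeps the smallest until the majority count matches the minority
#' count. Deterministic given the lower-index tie rule.
#'
#' @inheritParams random_oversample
#' @param m_keep Majority neighbors retained per minority row in stage 1.
#' @param n_dist Minority neighbors averaged over in stage 2.
#' @family undersamplers
#' @export
nearmiss3 <- function(data, m_keep = 3, n_dist = 3) {
  check_binary_labels(data)
  cs <- class_split(data)
  if (length(cs$min_idx) == 0L || length(cs$maj_idx) == 0L) {
    abort("nearmiss3: both classes must be non-empty")
  }
  X <- feature_matrix(data)
  Xmin <- X[cs$min_idx, , drop = FALSE]
  Xmaj <- X[cs$maj_idx, , drop = FALSE]
  mk <- min(m_keep, length(cs$maj_idx))
  nn_maj <- nn_indices(Xmin, Xmaj, k = mk, exclude_self = FALSE)
  retained <- sort(unique(as.vector(nn_maj)))
  nd <- min(n_dist, length(cs$min_idx))
  d2 <- dist_sq(Xmaj[retained, , drop = FALSE], Xmin)
  avg_dist <- apply(d2, 1L, function(row) mean(sqrt(sort(row)[seq_len(nd)])))
  target <- min(length(retained), length(cs$min_idx))
  keep_local <- order(avg_dist, retained)[seq_len(target)]
  keep_rows_result(data, c(cs$min_idx, cs$maj_idx[retained[keep_local]]), "Near-miss")
}

#' Find Tomek links
#'
#' A pair of opposite-class rows (x, y) is a Tomek link when no third row
#' z is strictly closer to either of them than they are to each other —
#' i.e. x and y are mutual nearest neighbors of opposite class.
#'
#' @param data Labeled dataset with at least 2 rows.
#' @return A tibble with integer columns `i`, `j` (row indices, `i < j`),
#'   possibly empty.
#' @export
find_tomek_links <- function(data) {
  if (nrow(data) < 2L) abort("find_tomek_links: need at least 2 rows")
  X <- feature_matrix(data)
  d2 <- dist_sq(X)
  diag(d2) <- Inf
  nn_d2 <- apply(d2, 1L, min)
  links <- list()
  for (a in seq_len(nrow(data) - 1L)) {
    for (b in seq(a + 1L, nrow(data))) {
      if (data$y[a] == data$y[b]) next
      if (d2[a, b] <= nn_d2[a] && d2[a, b] <= nn_d2[b]) {
        links[[length(links) + 1L]] <- c(a, b)
      }
    }
  }
  if (length(links) == 0L) {
    return(tibble(i = integer(), j = integer()))
  }
  m <- do.call(rbind, links)
  tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

#' Tomek-link undersampling
#'
#' Removes the majority member of every Tomek link; minority rows are
#' always kept.
#'
#' @inheritParams find_tomek_links
#' @family undersamplers
#' @export
tomek_undersample <- function(data) {
  check_binary_labels(data)
  cs <- class_split(data)
  links <- find_tomek_links(data)
  linked <- unique(c(links$i, links$j))
  drop <- intersect(linked, cs$maj_idx)
  keep_rows_result(data, setdiff(seq_len(nrow(data)), drop), "Tomek Link")
}

# One ENN editing pass: rows of the edited class whose k-NN majority vote
# (self excluded, computed on the full current data) disagrees with their
# own label are deleted. Vote ties (possible for even k) keep the row.
enn_removals <- function(data, k, edit_class, pos) {
  X <- feature_matrix(data)
  kk <- min(k, nrow(data) - 1L)
  nn <- nn_indices(X, k = kk)
  editable <- switch(edit_class,
    majority = which(data$y != pos),
    minority = which(data$y == pos),
    all = seq_len(nrow(data))
  )
  editable[vapply(editable, function(ii) {
    votes_for_own <- sum(data$y[nn[ii, ]] == data$y[ii])
    votes_for_own < kk - votes_for_own
  }, logical(1))]
}

#' Edited nearest-neighbor (ENN) undersampling
#'
#' Deletes each row of `edit_class` whose majority vote among its `k`
#' nearest neighbors (self excluded) disagrees with its own label. A
#' single pass; all votes are computed on the original data. In
#' undersampling mode only majority rows are edited; `edit_class = "all"`
#' gives the hybrid-cleaning orientation used inside SMOTE-ENN.
#'
#' @inheritParams random_oversample
#' @param k Neighborhood size for the vote.
#' @param edit_class Which rows may be deleted: `"majority"`,
#'   `"minority"` or `"all"`.
#' @family undersamplers
#' @export
enn_edit <- function(data, k = 3, edit_class = c("majority", "all", "minority")) {
  check_binary_labels(data)
  edit_class <- match.arg(edit_class)
  if (nrow(data) < k + 1L) abort("enn_edit: need at least k + 1 rows")
  pos <- minority_label(data$y)
  drop <- enn_removals(data, k, edit_class, pos)
  keep_rows_result(data, setdiff(seq_len(nrow(data)), drop), "ENN")
}

#' Repeated ENN (RENN)
#'
#' Applies [enn_edit()] repeatedly, recomputing neighborhoods on the
#' shrinking dataset, until a pass removes nothing (or `max_iter`).
#'
#' @inheritParams enn_edit
#' @param max_iter Safety cap on editing passes.
#' @family undersamplers
#' @export
renn <- function(data, k = 3, edit_class = "majority", max_iter = 100) {
  check_binary_labels(data)
  # the minority class is pinned to the input's orientation so that later
  # passes keep editing the same class even if the counts cross over
  pos <- minority_label(data$y)
  current <- data
  for (it in seq_len(max_iter)) {
    if (nrow(current) < k + 1L || length(unique(current$y)) < 2L) break
    drop <- enn_removals(current, k, edit_class, pos)
    if (length(drop) == 0L) break
    current <- current[-drop, , drop = FALSE]
  }
  current$.source <- "original"
  new_resample_result(current, data, "RENN")
}

#' All-KNN undersampling
#'
#' Applies ENN editing for k = 1, 2, ..., `k_max` in sequence on the
#' progressively cleaned data; a row removed at any k stays removed.
#'
#' @inheritParams enn_edit
#' @param k_max Largest neighborhood size.
#' @family undersamplers
#' @export
all_knn <- function(data, k_max = 3, edit_class = "majority") {
  check_binary_labels(data)
  pos <- minority_label(data$y)
  current <- data
  for (k in seq_len(k_max)) {
    if (nrow(current) < k + 1L || length(unique(current$y)) < 2L) break
    drop <- enn_removals(current, k, edit_class, pos)
    if (length(drop) > 0L) current <- current[-drop, , drop = FALSE]
  }
  current$.source <- "original"
  new_resample_result(current, data, "ALL KNN")
}

#' Condensed nearest-neighbor (CNN) undersampling
#'
#' Seeks a small majority subset that still lets 1-NN classify every
#' input row correctly. The store starts with all minority rows plus one
#' random majority row; repeated passes over the remaining majority rows
#' (in seeded random order) add any row the current store misclassifies
#' by 1-NN, until a full pass adds nothing.
#'
#' @inheritParams random_oversample
#' @family undersamplers
#' @export
cnn_condense <- function(data, seed = NULL) {
  check_binary_labels(data)
  cs <- class_split(data)
  if (length(cs$min_idx) == 0L || length(cs$maj_idx) == 0L) {
    abort("cnn_condense: both classes must be non-empty")
  }
  X <- feature_matrix(data)
  with_seed_or_not(seed, {
    scan_order <- sample(cs$maj_idx)
    store <- c(cs$min_idx, scan_order[1L])
    remaining <- scan_order[-1L]
    repeat {
      added <- FALSE
      still <- integer()
      for (ii in remaining) {
        d2 <- dist_sq(X[ii, , drop = FALSE], X[store, , drop = FALSE])
        nn <- store[order(d2[1, ], store)[1L]]
        if (data$y[nn] != data$y[ii]) {
          store <- c(store, ii)
          added <- TRUE
        } else {
          still <- c(still, ii)
        }
      }
      remaining <- still
      if (!added || length(remaining) == 0L) break
    }
    keep_rows_result(data, store, "CNN")
  })
}

#' One-sided selection (OSS)
#'
#' CNN condensation of the majority class followed by Tomek-link removal
#' of the remaining noisy majority rows.
#'
#' @inheritParams cnn_condense
#' @family undersamplers
#' @export
oss <- function(data, seed = NULL) {
  pos <- minority_label(data$y)
  condensed <- cnn_condense(data, seed = seed)$data
  links <- find_tomek_links(condensed)
  linked <- unique(c(links$i, links$j))
  # only members of the input's majority class are removed, regardless of
  # which class is rarer after condensation
  drop <- linked[condensed$y[linked] != pos]
  out <- if (length(drop)) condensed[-drop, , drop = FALSE] else condensed
  out$.source <- "original"
  new_resample_result(out, data, "OSS")
}

#' Neighborhood cleaning rule (NCR)
#'
#' Two deletion rules, both evaluated on the original data with `k`
#' nearest neighbors: (A) a majority row misclassified by its k-NN vote
#' is deleted; (B) for every minority row misclassified by its k-NN vote,
#' the majority rows among its neighbors are deleted.
#'
#' @inheritParams enn_edit
#' @family undersamplers
#' @export
ncr <- function(data, k = 3) {
  check_binary_labels(data)
  if (nrow(data) < k + 1L) abort("ncr: need at least k + 1 rows")
  pos <- minority_label(data$y)
  X <- feature_matrix(data)
  kk <- min(k, nrow(data) - 1L)
  nn <- nn_indices(X, k = kk)
  misclassified <- vapply(seq_len(nrow(data)), function(ii) {
    votes_for_own <- sum(data$y[nn[ii, ]] == data$y[ii])
    votes_for_own < kk - votes_for_own
  }, logical(1))
  drop_a <- which(misclassified & data$y != pos)
  bad_min <- which(misclassified & data$y == pos)
  drop_b <- unlist(lapply(bad_min, function(ii) {
    nbrs <- nn[ii, ]
    nbrs[data$y[nbrs] != pos]
  }))
  drop <- unique(c(drop_a, drop_b))
  keep_rows_result(data, setdiff(seq_len(nrow(data)), drop), "NCR")
}

#' Instance-hardness-threshold (IHT) undersampling
#'
#' Estimates each row's out-of-fold predicted probability of its own
#' class by `cv_folds` cross-fitting of a probability-estimating learner,
#' then removes the hardest majority rows (lowest own-class probability)
#' until the minority/majority ratio reaches `target_ratio`.
#'
#' @inheritParams random_oversample
#' @param learner A classifier adapter (see [classifier_tree()]): a list
#'   with `fit(data)` and `predict_prob(model, newdata)` returning the
#'   minority-class probability.
#' @param cv_folds Number of stratified cross-fitting folds.
#' @family undersamplers
#' @export
iht <- function(data, learner = classifier_tree(), cv_folds = 3,
                target_ratio = 1, seed = NULL) {
  check_binary_labels(data)
  cs <- class_split(data)
  if (length(cs$min_idx) == 0L || length(cs$maj_idx) == 0L) {
    abort("iht: both classes must be non-empty")
  }
  with_seed_or_not(seed, {
    folds <- stratified_folds(data$y, cv_folds)
    prob_pos <- rep(NA_real_, nrow(data))
    for (f in seq_len(cv_folds)) {
      test_idx <- which(folds == f)
      train <- data[-test_idx, , drop = FALSE]
      if (length(unique(train$y)) < 2L) {
        prob_pos[test_idx] <- mean(train$y == cs$pos)
        next
      }
      model <- learner$fit(train)
      prob_pos[test_idx] <- learner$predict_prob(model, data[test_idx, , drop = FALSE])
    }
    own_prob <- ifelse(data$y == cs$pos, prob_pos, 1 - prob_pos)
    n_keep <- min(
      length(cs$maj_idx),
      as.integer(round_half_up(length(cs$min_idx) / target_ratio))
    )
    n_drop <- length(cs$maj_idx) - n_keep
    drop <- if (n_drop > 0) {
      cs$maj_idx[order(own_prob[cs$maj_idx], cs$maj_idx)[seq_len(n_drop)]]
    } else {
      integer()
    }
    keep_rows_result(data, setdiff(seq_len(nrow(data)), drop), "IHT")
  })
}

# Stratified fold assignment: shuffles within each class and deals fold
# ids round-robin, so every fold sees both classes whenever possible.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}
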