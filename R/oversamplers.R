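# Oversampling methods. All operate on the feature columns returned by
# feature_matrix() with Euclidean distance and label the synthetic rows
# with the minority class.

# Number of minority rows to add so that minority/majority reaches `ratio`.
oversample_deficit <- function(n_min, n_maj, ratio) {
  max(0L, as.integer(round_half_up(ratio * n_maj)) - n_min)
}

# Build a synthetic row tibble from parent rows and interpolation weights.
interpolate_rows <- function(data, seed_idx, nbr_idx, u) {
  X <- feature_matrix(data)
  newX <- X[seed_idx, , drop = FALSE] +
    u * (X[nbr_idx, , drop = FALSE] - X[seed_idx, , drop = FALSE])
  out <- as_tibble(as.data.frame(newX))
  out$y <- data$y[seed_idx]
  out
}

append_synthetic <- function(data, synth, method) {
  base <- data
  base$.source <- "original"
  if (nrow(synth)) {
    synth$.source <- "synthetic"
    keep <- intersect(names(base), names(synth))
    res <- bind_rows(base, synth[keep])
  } else {
    res <- base
  }
  new_resample_result(res, data, method)
}

#' Random oversampling
#'
#' Duplicates minority rows uniformly at random with replacement until the
#' minority/majority count ratio reaches `target_ratio`.
#'
#' @param data Labeled dataset (binary `y`, minority = rarer class).
#' @param target_ratio Desired minority/majority ratio after resampling
#'   (1.0 = full balance).
#' @param seed Optional integer seed.
#' @return A [`resample_result`][new_resample_result].
#' @family oversamplers
#' @export
random_oversample <- function(data, target_ratio = 1, seed = NULL) {
  check_binary_labels(data)
  cs <- class_split(data)
  if (length(cs$min_idx) == 0L || length(cs$maj_idx) == 0L) {
    abort("random_oversample: both classes must be non-empty")
  }
  g <- oversample_deficit(length(cs$min_idx), length(cs$maj_idx), target_ratio)
  with_seed_or_not(seed, {
    picks <- if (g > 0) sample(cs$min_idx, g, replace = TRUE) else integer()
    synth <- data[picks, setdiff(names(data), c("eta", ".interval", ".source"))]
    append_synthetic(data, as_tibble(synth), "Random Oversampling")
  })
}

# Shared SMOTE core: generate `g` synthetic points by interpolating seed
# minority rows toward one of their k nearest minority neighbors.
# `seed_pool` restricts which minority rows may be picked as seeds.
smote_core <- function(data, g, k, seed_pool = NULL) {
  cs <- class_split(data)
  min_idx <- cs$min_idx
  if (length(min_idx) < 2L) abort("SMOTE: minority class must have at least 2 rows")
  k <- min(k, length(min_idx) - 1L)
  X <- feature_matrix(data)
  nn <- nn_indices(X[min_idx, , drop = FALSE], k = k) # indices into min_idx
  pool <- seed_pool %||% seq_along(min_idx)
  seeds <- sample(pool, g, replace = TRUE)
  nbrs <- vapply(seeds, function(si) nn[si, sample.int(k, 1L)], integer(1))
  u <- stats::runif(g)
  interpolate_rows(data, min_idx[seeds], min_idx[nbrs], u)
}

#' SMOTE oversampling
#'
#' Synthetic minority oversampling: repeatedly picks a random minority
#' row, one of its `k` nearest minority neighbors, and emits a point
#' uniformly interpolated between them, until the target class ratio is
#' reached.
#'
#' @inheritParams random_oversample
#' @param k Number of minority nearest neighbors (capped at minority
#'   count - 1).
#' @family oversamplers
#' @export
smote <- function(data, k = 5, target_ratio = 1, seed = NULL) {
  check_binary_labels(data)
  cs <- class_split(data)
  if (length(cs$min_idx) < 2L) abort("smote: minority class must have at least 2 rows")
  g <- oversample_deficit(length(cs$min_idx), length(cs$maj_idx), target_ratio)
  with_seed_or_not(seed, {
    synth <- if (g > 0) smote_core(data, g, k) else data[0, c(colnames(feature_matrix(data)), "y")]
    append_synthetic(data, synth, "SMOTE")
  })
}

#' ADASYN oversampling
#'
#' Adaptive synthetic oversampling: each minority row gets a hardness
#' score `r = (majority among its k nearest neighbors over all rows) / k`;
#' the synthetic budget is allocated proportionally to the normalized
#' scores (largest-remainder rounding) and points are generated by
#' SMOTE-style interpolation with minority neighbors. If every score is
#' zero (minority nowhere near majority) the budget falls back to a
#' uniform allocation.
#'
#' @inheritParams smote
#' @family oversamplers
#' @export
adasyn <- function(data, k = 5, target_ratio = 1, seed = NULL) {
  check_binary_labels(data)
  cs <- class_split(data)
  n_min <- length(cs$min_idx)
  if (n_min < 2L) abort("adasyn: minority class must have at least 2 rows")
  g <- oversample_deficit(n_min, length(cs$maj_idx), target_ratio)
  with_seed_or_not(seed, {
    if (g == 0L) {
      return(append_synthetic(data, data[0, c(colnames(feature_matrix(data)), "y")], "ADASYN"))
    }
    X <- feature_matrix(data)
    kk <- min(k, nrow(data) - 1L)
    nn_all <- nn_indices(X, k = kk)
    r <- vapply(cs$min_idx, function(ii) {
      sum(data$y[nn_all[ii, ]] != cs$pos) / kk
    }, numeric(1))
    w <- if (sum(r) == 0) rep(1 / n_min, n_min) else r / sum(r)
    raw <- w * g
    alloc <- floor(raw)
    short <- g - sum(alloc)
    if (short > 0) {
      extra <- order(raw - alloc, seq_along(raw), decreasing = TRUE)[seq_len(short)]
      alloc[extra] <- alloc[extra] + 1L
    }
    k_min <- min(k, n_min - 1L)
    nn_min <- nn_indices(X[cs$min_idx, , drop = FALSE], k = k_min)
    seeds <- rep(seq_len(n_min), alloc)
    nbrs <- vapply(seeds, function(si) nn_min[si, sample.int(k_min, 1L)], integer(1))
    u <- stats::runif(length(seeds))
    synth <- interpolate_rows(data, cs$min_idx[seeds], cs$min_idx[nbrs], u)
    append_synthetic(data, synth, "ADASYN")
  })
}

#' Borderline-SMOTE oversampling (variant 1)
#'
#' Only minority rows in the DANGER set seed the interpolation: rows whose
#' `m` nearest neighbors (over all rows) contain at least `m/2` but fewer
#' than `m` majority rows. Rows with all-majority neighborhoods are
#' treated as noise and excluded; safe rows contribute nothing. Neighbors
#' for interpolation are drawn from the minority class (variant 1). An
#' empty DANGER set returns the input unchanged with a warning.
#'
#' @inheritParams smote
#' @param m Neighborhood size used to classify rows as safe, DANGER or
#'   noise.
#' @family oversamplers
#' @export
borderline_smote <- function(data, m = 5, k = 5, target_ratio = 1, seed = NULL) {
  check_binary_labels(data)
  cs <- class_split(data)
  n_min <- length(cs$min_idx)
  if (n_min < 2L) abort("borderline_smote: minority class must have at least 2 rows")
  g <- oversample_deficit(n_min, length(cs$maj_idx), target_ratio)
  with_seed_or_not(seed, {
    X <- feature_matrix(data)
    mm <- min(m, nrow(data) - 1L)
    nn_all <- nn_indices(X, k = mm)
    n_maj_nbr <- vapply(cs$min_idx, function(ii) {
      sum(data$y[nn_all[ii, ]] != cs$pos)
    }, numeric(1))
    danger <- which(n_maj_nbr >= mm / 2 & n_maj_nbr < mm)
    if (length(danger) == 0L || g == 0L) {
      if (length(danger) == 0L && g > 0L) {
        warn("borderline_smote: DANGER set is empty; returning input unchanged")
      }
      return(append_synthetic(data, data[0, c(colnames(feature_matrix(data)), "y")], "Borderline SMOTE"))
    }
    synth <- smote_core(data, g, k, seed_pool = danger)
    append_synthetic(data, synth, "Borderline SMOTE")
  })
}
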