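# Uniform resampler registry: every method is exposed under its display
# name as callable(data, params, seed). The study machinery, the CLI and
# users address methods only through these names.

#' The resampler registry
#'
#' Returns the named list of available resamplers. Each entry has
#' `family` (`"oversampling"`, `"undersampling"`, `"filtering"`) and
#' `fn(data, params, seed)`. `include_optional = TRUE` adds the
#' SVM-SMOTE and k-means-SMOTE variants, which depend on an auxiliary
#' learner/clusterer and are excluded from the default study set.
#'
#' @param include_optional Include the optional SMOTE variants.
#' @return Named list of registry entries.
#' @export
#' @examples
#' names(resampler_registry())
resampler_registry <- function(include_optional = FALSE) {
  wrap <- function(fn, seeded = TRUE) {
    if (seeded) {
      function(data, params = list(), seed = NULL) {
        do.call(fn, c(list(data = data), params, list(seed = seed)))
      }
    } else {
      function(data, params = list(), seed = NULL) {
        do.call(fn, c(list(data = data), params))
      }
    }
  }
  reg <- list(
    "Random Oversampling" = list(family = "oversampling", fn = wrap(random_oversample)),
    "SMOTE"               = list(family = "oversampling", fn = wrap(smote)),
    "ADASYN"              = list(family = "oversampling", fn = wrap(adasyn)),
    "Borderline SMOTE"    = list(family = "oversampling", fn = wrap(borderline_smote)),
    "Random Undersampling" = list(family = "undersampling", fn = wrap(random_undersample)),
    "Near-miss"           = list(family = "undersampling", fn = wrap(nearmiss3, seeded = FALSE)),
    "Tomek Link"          = list(family = "undersampling", fn = wrap(tomek_undersample, seeded = FALSE)),
    "CNN"                 = list(family = "undersampling", fn = wrap(cnn_condense)),
    "ENN"                 = list(family = "undersampling", fn = wrap(enn_edit, seeded = FALSE)),
    "RENN"                = list(family = "undersampling", fn = wrap(renn, seeded = FALSE)),
    "ALL KNN"             = list(family = "undersampling", fn = wrap(all_knn, seeded = FALSE)),
    "OSS"                 = list(family = "undersampling", fn = wrap(oss)),
    "NCR"                 = list(family = "undersampling", fn = wrap(ncr, seeded = FALSE)),
    "IHT"                 = list(family = "undersampling", fn = wrap(iht)),
    "SMOTE-TL"  = list(family = "filtering", fn = function(data, params = list(), seed = NULL) {
      do.call(smote_then_clean, c(list(data = data, cleaner = "tomek"), params, list(seed = seed)))
    }),
    "SMOTE-ENN" = list(family = "filtering", fn = function(data, params = list(), seed = NULL) {
      do.call(smote_then_clean, c(list(data = data, cleaner = "enn"), params, list(seed = seed)))
    }),
    "SMOTE-IPF" = list(family = "filtering", fn = function(data, params = list(), seed = NULL) {
      do.call(smote_then_clean, c(list(data = data, cleaner = "ipf"), params, list(seed = seed)))
    })
  )
  if (include_optional) {
    reg <- c(reg, list(
      "SVM SMOTE"     = list(family = "oversampling", fn = wrap(svm_smote)),
      "K-means SMOTE" = list(family = "oversampling", fn = wrap(kmeans_smote))
    ))
  }
  reg
}

#' Apply a registered resampler by name
#'
#' @param data Labeled dataset.
#' @param method Registry name (e.g. `"SMOTE-TL"`, `"ALL KNN"`).
#' @param params Named list of method parameters.
#' @param seed Optional integer seed.
#' @return A [`resample_result`][new_resample_result].
#' @export
apply_resampler <- function(data, method, params = list(), seed = NULL) {
  reg <- resampler_registry(include_optional = TRUE)
  if (!method %in% names(reg)) {
    abort(sprintf(
      "unknown resampler '%s'; available: %s",
      method, paste(names(reg), collapse = ", ")
    ))
  }
  reg[[method]]$fn(data, params, seed)
}

#' SVM-SMOTE oversampling (optional variant)
#'
#' Borderline variant that uses the minority support vectors of a linear
#' SVM as interpolation seeds.
#'
#' @inheritParams smote
#' @family oversamplers
#' @export
svm_smote <- function(data, k = 5, target_ratio = 1, seed = NULL) {
  check_binary_labels(data)
  cs <- class_split(data)
  if (length(cs$min_idx) < 2L) abort("svm_smote: minority class must have at least 2 rows")
  g <- oversample_deficit(length(cs$min_idx), length(cs$maj_idx), target_ratio)
  with_seed_or_not(seed, {
    if (g == 0L) {
      return(append_synthetic(data, data[0, c(colnames(feature_matrix(data)), "y")], "SVM SMOTE"))
    }
    df <- model_frame(data)
    fit <- e1071::svm(.y ~ ., data = df, kernel = "linear")
    sv <- fit$index
    seeds <- match(intersect(sv, cs$min_idx), cs$min_idx)
    if (length(seeds) == 0L) seeds <- seq_along(cs$min_idx)
    synth <- smote_core(data, g, k, seed_pool = seeds)
    append_synthetic(data, synth, "SVM SMOTE")
  })
}

#' k-means-SMOTE oversampling (optional variant)
#'
#' Clusters all rows with k-means and applies SMOTE interpolation only
#' within clusters where the minority class is at least half of the
#' cluster, allocating the synthetic budget proportionally to cluster
#' minority counts.
#'
#' @inheritParams smote
#' @param n_clusters Number of k-means clusters.
#' @family oversamplers
#' @export
kmeans_smote <- function(data, k = 5, n_clusters = 4, target_ratio = 1, seed = NULL) {
  check_binary_labels(data)
  cs <- class_split(data)
  if (length(cs$min_idx) < 2L) abort("kmeans_smote: minority class must have at least 2 rows")
  g <- oversample_deficit(length(cs$min_idx), length(cs$maj_idx), target_ratio)
  with_seed_or_not(seed, {
    if (g == 0L) {
      return(append_synthetic(data, data[0, c(colnames(feature_matrix(data)), "y")], "K-means SMOTE"))
    }
    X <- feature_matrix(data)
    n_clusters <- min(n_clusters, nrow(unique(as.data.frame(X))))
    cl <- stats::kmeans(X, centers = n_clusters, nstart = 3)$cluster
    min_frac <- vapply(seq_len(n_clusters), function(cc) {
      mean(data$y[cl == cc] == cs$pos)
    }, numeric(1))
    eligible <- which(min_frac >= 0.5)
    pool <- which(cl[cs$min_idx] %in% eligible) # indices into min_idx
    if (length(pool) < 2L) pool <- seq_along(cs$min_idx)
    synth <- smote_core(data, g, k, seed_pool = pool)
    append_synthetic(data, synth, "K-means SMOTE")
  })
}
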