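# Data-complexity measures, oriented so that higher values mean a more
# complex (harder) classification problem, each in [0, 1].

#' Maximum individual feature efficiency (F3), complexity orientation
#'
#' For each feature, the class-overlap region is
#' \[max of per-class minima, min of per-class maxima\]; the feature's
#' overlap fraction is the share of rows whose value falls inside it
#' (inclusive). F3 is the minimum overlap fraction over features: 0 when
#' some single feature separates the classes perfectly, 1 when every
#' feature's classes overlap completely.
#'
#' @param data Labeled dataset (binary `y`; binary features participate
#'   as 0/1 values).
#' @return F3 in \[0, 1\].
#' @export
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4, 3, 4, 5, 6), y = rep(0:1, each = 4))
#' f3(d) # 0.5
f3 <- function(data) {
  check_binary_labels(data)
  if (length(unique(data$y)) < 2L) abort("f3: labels must not be constant")
  X <- feature_matrix(data)
  if (ncol(X) < 1L) abort("f3: need at least one feature")
  cls <- data$y == minority_label(data$y)
  frac <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    lo <- max(min(v[cls]), min(v[!cls]))
    hi <- min(max(v[cls]), max(v[!cls]))
    if (lo > hi) 0 else mean(v >= lo & v <= hi)
  }, numeric(1))
  min(frac)
}

#' Intra/inter-class nearest-neighbor distance ratio (N2)
#'
#' `r` is the sum of each row's distance to its nearest same-class
#' neighbor divided by the sum of distances to the nearest other-class
#' neighbor; N2 = r / (1 + r) maps the ratio into \[0, 1\]. Near 0 for
#' tight, well-separated class clusters; large when classes interleave.
#' Scale-invariant. Degenerate all-duplicate data returns 0 with a
#' warning.
#'
#' @inheritParams f3
#' @return N2 in \[0, 1\].
#' @export
n2 <- function(data) {
  check_binary_labels(data)
  pos <- minority_label(data$y)
  if (min(table(data$y)) < 2L) abort("n2: need at least 2 rows per class")
  X <- feature_matrix(data)
  d2 <- dist_sq(X)
  diag(d2) <- Inf
  same <- outer(data$y, data$y, "==")
  intra <- vapply(seq_len(nrow(X)), function(ii) {
    sqrt(min(d2[ii, same[ii, ]]))
  }, numeric(1))
  inter <- vapply(seq_len(nrow(X)), function(ii) {
    sqrt(min(d2[ii, !same[ii, ]]))
  }, numeric(1))
  if (sum(inter) == 0) {
    warn("n2: degenerate data (zero inter-class distances); returning 0")
    return(0)
  }
  r <- sum(intra) / sum(inter)
  r / (1 + r)
}

#' Class-balance complexity (C2)
#'
#' The imbalance-ratio index
#' `IRm = ((C - 1) / C) * sum_c n_c / (n - n_c)` over the C classes;
#' C2 = 1 - 1 / IRm. Zero for balanced data, approaching 1 as the
#' minority class vanishes; depends only on the class counts.
#'
#' @inheritParams f3
#' @return C2 in \[0, 1\].
#' @export
#' @examples
#' d <- data.frame(x = 1, y = rep(c(0, 1), c(156, 10)))
#' c2(d) # 0.8723
c2 <- function(data) {
  if (!"y" %in% names(data)) abort("`data` must contain a label column `y`")
  counts <- as.vector(table(data$y))
  if (length(counts) < 2L) abort("c2: need at least 2 classes")
  n <- sum(counts)
  C <- length(counts)
  irm <- ((C - 1) / C) * sum(counts / (n - counts))
  1 - 1 / irm
}

#' Complexity profile of a dataset
#'
#' @inheritParams f3
#' @param dataset_id Optional identifier carried into the output.
#' @return A one-row tibble with columns `dataset`, `f3`, `n2`, `c2`.
#' @export
complexity_profile <- function(data, dataset_id = "dataset") {
  tibble(dataset = dataset_id, f3 = f3(data), n2 = n2(data), c2 = c2(data))
}

#' Stratify datasets by a complexity measure
#'
#' `"tertiles"` assigns three equal-frequency bins (`"low"`, `"mid"`,
#' `"high"`); `"top25"` / `"bottom25"` flag membership in the stated
#' quartile. Quantiles use the inclusive linear-interpolation convention
#' (type 7) and ties keep all tied members.
#'
#' @param values Numeric measure, one per dataset.
#' @param rule One of `"tertiles"`, `"top25"`, `"bottom25"`.
#' @return For tertiles, a factor of bin labels; for the quartile rules,
#'   a logical vector.
#' @export
#' @examples
#' stratify(1:100, "top25") # TRUE for 76..100
stratify <- function(values, rule = c("tertiles", "top25", "bottom25")) {
  rule <- match.arg(rule)
  if (rule %in% c("top25", "bottom25") && length(values) < 4L) {
    abort("quartile rules need at least 4 datasets")
  }
  if (length(unique(values)) == 1L) {
    warn("stratify: constant values; single stratum")
    return(switch(rule,
      tertiles = factor(rep("mid", length(values)), levels = c("low", "mid", "high")),
      top25 = rep(TRUE, length(values)),
      bottom25 = rep(TRUE, length(values))
    ))
  }
  switch(rule,
    tertiles = {
      qs <- stats::quantile(values, c(1 / 3, 2 / 3), type = 7)
      cut(values, c(-Inf, qs, Inf), labels = c("low", "mid", "high"))
    },
    top25 = values >= stats::quantile(values, 0.75, type = 7),
    bottom25 = values <= stats::quantile(values, 0.25, type = 7)
  )
}
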