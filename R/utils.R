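#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Round half away from zero. Quota arithmetic must not use base round()'s
# half-to-even rule.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL means "use the ambient stream".
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic child-seed derivation: a fixed multiplicative hash of
# (master, index), kept inside 32-bit signed range. Documented scheme so a
# study run is reproducible from its master seed alone.
derive_seed <- function(master, index) {
  m <- 2147483587
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807 + 1) %% m)
}

#' Extract the feature matrix of a labeled dataset
#'
#' Feature columns are every numeric column except the label `y` and the
#' bookkeeping columns `eta`, `.interval` and `.source`.
#'
#' @param data A data frame with a binary label column `y`.
#' @return A numeric matrix (rows x features).
#' @keywords internal
feature_matrix <- function(data) {
  keep <- setdiff(names(data), c("y", "eta", ".interval", ".source"))
  as.matrix(data[keep])
}

# Label value of the minority (positive) class. For 0/1-coded labels the
# positive class is always 1 (the simulator's coding) no matter the counts:
# resampling can leave class 0 the rarer one, and the positive class must
# not flip mid-pipeline. For other encodings the rarer label is positive,
# ties resolved toward the second level.
minority_label <- function(y) {
  tab <- table(y)
  if (length(tab) == 1L) {
    abort("both classes must be present in `y`")
  }
  lv <- names(tab)
  if (all(lv %in% c("0", "1"))) {
    return(if (is.numeric(y)) 1 else "1")
  }
  counts <- as.vector(tab)
  val <- if (counts[1] == counts[2]) lv[2] else lv[which.min(counts)]
  if (is.numeric(y)) as.numeric(val) else val
}

# Squared Euclidean distance matrix between rows of a and rows of b.
dist_sq <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Indices of the k nearest rows of `pool` to each row of `query`
# (Euclidean; ties broken by lower pool-row index; `exclude_self` removes
# the diagonal when query and pool are the same matrix).
#
# Returns an n_query x k integer matrix of pool-row indices.
nn_indices <- function(query, pool = query, k, exclude_self = identical(query, pool)) {
  d2 <- dist_sq(query, pool)
  if (exclude_self && nrow(d2) == ncol(d2)) diag(d2) <- Inf
  k <- max(min(k, ncol(d2) - as.integer(exclude_self)), 0L)
  if (k == 0L) return(matrix(integer(0), nrow = nrow(d2), ncol = 0L))
  out <- vapply(seq_len(nrow(d2)), function(i) {
    order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
  }, integer(k))
  matrix(t(out), nrow = nrow(d2), ncol = k)
}

# Nearest-neighbor distance (not squared) of each row to any other row.
nn_distance <- function(X) {
  d2 <- dist_sq(X)
  diag(d2) <- Inf
  sqrt(apply(d2, 1L, min))
}

check_binary_labels <- function(data) {
  if (!"y" %in% names(data)) abort("`data` must contain a label column `y`")
  vals <- unique(data$y)
  if (length(vals) > 2L) abort("`y` must be binary")
  invisible(data)
}
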