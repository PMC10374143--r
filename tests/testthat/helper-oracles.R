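# Brute-force oracles, written independently of the package internals:
# plain loops over explicit pairwise distances, re-deriving each rule
# from its definition. Used to pin the k-NN-based resamplers and the
# threshold metrics.

# Random small labeled dataset: two noisy Gaussian blobs, 2 features.
fuzz_dataset <- function(seed, n_min = NULL, n_maj = NULL) {
  set.seed(seed)
  n_min <- n_min %||% sample(3:8, 1)
  n_maj <- n_maj %||% sample(9:40, 1)
  sep <- runif(1, 0.5, 3)
  tibble::tibble(
    V1 = c(rnorm(n_maj), rnorm(n_min, mean = sep)),
    V2 = c(rnorm(n_maj), rnorm(n_min, mean = sep)),
    y = rep(c(0, 1), c(n_maj, n_min))
  )
}

oracle_dist <- function(data) {
  X <- as.matrix(data[setdiff(names(data), c("y", "eta", ".interval", ".source"))])
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      D[a, b] <- sqrt(sum((X[a, ] - X[b, ])^2))
    }
  }
  D
}

# k nearest neighbors of row i (self excluded, lower index wins ties).
oracle_neighbors <- function(D, i, k) {
  d <- D[i, ]
  d[i] <- Inf
  ord <- order(d, seq_along(d))
  ord[seq_len(min(k, length(d) - 1))]
}

oracle_enn_drop <- function(data, k = 3, edit_class = "majority", pos = NULL) {
  D <- oracle_dist(data)
  if (is.null(pos)) {
    tab <- table(data$y)
    pos <- if (tab[["1"]] == tab[["0"]]) 1 else as.numeric(names(which.min(tab)))
  }
  editable <- switch(edit_class,
    majority = which(data$y != pos),
    all = seq_len(nrow(data))
  )
  drop <- integer()
  for (i in editable) {
    nbrs <- oracle_neighbors(D, i, k)
    agree <- sum(data$y[nbrs] == data$y[i])
    if (agree < length(nbrs) - agree) drop <- c(drop, i)
  }
  drop
}

oracle_renn_keep <- function(data, k = 3, max_iter = 100) {
  tab <- table(data$y)
  pos <- if (tab[["1"]] == tab[["0"]]) 1 else as.numeric(names(which.min(tab)))
  keep <- seq_len(nrow(data))
  for (it in seq_len(max_iter)) {
    cur <- data[keep, ]
    if (nrow(cur) < k + 1 || length(unique(cur$y)) < 2) break
    drop <- oracle_enn_drop(cur, k, pos = pos)
    if (length(drop) == 0) break
    keep <- keep[-drop]
  }
  keep
}

oracle_allknn_keep <- function(data, k_max = 3) {
  tab <- table(data$y)
  pos <- if (tab[["1"]] == tab[["0"]]) 1 else as.numeric(names(which.min(tab)))
  keep <- seq_len(nrow(data))
  for (k in seq_len(k_max)) {
    cur <- data[keep, ]
    if (nrow(cur) < k + 1 || length(unique(cur$y)) < 2) break
    drop <- oracle_enn_drop(cur, k, pos = pos)
    if (length(drop) > 0) keep <- keep[-drop]
  }
  keep
}

oracle_tomek_pairs <- function(data) {
  D <- oracle_dist(data)
  n <- nrow(data)
  links <- list()
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a || data$y[a] == data$y[b]) next
      is_link <- TRUE
      for (z in seq_len(n)) {
        if (z == a || z == b) next
        if (D[a, z] < D[a, b] || D[b, z] < D[a, b]) {
          is_link <- FALSE
          break
        }
      }
      if (is_link) links[[length(links) + 1]] <- c(a, b)
    }
  }
  links
}

oracle_ncr_drop <- function(data, k = 3) {
  D <- oracle_dist(data)
  tab <- table(data$y)
  pos <- if (tab[["1"]] == tab[["0"]]) 1 else as.numeric(names(which.min(tab)))
  drop <- integer()
  for (i in seq_len(nrow(data))) {
    nbrs <- oracle_neighbors(D, i, k)
    agree <- sum(data$y[nbrs] == data$y[i])
    wrong <- agree < length(nbrs) - agree
    if (!wrong) next
    if (data$y[i] != pos) {
      drop <- c(drop, i)
    } else {
      drop <- c(drop, nbrs[data$y[nbrs] != pos])
    }
  }
  sort(unique(drop))
}

oracle_nearmiss3_keep_maj <- function(data, m_keep = 3, n_dist = 3) {
  D <- oracle_dist(data)
  tab <- table(data$y)
  pos <- if (tab[["1"]] == tab[["0"]]) 1 else as.numeric(names(which.min(tab)))
  min_idx <- which(data$y == pos)
  maj_idx <- which(data$y != pos)
  retained <- integer()
  for (i in min_idx) {
    d <- D[i, maj_idx]
    ord <- order(d, maj_idx)
    retained <- union(retained, maj_idx[ord[seq_len(min(m_keep, length(maj_idx)))]])
  }
  retained <- sort(retained)
  nd <- min(n_dist, length(min_idx))
  avg <- sapply(retained, function(j) mean(sort(D[j, min_idx])[seq_len(nd)]))
  target <- min(length(retained), length(min_idx))
  retained[order(avg, retained)[seq_len(target)]]
}

# ADASYN hardness ratios by brute-force k-NN over all rows.
oracle_adasyn_r <- function(data, k = 5) {
  D <- oracle_dist(data)
  tab <- table(data$y)
  pos <- if (tab[["1"]] == tab[["0"]]) 1 else as.numeric(names(which.min(tab)))
  min_idx <- which(data$y == pos)
  kk <- min(k, nrow(data) - 1)
  sapply(min_idx, function(i) {
    nbrs <- oracle_neighbors(D, i, kk)
    sum(data$y[nbrs] != pos) / kk
  })
}

# Average precision by direct enumeration over distinct thresholds.
oracle_auprc <- function(scores, labels) {
  pos <- labels == 1
  th <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(pos & sel) / sum(sel)
    rec <- sum(pos & sel) / sum(pos)
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# AUROC by exhaustive positive/negative pair counting (ties = 1/2).
oracle_auroc <- function(scores, labels) {
  p <- scores[labels == 1]
  q <- scores[labels == 0]
  total <- 0
  for (a in p) {
    for (b in q) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(p) * length(q))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
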