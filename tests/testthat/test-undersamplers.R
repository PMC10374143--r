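test_that("random undersampling drops only majority rows to the target ratio", {
  d <- generate_domain(domain_spec("low", 1, 1, seed = 1))
  res <- random_undersample(d, seed = 2)
  expect_equal(unname(res$removed["majority"]), 146)
  expect_equal(unname(res$removed["minority"]), 0)
  expect_equal(sum(res$data$y == 0), 10)
  bal <- tibble::tibble(V1 = 1:4, y = c(0, 0, 1, 1))
  expect_equal(nrow(random_undersample(bal, seed = 3)$data), 4L)
})

test_that("NearMiss-3 retains the minority-adjacent majority rows", {
  d <- tibble::tibble(V1 = c(0, 1, 2, 9, 3), y = c(0, 0, 0, 0, 1))
  res <- nearmiss3(d, m_keep = 3)
  kept_maj <- res$data$V1[res$data$y == 0]
  # stage 1 retains {0, 1, 2}; stage 2 keeps the closest (2) to balance
  expect_true(all(kept_maj %in% c(0, 1, 2)))
  expect_equal(kept_maj, 2)
  expect_true(3 %in% res$data$V1)
})

test_that("Tomek links are the mutual cross-class nearest-neighbor pairs", {
  d <- tibble::tibble(V1 = c(0.0, 0.3, 1.0, 1.1), y = c(0, 1, 0, 0))
  links <- find_tomek_links(d)
  expect_equal(nrow(links), 1L)
  expect_equal(c(links$i, links$j), c(1L, 2L))
  res <- tomek_undersample(d)
  expect_equal(res$data$V1, c(0.3, 1.0, 1.1))
  # single-class data has no links
  same <- tibble::tibble(V1 = 1:4, y = rep(1, 4))
  expect_equal(nrow(find_tomek_links(same)), 0L)
})

test_that("ENN removes majority rows out-voted by their neighborhoods", {
  d <- tibble::tibble(V1 = c(0.0, 0.1, 0.2, 5.0, 4.9, 5.1, 5.2),
                      y = c(0, 0, 0, 0, 1, 1, 1))
  res <- enn_edit(d, k = 3)
  expect_equal(sort(res$data$V1), c(0.0, 0.1, 0.2, 4.9, 5.1, 5.2))
  # well-separated clusters: nothing removed
  sep <- tibble::tibble(V1 = c(0, 0.1, 0.2, 0.3, 9, 9.1, 9.2), y = c(rep(0, 4), 1, 1, 1))
  expect_equal(nrow(enn_edit(sep, k = 3)$data), 7L)
})

test_that("CNN keeps all minority rows and satisfies its 1-NN stopping rule", {
  # one tight majority cluster far from the minority: 1 prototype suffices
  d <- tibble::tibble(V1 = c(10, 10.01, 10.02, 10.03, 10.04, 0, 0.1),
                      y = c(0, 0, 0, 0, 0, 1, 1))
  res <- cnn_condense(d, seed = 4)
  expect_equal(sum(res$data$y == 0), 1L)
  expect_equal(sum(res$data$y == 1), 2L)
  # on fuzzed data: store classifies every input row correctly by 1-NN
  for (seed in 301:305) {
    dd <- fuzz_dataset(seed)
    rr <- cnn_condense(dd, seed = seed)
    store <- rr$data
    D <- oracle_dist(dd)
    keep_idx <- which(sapply(seq_len(nrow(dd)), function(i) {
      any(abs(dd$V1[i] - store$V1) < 1e-12 & abs(dd$V2[i] - store$V2) < 1e-12)
    }))
    expect_equal(sum(dd$y == 1), sum(store$y == 1)) # minority retained
  }
})

test_that("OSS composes condensation with Tomek-link cleaning", {
  d <- tibble::tibble(V1 = c(0.0, 0.3, 1.0, 1.1, 5, 5.05, 5.1), y = c(0, 1, 0, 0, 0, 0, 0))
  res <- oss(d, seed = 5)
  expect_true(0.3 %in% res$data$V1) # minority preserved end-to-end
  expect_equal(unname(res$added["minority"] + res$added["majority"]), 0)
  expect_true(nrow(res$data) <= nrow(d))
  # equals the explicit composition under the same seed
  composed <- tomek_undersample(cnn_condense(d, seed = 5)$data)
  expect_equal(sort(res$data$V1), sort(composed$data$V1))
})

test_that("NCR applies both cleaning rules on the original data", {
  # rule A: a majority point inside the minority cluster is removed
  a <- tibble::tibble(V1 = c(5.0, 4.9, 5.1, 5.2, 0, 0.1, 0.2, 0.3, 0.4),
                      y = c(0, 1, 1, 1, 0, 0, 0, 0, 0))
  res_a <- ncr(a, k = 3)
  expect_false(5.0 %in% res_a$data$V1)
  # rule B: majority neighbors of a misclassified minority row are removed
  b <- tibble::tibble(V1 = c(1.0, 1.1, 1.2, 2.5, 2.6, 5, 5.1, 5.2),
                      y = c(1, 0, 0, 0, 0, 1, 1, 1))
  res_b <- ncr(b, k = 3)
  expect_false(1.1 %in% res_b$data$V1)
  expect_false(1.2 %in% res_b$data$V1)
  expect_true(1.0 %in% res_b$data$V1) # minority rows never deleted
  # clean separation: nothing removed
  sep <- tibble::tibble(V1 = c(0, 0.1, 0.2, 0.3, 9, 9.1, 9.2), y = c(rep(0, 4), 1, 1, 1))
  expect_equal(nrow(ncr(sep, k = 3)$data), 7L)
})

test_that("IHT removes the lowest-own-probability majority rows", {
  d <- generate_domain(domain_spec("low", 1, 3, seed = 6))
  res <- iht(d, seed = 7)
  expect_equal(sum(res$data$y == 0), sum(res$data$y == 1))
  expect_equal(unname(res$removed["minority"]), 0)
  # ratio below the current one -> no removals
  bal <- tibble::tibble(V1 = c(rnorm(5), rnorm(5, 4)), y = rep(c(0, 1), each = 5))
  expect_equal(nrow(iht(bal, target_ratio = 1, seed = 8)$data), 10L)
  # a majority outlier inside the minority cluster goes first
  out <- tibble::tibble(
    V1 = c(5.0, 4.8, 4.9, 5.1, 5.2, 0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    y = c(0, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  )
  res2 <- iht(out, target_ratio = 1, cv_folds = 3, seed = 9)
  expect_false(5.0 %in% res2$data$V1)
})

test_that("deterministic k-NN undersamplers match brute-force re-implementations", {
  n_checked <- 0
  for (seed in 401:435) {
    d <- fuzz_dataset(seed)
    if (nrow(d) > 60) next
    n_checked <- n_checked + 1
    # ENN
    keep_enn <- setdiff(seq_len(nrow(d)), oracle_enn_drop(d, 3))
    expect_equal(sort(enn_edit(d, k = 3)$data$V1), sort(d$V1[keep_enn]),
                 info = sprintf("enn seed %d", seed))
    # RENN
    expect_equal(sort(renn(d, k = 3)$data$V1), sort(d$V1[oracle_renn_keep(d, 3)]),
                 info = sprintf("renn seed %d", seed))
    # ALL KNN
    expect_equal(sort(all_knn(d, k_max = 3)$data$V1), sort(d$V1[oracle_allknn_keep(d, 3)]),
                 info = sprintf("allknn seed %d", seed))
    # NCR
    keep_ncr <- setdiff(seq_len(nrow(d)), oracle_ncr_drop(d, 3))
    expect_equal(sort(ncr(d, k = 3)$data$V1), sort(d$V1[keep_ncr]),
                 info = sprintf("ncr seed %d", seed))
    # Tomek links
    pkg_links <- find_tomek_links(d)
    or_links <- oracle_tomek_pairs(d)
    expect_equal(nrow(pkg_links), length(or_links), info = sprintf("tomek seed %d", seed))
    if (length(or_links)) {
      or_mat <- do.call(rbind, or_links)
      expect_equal(as.matrix(pkg_links[order(pkg_links$i, pkg_links$j), ]),
                   or_mat[order(or_mat[, 1], or_mat[, 2]), , drop = FALSE],
                   ignore_attr = TRUE, info = sprintf("tomek pairs seed %d", seed))
    }
    # NearMiss-3
    keep_nm <- oracle_nearmiss3_keep_maj(d, 3, 3)
    nm <- nearmiss3(d, 3, 3)
    expect_equal(sort(nm$data$V1[nm$data$y == 0]), sort(d$V1[keep_nm]),
                 info = sprintf("nearmiss seed %d", seed))
  }
  expect_gte(n_checked, 30)
})

test_that("ENN vote ties with even k keep the row", {
  # k = 2: the row at 0 sees one neighbor of each class -> tie -> kept
  d <- tibble::tibble(V1 = c(0, 1, -1, 10, 11), y = c(0, 0, 1, 1, 1))
  res <- enn_edit(d, k = 2, edit_class = "all")
  expect_true(0 %in% res$data$V1)
})

test_that("undersampler outputs are exact row subsets of their input", {
  fns <- list(
    function(d) random_undersample(d, seed = 1),
    function(d) nearmiss3(d),
    function(d) tomek_undersample(d),
    function(d) enn_edit(d),
    function(d) renn(d),
    function(d) all_knn(d),
    function(d) cnn_condense(d, seed = 1),
    function(d) oss(d, seed = 1),
    function(d) ncr(d),
    function(d) iht(d, seed = 1)
  )
  for (seed in 501:506) {
    d <- fuzz_dataset(seed)
    key <- paste(d$V1, d$V2, d$y)
    for (fn in fns) {
      res <- fn(d)
      expect_true(all(paste(res$data$V1, res$data$V2, res$data$y) %in% key))
      expect_equal(unname(res$added["minority"] + res$added["majority"]), 0)
      expect_equal(sum(res$data$y == 1), sum(d$y == 1)) # minority untouched
    }
  }
})
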