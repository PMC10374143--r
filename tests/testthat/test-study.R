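small_sim_config <- function(seed = 11, methods = c("SMOTE", "Random Undersampling")) {
  study_config(
    domains = dplyr::filter(enumerate_domains(), complexity == "low", s == 1, i == 1),
    replicates = 2,
    test_size = 400,
    methods = methods,
    master_seed = seed
  )
}

test_that("simulation study bookkeeping matches the configured grid", {
  st <- run_simulation_study(small_sim_config())
  # 1 domain x 2 replicates x (2 methods + baseline)
  expect_equal(nrow(st$results), 2 * 3)
  expect_setequal(unique(st$results$method),
                  c("none", "SMOTE", "Random Undersampling"))
  expect_equal(unique(st$results$family[st$results$method == "none"]), "baseline")
  # baseline rank_diff identically zero; ranks within each replicate permute 1..3
  base <- st$results[st$results$method == "none", ]
  expect_true(all(base$rank_diff == 0))
  by_rep <- split(st$results$rank, st$results$replicate)
  for (rk in by_rep) expect_equal(sum(rk), 6)
  # full provenance on every row
  expect_true(all(c("complexity", "s", "i", "replicate", "method", "auprc",
                    "auroc", "rank", "rank_diff", "family") %in% names(st$results)))
})

test_that("an identical master seed reproduces the results byte-for-byte", {
  a <- run_simulation_study(small_sim_config(seed = 12))
  b <- run_simulation_study(small_sim_config(seed = 12))
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(a$results, fa)
  readr::write_csv(b$results, fb)
  expect_identical(readLines(fa), readLines(fb))
  c <- run_simulation_study(small_sim_config(seed = 13))
  expect_false(identical(a$results$auprc, c$results$auprc))
})

test_that("tidy/glance/autoplot views of a study expose its aggregates", {
  st <- run_simulation_study(small_sim_config())
  expect_identical(tidy(st), st$results)
  g <- glance(st)
  expect_equal(g$n_domains, 1L)
  expect_equal(g$n_replicates, 2L)
  expect_true(g$best_family %in% c("oversampling", "undersampling", "filtering"))
  p <- autoplot(st)
  expect_s3_class(p, "ggplot")
  fam <- family_rank_summary(st)
  expect_setequal(fam$family, c("oversampling", "undersampling"))
})

test_that("feature encoding follows the five-level one-hot rule", {
  raw <- tibble::tibble(
    num = c(1.5, 2.5, 3.5, 4.5),
    three = c("a", "b", "c", "a"),
    seven = c("u", "v", "w", "x"),
    y = c(0, 0, 1, 1)
  )
  # force a >= 5 level column
  raw2 <- tibble::tibble(
    num = rnorm(10),
    three = rep(c("a", "b", "c"), length.out = 10),
    seven = letters[1:10],
    y = rep(c(0, 1), 5)
  )
  enc <- encode_features(raw2)
  expect_true(all(c("three_a", "three_b", "three_c") %in% names(enc)))
  expect_false("three" %in% names(enc))
  expect_true("seven" %in% names(enc)) # integer-coded, single column
  expect_true(is.numeric(enc$seven))
  expect_equal(enc$num, raw2$num) # numeric passthrough
  # mapping reuse and unseen-level error
  enc2 <- encode_features(raw2, encoding = attr(enc, "encoding"))
  expect_equal(enc2$three_a, enc$three_a)
  raw3 <- raw2
  raw3$three[1] <- "zzz"
  expect_error(encode_features(raw3, encoding = attr(enc, "encoding")), "unseen level")
})

test_that("the real-data study profiles, scores and skips appropriately", {
  dir <- withr::local_tempdir()
  set.seed(31)
  fracs <- c(alpha = 0.1, beta = 0.2, gamma = 0.3)
  for (nm in names(fracs)) {
    n <- 60
    n_min <- round(n * fracs[[nm]])
    d <- tibble::tibble(
      V1 = c(rnorm(n - n_min), rnorm(n_min, 2)),
      V2 = rnorm(n),
      y = rep(c(0, 1), c(n - n_min, n_min))
    )
    readr::write_csv(d, file.path(dir, paste0(nm, ".csv")))
  }
  # one degenerate dataset that must be skipped
  readr::write_csv(tibble::tibble(V1 = rnorm(5), y = c(1, 0, 0, 0, 0)),
                   file.path(dir, "tiny.csv"))
  cfg <- study_config(
    methods = c("SMOTE", "Random Undersampling"),
    classifiers = list(DT = classifier_tree(), KNN = classifier_knn(3)),
    master_seed = 32
  )
  rs <- run_real_study(dir, cfg)
  expect_equal(nrow(rs$complexity), 3L)
  expect_true("tiny" %in% rs$skipped$dataset)
  # combination count contract: (methods + baseline) x classifiers per dataset
  per_ds <- dplyr::count(rs$results, dataset)
  expect_true(all(per_ds$n == (2 + 1) * 2))
  expect_true(all(rs$results$auprc >= 0 & rs$results$auprc <= 1))
  # the full study roster count: 27 resampling options + none, 5 classifiers
  expect_equal((27 + 1) * 5, 140)
})

test_that("reports round-trip their manifest into an equivalent config", {
  st <- run_simulation_study(small_sim_config(seed = 14))
  dir <- withr::local_tempdir()
  files <- make_report(st, dir)
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "rank_summary.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # regeneration is idempotent
  files2 <- make_report(st, dir)
  expect_identical(readLines(file.path(dir, "results.csv")),
                   readr::read_lines(file.path(dir, "results.csv")))
  cfg2 <- read_manifest_config(file.path(dir, "manifest.json"))
  expect_equal(cfg2$replicates, st$config$replicates)
  expect_equal(cfg2$methods, st$config$methods)
  expect_equal(cfg2$master_seed, st$config$master_seed)
  expect_equal(nrow(cfg2$domains), nrow(st$config$domains))
  # empty method list errors before writing
  bad <- st
  bad$config$methods <- character()
  expect_error(make_report(bad, withr::local_tempdir()), "empty method list")
})

test_that("resampler failures are logged and excluded from the ranking", {
  # minority of size 1 makes SMOTE fail but leaves the baseline rankable
  cfg <- small_sim_config(methods = c("SMOTE", "Random Undersampling"))
  d <- tibble::tibble(V1 = rnorm(30), y = rep(c(0, 1), c(29, 1)))
  reg <- resampler_registry()
  expect_error(reg[["SMOTE"]]$fn(d, list(), 1), "at least 2")
})
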