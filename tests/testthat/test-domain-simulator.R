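test_that("interval quotas reproduce the published simulation settings", {
  # (c, s, i) -> per-interval and summed class totals
  expect_equal(interval_quota(1, 1, 1, "majority"), 156L)
  expect_equal(interval_quota(1, 1, 1, "minority"), 10L)
  expect_equal(interval_quota(1, 3, 1, "majority"), 625L)
  expect_equal(interval_quota(1, 3, 1, "minority"), 39L)
  expect_equal(interval_quota(1, 5, 1, "majority"), 2500L)
  expect_equal(interval_quota(1, 5, 3, "minority"), 625L)
  # halving per interval at c = 2 preserves the class totals
  expect_equal(2 * interval_quota(2, 1, 1, "majority"), 156L)
  expect_equal(2 * interval_quota(2, 1, 1, "minority"), 10L)
  expect_error(interval_quota(3, 1, 1, "majority"), "must be 1 or 2")
  expect_error(interval_quota(1, 2, 1, "majority"), "one of 1, 3, 5")
})

test_that("domain totals and imbalance ratios match the design table", {
  cases <- list(
    list(s = 1, i = 1, n = 166, n_maj = 156, ir = 15.6),
    list(s = 3, i = 1, n = 664, n_maj = 625, ir = 16),
    list(s = 5, i = 1, n = 2656, n_maj = 2500, ir = 16),
    list(s = 5, i = 3, n = 3125, n_maj = 2500, ir = 4)
  )
  for (cs in cases) {
    bb <- build_backbone(domain_spec("low", s = cs$s, i = cs$i))
    n_maj <- sum(bb$quota[bb$class == "majority"])
    n_min <- sum(bb$quota[bb$class == "minority"])
    expect_equal(n_maj + n_min, cs$n)
    expect_equal(n_maj, cs$n_maj)
    expect_equal(round(n_maj / n_min, 1), cs$ir)
    # at c = 2 the per-interval rule can land on .5 halves; totals agree
    # with the c = 1 class totals to within one count per interval
    bb2 <- build_backbone(domain_spec("medium", s = cs$s, i = cs$i))
    expect_true(abs(sum(bb2$quota[bb2$class == "majority"]) - cs$n_maj) <= 2)
    expect_true(abs(sum(bb2$quota) - cs$n) <= 4)
  }
  # i = 5 gives equal class counts (imbalance factor 32/2^5 = 1)
  bb <- build_backbone(domain_spec("low", s = 1, i = 5))
  expect_equal(
    sum(bb$quota[bb$class == "majority"]),
    sum(bb$quota[bb$class == "minority"])
  )
})

test_that("the domain factorial enumerates 27 specs in stable order", {
  doms <- enumerate_domains()
  expect_equal(nrow(doms), 27L)
  expect_equal(sum(doms$complexity == "low"), 9L)
  expect_equal(doms$complexity[1], "low")
  expect_equal(doms$s[1], 1L)
  expect_equal(doms$i[1], 1L)
  expect_equal(doms$c, ifelse(doms$complexity == "low", 1L, 2L))
})

test_that("latent draws have the configured equicorrelation structure", {
  z <- sample_latent(2e5, rho = 0.3, seed = 11)
  cors <- cor(z)
  expect_true(all(abs(cors[upper.tri(cors)] - 0.3) < 0.01))
  expect_true(all(abs(colMeans(z)) < 0.02))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 0.02))
  z0 <- sample_latent(1e5, rho = 0, seed = 12)
  expect_true(all(abs(cor(z0)[upper.tri(diag(6))]) < 0.02))
  z9 <- sample_latent(5e3, rho = 0.999, seed = 13)
  expect_true(all(cor(z9)[upper.tri(diag(6))] > 0.99))
  expect_error(sample_latent(10, rho = -0.5), "positive-definite")
  expect_error(sample_latent(0), "at least 1")
})

test_that("binarization hits the stated zero-probabilities", {
  feats <- discretize_features(sample_latent(2e5, seed = 14))
  expect_true(abs(mean(feats$X4 == 0) - 0.30) < 0.01)
  expect_true(abs(mean(feats$X5 == 0) - 0.20) < 0.01)
  expect_true(abs(mean(feats$X6 == 0) - 0.15) < 0.01)
  # far-below-threshold latent value maps to 0; continuous columns untouched
  row <- matrix(c(1.5, -2, 0.3, -10, 0, 0), nrow = 1)
  out <- discretize_features(row)
  expect_equal(out$X4, 0)
  expect_equal(out$X1, 1.5)
  expect_equal(out$X3, 0.3)
})

test_that("the sigmoid response evaluates to its closed forms", {
  zero <- data.frame(X1 = 0, X2 = 0, X3 = 0, X4 = 0, X5 = 0, X6 = 0)
  expect_equal(compute_eta(zero, 0), 0.5)
  expect_equal(compute_eta(transform(zero, X1 = 1), 0), 1 / (1 + exp(-1.1)))
  expect_equal(compute_eta(transform(zero, X6 = 1), 0), 1 / (1 + exp(1)))
  expect_true(compute_eta(zero, 1e4) < 1) # guarded to the asymptote
  expect_true(compute_eta(zero, -1e4) > 0)
})

test_that("backbone layouts follow the complexity conventions", {
  low <- build_backbone(domain_spec("low", 1, 1))
  expect_equal(nrow(low), 2L)
  expect_equal(low$class, c("majority", "minority"))
  med <- build_backbone(domain_spec("medium", 1, 1))
  expect_equal(nrow(med), 4L)
  expect_equal(sum(med$class == "minority"), 2L)
  expect_equal(med$class, c("majority", "minority", "majority", "minority"))
  ext <- build_backbone(domain_spec("extreme", 1, 1))
  expect_equal(ext$class, c("minority", "majority", "majority", "minority"))
  expect_equal(sum(ext$quota), 166L)
  # intervals tile [0, 1] with equal width
  expect_equal(ext$lower, c(0, 0.25, 0.5, 0.75))
  expect_equal(ext$upper, c(0.25, 0.5, 0.75, 1))
  # layout override
  ov <- build_backbone(domain_spec("medium", 1, 1, layout = "MIN,MAJ,MIN,MAJ"))
  expect_equal(ov$class, c("minority", "majority", "minority", "majority"))
  expect_error(build_backbone(domain_spec("low", 1, 1, layout = "MAJ,MAJ")),
               "at least one of each")
})

test_that("generated domains meet quotas exactly and respect intervals", {
  for (cl in c("low", "medium", "extreme")) {
    spec <- domain_spec(cl, s = 1, i = 3, seed = 21)
    d <- generate_domain(spec)
    bb <- build_backbone(spec)
    expect_equal(nrow(d), sum(bb$quota))
    expect_equal(as.vector(table(factor(d$.interval, levels = bb$interval))),
                 bb$quota)
    # every row's eta lies inside its assigned interval
    lo <- bb$lower[d$.interval]
    hi <- bb$upper[d$.interval]
    expect_true(all(d$eta >= lo & (d$eta < hi | (hi == 1 & d$eta <= 1))))
    # labels follow the interval class
    expect_equal(d$y, as.numeric(bb$class[d$.interval] == "minority"))
  }
})

test_that("domain generation is reproducible and seed-sensitive", {
  spec <- domain_spec("low", 1, 1, seed = 31)
  a <- generate_domain(spec)
  b <- generate_domain(spec)
  expect_identical(a, b)
  c <- generate_domain(spec, seed = 32)
  expect_false(identical(a, c))
})

test_that("test sets rescale quotas proportionally at the requested total", {
  spec <- domain_spec("low", 1, 1)
  ts <- generate_test_set(spec, total = 5000, seed = 41)
  expect_equal(nrow(ts), 5000L)
  # class ratio equals 156:10 within rounding
  expect_equal(sum(ts$y == 0), round(5000 * 156 / 166))
  empty <- generate_test_set(spec, total = 0)
  expect_equal(nrow(empty), 0L)
  other <- generate_test_set(spec, total = 5000, seed = 42)
  expect_false(identical(ts, other))
})

test_that("datasets and manifests round-trip through CSV/JSON", {
  spec <- domain_spec("low", 1, 1, seed = 51)
  d <- generate_domain(spec)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_dataset(d, csv)
  back <- read_dataset(csv)
  expect_equal(back$y, d$y)
  expect_equal(back$X1, d$X1, tolerance = 1e-12)
  write_domain_manifest(spec, d, js)
  spec2 <- read_domain_manifest(js)
  expect_equal(spec2$complexity, "low")
  expect_equal(spec2$s, 1L)
  expect_equal(spec2$seed, 51L)
})
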