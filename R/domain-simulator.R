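#' Specify a simulated imbalanced domain
#'
#' A domain is identified by its complexity level, its size level `s` and
#' its imbalance level `i`. Complexity maps to an interval exponent `c`
#' (1 for low, 2 for medium and extreme): the response eta in \[0, 1\] is
#' partitioned into `2^c` equal-width backbone intervals, each assigned to
#' one class. "Extreme" uses the same four intervals as "medium" but places
#' the two minority intervals at the outer ends, maximally separated.
#'
#' @param complexity One of `"low"`, `"medium"`, `"extreme"`.
#' @param s Size level, one of 1, 3, 5. Doubling steps of the overall
#'   sample size (the base interval quota scales with `2^s`).
#' @param i Imbalance level, one of 1, 3, 5. The majority:minority ratio is
#'   `32 / 2^i` (16, 4 and 1 before rounding), so `i = 1` is the most
#'   imbalanced and `i = 5` is balanced.
#' @param rho Equicorrelation of the six latent Gaussian variables.
#'   Must keep the correlation matrix positive definite (`rho > -1/5`)
#'   and below 1.
#' @param seed Optional integer seed attached to the spec; used by
#'   [generate_domain()] when no explicit seed is given.
#' @param layout Optional backbone layout override such as
#'   `"MAJ,MIN,MAJ,MIN"`; by default the layout is implied by `complexity`.
#'
#' @return An object of class `domain_spec`.
#' @seealso [generate_domain()], [enumerate_domains()], [build_backbone()]
#' @export
#' @examples
#' domain_spec("low", s = 1, i = 1)
domain_spec <- function(complexity = c("low", "medium", "extreme"),
                        s = 1, i = 1, rho = 0.3, seed = NULL,
                        layout = NULL) {
  complexity <- match.arg(complexity)
  if (!s %in% c(1, 3, 5)) abort("`s` must be one of 1, 3, 5")
  if (!i %in% c(1, 3, 5)) abort("`i` must be one of 1, 3, 5")
  if (!is.numeric(rho) || rho <= -1 / 5 || rho >= 1) {
    abort("`rho` must lie in (-0.2, 1) so the equicorrelation matrix is positive definite")
  }
  structure(
    list(
      complexity = complexity,
      c = if (complexity == "low") 1L else 2L,
      s = as.integer(s),
      i = as.integer(i),
      rho = rho,
      seed = if (is.null(seed)) NULL else as.integer(seed),
      layout = layout
    ),
    class = "domain_spec"
  )
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf(
    "<domain_spec> complexity=%s (c=%d), s=%d, i=%d, rho=%g%s\n",
    x$complexity, x$c, x$s, x$i, x$rho,
    if (is.null(x$seed)) "" else sprintf(", seed=%d", x$seed)
  ))
  invisible(x)
}

#' Enumerate the full factorial of simulated domains
#'
#' The 3 x 3 x 3 factorial of complexity levels (low, medium, extreme),
#' size levels (1, 3, 5) and imbalance levels (1, 3, 5), in a stable
#' ordering: complexity slowest, then `s`, then `i`, so the first row is
#' (low, s = 1, i = 1).
#'
#' @return A tibble with columns `complexity`, `c`, `s`, `i` and a
#'   list-column `spec` of [domain_spec()] objects, 27 rows.
#' @export
#' @examples
#' enumerate_domains()
enumerate_domains <- function() {
  grid <- tidyr::expand_grid(
    complexity = c("low", "medium", "extreme"),
    s = c(1L, 3L, 5L),
    i = c(1L, 3L, 5L)
  )
  grid |>
    mutate(
      c = if_else(.data$complexity == "low", 1L, 2L),
      spec = purrr::pmap(list(.data$complexity, .data$s, .data$i), domain_spec)
    ) |>
    select("complexity", "c", "s", "i", "spec")
}

#' Draw correlated latent Gaussian variables
#'
#' Samples `n` rows from a 6-variate standard normal with a common
#' pairwise correlation `rho` (equicorrelation structure).
#'
#' @param n Number of draws.
#' @param rho Common pairwise correlation; must exceed -1/5 (positive
#'   definiteness for 6 variables) and be below 1.
#' @param seed Optional integer seed.
#' @return An `n` x 6 numeric matrix.
#' @export
sample_latent <- function(n, rho = 0.3, seed = NULL) {
  if (n < 1) abort("`n` must be at least 1")
  if (rho <= -1 / 5 || rho >= 1) {
    abort("`rho` must lie in (-0.2, 1) for a positive-definite equicorrelation matrix")
  }
  sigma <- matrix(rho, 6, 6)
  diag(sigma) <- 1
  with_seed_or_not(seed, {
    m <- MASS::mvrnorm(n, mu = rep(0, 6), Sigma = sigma)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    colnames(m) <- c("X1", "X2", "X3", "X4", "X5", "X6")
    m
  })
}

# Binarization thresholds for the three categorical features: the latent
# normal is cut so that P(X4 = 0) = 0.3, P(X5 = 0) = 0.2, P(X6 = 0) = 0.15.
binary_cut_probs <- c(X4 = 0.3, X5 = 0.2, X6 = 0.15)

#' Binarize the latent categorical features
#'
#' Columns 4-6 of the latent draw are thresholded at the standard-normal
#' quantiles of 0.3, 0.2 and 0.15 respectively (value 0 below the
#' threshold, 1 otherwise); columns 1-3 pass through as the continuous
#' features X1-X3.
#'
#' @param latent Matrix of latent draws from [sample_latent()].
#' @return A tibble with columns `X1`..`X6`.
#' @export
discretize_features <- function(latent) {
  stopifnot(ncol(latent) == 6)
  out <- as_tibble(as.data.frame(latent))
  names(out) <- c("X1", "X2", "X3", "X4", "X5", "X6")
  for (nm in names(binary_cut_probs)) {
    out[[nm]] <- as.numeric(out[[nm]] >= stats::qnorm(binary_cut_probs[[nm]]))
  }
  out
}

#' Sigmoid response of the generative model
#'
#' Computes `eta = plogis(1.1 X1 + 0.9 X2 + 0.7 X3 + X4 + X5 - X6 + eps)`,
#' strictly inside (0, 1) (the logistic guards overflow to the
#' asymptotes).
#'
#' @param features Data frame with columns `X1`..`X6`.
#' @param epsilon Per-row noise draw (standard normal in the generative
#'   model); recycled if scalar.
#' @return Numeric vector of responses in (0, 1).
#' @export
#' @examples
#' compute_eta(data.frame(X1 = 0, X2 = 0, X3 = 0, X4 = 0, X5 = 0, X6 = 0), 0)
compute_eta <- function(features, epsilon = 0) {
  lp <- 1.1 * features$X1 + 0.9 * features$X2 + 0.7 * features$X3 +
    features$X4 + features$X5 - features$X6 + epsilon
  eps <- .Machine$double.eps
  pmin(pmax(stats::plogis(lp), eps), 1 - eps)
}

#' Per-interval sample quota
#'
#' The base interval size is `(5000/32) * 2^s / 2^c`. Rounded to the
#' nearest integer (half away from zero) this is the majority-interval
#' quota; the minority-interval quota divides the unrounded base by the
#' imbalance factor `32 / 2^i` before rounding.
#'
#' @param c Interval exponent (1 or 2).
#' @param s Size level (1, 3 or 5).
#' @param i Imbalance level (1, 3 or 5); ignored for majority intervals.
#' @param interval_class `"majority"` or `"minority"`.
#' @return Integer quota for one interval.
#' @export
#' @examples
#' interval_quota(c = 1, s = 1, i = 1, "majority") # 156
#' interval_quota(c = 1, s = 1, i = 1, "minority") # 10
interval_quota <- function(c, s, i = NULL, interval_class = c("majority", "minority")) {
  interval_class <- match.arg(interval_class)
  if (!c %in% c(1, 2)) abort("`c` must be 1 or 2")
  if (!s %in% c(1, 3, 5)) abort("`s` must be one of 1, 3, 5")
  base <- (5000 / 32) * 2^s / 2^c
  if (interval_class == "majority") {
    as.integer(round_half_up(base))
  } else {
    if (is.null(i) || !i %in% c(1, 3, 5)) abort("`i` must be one of 1, 3, 5")
    as.integer(round_half_up(base / (32 / 2^i)))
  }
}

# Layout strings implied by each complexity level. Figures in the source
# design only fix the interval count; the placement below (minority in the
# upper half for low, alternating for medium, minority pushed to both ends
# for extreme) is this package's documented convention and can be
# overridden via domain_spec(layout = ...).
default_layout <- function(complexity) {
  switch(complexity,
    low = c("MAJ", "MIN"),
    medium = c("MAJ", "MIN", "MAJ", "MIN"),
    extreme = c("MIN", "MAJ", "MAJ", "MIN")
  )
}

#' Build the backbone interval model of a domain
#'
#' Partitions eta in \[0, 1\] into `2^c` equal-width intervals (half-open,
#' the last closed at 1), tags each as minority or majority, and attaches
#' the per-interval sample quota.
#'
#' @param spec A [domain_spec()] (or a complexity string, with `s` and `i`
#'   given separately).
#' @param s,i Size and imbalance levels when `spec` is a string.
#' @return A tibble with columns `interval`, `lower`, `upper`, `class`,
#'   `quota`.
#' @export
#' @examples
#' build_backbone(domain_spec("extreme", s = 1, i = 1))
build_backbone <- function(spec, s = NULL, i = NULL) {
  if (is.character(spec)) spec <- domain_spec(spec, s = s, i = i)
  layout <- spec$layout %||% default_layout(spec$complexity)
  if (is.character(layout) && length(layout) == 1L) {
    layout <- strsplit(layout, ",")[[1]]
  }
  layout <- toupper(trimws(layout))
  n_int <- 2^spec$c
  if (length(layout) != n_int) {
    abort(sprintf("layout must name %d intervals, got %d", n_int, length(layout)))
  }
  if (!all(layout %in% c("MIN", "MAJ")) || length(unique(layout)) < 2L) {
    abort("layout must use MIN/MAJ tags and contain at least one of each")
  }
  cls <- if_else(layout == "MIN", "minority", "majority")
  tibble(
    interval = seq_len(n_int),
    lower = (seq_len(n_int) - 1) / n_int,
    upper = seq_len(n_int) / n_int,
    class = cls,
    quota = purrr::map_int(cls, ~ interval_quota(spec$c, spec$s, spec$i, .x))
  )
}

# Map eta values to backbone interval ids: half-open [lower, upper), with
# the final interval closed at 1.
interval_of_eta <- function(eta, n_int) {
  pmin(floor(eta * n_int) + 1L, n_int)
}

# Rejection-sample rows until every interval quota is exactly met.
sample_to_quota <- function(backbone, rho, batch_size = 4096L, max_draws = 1e7) {
  n_int <- nrow(backbone)
  need <- backbone$quota
  kept <- vector("list", 0L)
  drawn <- 0
  while (sum(need) > 0) {
    if (drawn >= max_draws) {
      abort("rejection sampling exceeded the draw cap; interval quotas appear unreachable")
    }
    latent <- sample_latent(min(batch_size, max_draws - drawn), rho = rho)
    drawn <- drawn + nrow(latent)
    feats <- discretize_features(latent)
    feats$eta <- compute_eta(feats, epsilon = stats::rnorm(nrow(feats)))
    feats$.interval <- interval_of_eta(feats$eta, n_int)
    for (j in seq_len(n_int)) {
      if (need[j] == 0L) next
      rows <- which(feats$.interval == j)
      if (length(rows) == 0L) next
      take <- utils::head(rows, need[j])
      need[j] <- need[j] - length(take)
      kept[[length(kept) + 1L]] <- feats[take, ]
    }
  }
  out <- bind_rows(kept)
  out$y <- as.numeric(backbone$class[out$.interval] == "minority")
  out <- arrange(out, .data$.interval)
  out[c("X1", "X2", "X3", "X4", "X5", "X6", "y", "eta", ".interval")]
}

#' Generate one simulated imbalanced domain
#'
#' Draws latent correlated Gaussians, binarizes X4-X6, computes the noisy
#' sigmoid response eta, routes each row to its backbone interval and
#' keeps rows until every interval quota is met exactly. Rows in minority
#' intervals are labeled `y = 1`.
#'
#' @param spec A [domain_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`.
#' @return A tibble with columns `X1`..`X6`, `y`, `eta`, `.interval`;
#'   the row count equals the summed interval quotas.
#' @export
#' @examples
#' d <- generate_domain(domain_spec("low", s = 1, i = 1, seed = 1))
#' table(d$y) # 156 majority, 10 minority
generate_domain <- function(spec, seed = spec$seed) {
  backbone <- build_backbone(spec)
  with_seed_or_not(seed, sample_to_quota(backbone, rho = spec$rho))
}

#' Generate an independent test set matched to a domain
#'
#' Uses the same backbone and class layout as the training domain, with
#' per-interval quotas rescaled proportionally (largest-remainder
#' apportionment) so that the total equals `total` while the imbalance
#' ratio matches the training domain's within rounding.
#'
#' @param spec A [domain_spec()].
#' @param total Total number of test rows (default 5000).
#' @param seed Integer seed; keep distinct from the training seed to get
#'   an independent stream.
#' @return A tibble in the same format as [generate_domain()].
#' @export
generate_test_set <- function(spec, total = 5000, seed = NULL) {
  backbone <- build_backbone(spec)
  if (total == 0) {
    empty <- backbone[0, ]
    return(tibble(
      X1 = numeric(), X2 = numeric(), X3 = numeric(), X4 = numeric(),
      X5 = numeric(), X6 = numeric(), y = numeric(), eta = numeric(),
      .interval = integer()
    ))
  }
  raw <- backbone$quota / sum(backbone$quota) * total
  quota <- floor(raw)
  short <- total - sum(quota)
  if (short > 0) {
    extra <- order(raw - quota, seq_along(raw), decreasing = TRUE)[seq_len(short)]
    quota[extra] <- quota[extra] + 1L
  }
  backbone$quota <- as.integer(quota)
  with_seed_or_not(seed, sample_to_quota(backbone, rho = spec$rho))
}
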