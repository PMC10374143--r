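# Rank-difference evaluation protocol: within each replicate, all method
# configurations (the no-resampling baseline included) are ranked by
# AUPRC, and performance is expressed as baseline rank minus method rank
# (positive = the method ranks better than leaving the data alone).

#' Rank methods within one replicate
#'
#' Rank 1 is the best (highest) AUPRC; ties receive average ranks. The
#' baseline is part of the ranked pool, and each method's rank difference
#' is `baseline rank - method rank`.
#'
#' @param auprc_by_method Tibble with columns `method` and `auprc`
#'   (one replicate), or a named numeric vector.
#' @param baseline Name of the no-resampling baseline entry.
#' @return A tibble with columns `method`, `auprc`, `rank`, `rank_diff`.
#' @export
#' @examples
#' rank_methods(c(none = 0.5, A = 0.7, B = 0.3))
rank_methods <- function(auprc_by_method, baseline = "none") {
  if (!is.data.frame(auprc_by_method)) {
    auprc_by_method <- tibble(
      method = names(auprc_by_method),
      auprc = as.numeric(auprc_by_method)
    )
  }
  if (nrow(auprc_by_method) < 2L) abort("rank_methods: need at least 2 entries")
  if (!baseline %in% auprc_by_method$method) {
    abort(sprintf("rank_methods: baseline '%s' not among the methods", baseline))
  }
  out <- auprc_by_method |>
    mutate(rank = rank(-.data$auprc, ties.method = "average"))
  out$rank_diff <- out$rank[out$method == baseline] - out$rank
  out
}

#' Aggregate rank differences across replicates
#'
#' Computes each method's mean rank difference over replicates and flags
#' significance by a paired two-sided t-test on the per-replicate AUPRC
#' differences (method minus baseline) at `alpha`, without multiplicity
#' correction. Zero-variance differences are reported non-significant
#' unless every difference is non-zero with the same sign, in which case
#' the flag is set with a note.
#'
#' @param records Long tibble with columns `replicate`, `method`,
#'   `auprc`, `rank`, `rank_diff` (as produced by [rank_methods()] per
#'   replicate and bound together).
#' @param baseline Baseline method name.
#' @param alpha Significance level.
#' @return A tibble per method: `mean_rank_diff`, `mean_auprc`,
#'   `p_value`, `significant`, `note`, `n_replicates`.
#' @export
aggregate_ranks <- function(records, baseline = "none", alpha = 0.05) {
  base <- records |>
    filter(.data$method == baseline) |>
    select("replicate", base_auprc = "auprc")
  if (nrow(base) == 0L) abort("aggregate_ranks: baseline records missing")
  records |>
    left_join(base, by = "replicate") |>
    group_by(.data$method) |>
    summarise(
      n_replicates = dplyr::n(),
      mean_rank_diff = mean(.data$rank_diff),
      mean_auprc = mean(.data$auprc),
      test = list(paired_significance(.data$auprc - .data$base_auprc, alpha)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("test")
}

paired_significance <- function(diffs, alpha) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2L) {
    return(list(p_value = NA_real_, significant = FALSE, note = "fewer than 2 replicates"))
  }
  if (stats::sd(diffs) == 0) {
    if (all(diffs != 0)) {
      return(list(
        p_value = NA_real_, significant = TRUE,
        note = "zero variance; identical non-zero differences"
      ))
    }
    return(list(p_value = NA_real_, significant = FALSE, note = "zero variance"))
  }
  p <- stats::t.test(diffs)$p.value
  list(p_value = p, significant = p < alpha, note = NA_character_)
}

#' Mean AUPRC change per complexity stratum
#'
#' Joins the per-dataset baseline and resampled AUPRC tables on dataset
#' id and averages (after - before) within each stratum.
#'
#' @param before Tibble with columns `dataset`, `auprc` (baseline).
#' @param after Tibble with columns `dataset`, `auprc` (after
#'   resampling).
#' @param strata Tibble with columns `dataset`, `stratum`.
#' @return A tibble per stratum: `mean_change`, `n`.
#' @export
mean_auprc_change <- function(before, after, strata) {
  if (!setequal(before$dataset, after$dataset)) {
    abort("mean_auprc_change: before/after dataset ids do not match")
  }
  before |>
    inner_join(after, by = "dataset", suffix = c("_before", "_after")) |>
    inner_join(strata, by = "dataset") |>
    group_by(.data$stratum) |>
    summarise(
      mean_change = mean(.data$auprc_after - .data$auprc_before),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Top method-classifier combinations by average rank
#'
#' Ranks every (method, classifier) pair within each dataset by AUPRC
#' (average ranks for ties), averages the ranks across datasets, and
#' returns the `k` best pairs. Every pair must be evaluated on every
#' dataset.
#'
#' @param results Tibble with columns `dataset`, `method`, `classifier`,
#'   `auprc`.
#' @param k Number of combinations to return.
#' @return A tibble: `method`, `classifier`, `average_rank`, sorted
#'   ascending.
#' @export
top_combinations <- function(results, k = 10) {
  counts <- results |>
    count(.data$method, .data$classifier)
  if (length(unique(counts$n)) > 1L) {
    bad <- counts |> filter(.data$n < max(counts$n))
    abort(sprintf(
      "top_combinations: missing cells for %s",
      paste(bad$method, bad$classifier, sep = "/", collapse = ", ")
    ))
  }
  results |>
    group_by(.data$dataset) |>
    mutate(rank = rank(-.data$auprc, ties.method = "average")) |>
    ungroup() |>
    group_by(.data$method, .data$classifier) |>
    summarise(average_rank = mean(.data$rank), .groups = "drop") |>
    arrange(.data$average_rank) |>
    slice_head(n = k)
}
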