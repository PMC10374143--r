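# Orchestration of the simulation study (replicated domains, resampling,
# tuned decision tree, AUPRC/AUROC scoring, rank differences) and the
# real-CSV study (encode, 7:3 split, complexity strata, method x
# classifier grids).

#' Configure a resampling study
#'
#' @param domains Tibble of domain levels to include (subset of
#'   [enumerate_domains()], or that full factorial).
#' @param replicates Replicated training sets per domain (the full study
#'   design uses 50).
#' @param test_size Rows per shared test set (full design: 5000).
#' @param methods Character vector of registry names (default: the full
#'   in-scope method set).
#' @param method_params Named list of per-method parameter lists.
#' @param cv_folds Folds for classifier tuning (full design: 3).
#' @param tuning_grid Decision-tree tuning grid.
#' @param classifiers Named list of classifier adapters (real-data
#'   study; the simulation study uses the tuned tree only).
#' @param master_seed Master seed; all per-replicate seeds derive from it
#'   by a fixed arithmetic scheme.
#' @param output_dir Optional directory for [make_report()].
#' @return A `study_config` list.
#' @export
study_config <- function(domains = enumerate_domains(),
                         replicates = 50,
                         test_size = 5000,
                         methods = names(resampler_registry()),
                         method_params = list(),
                         cv_folds = 3,
                         tuning_grid = tree_tuning_grid(),
                         classifiers = list(DT = classifier_tree()),
                         master_seed = 1L,
                         output_dir = NULL) {
  if (replicates < 1) abort("`replicates` must be at least 1")
  reg <- resampler_registry(include_optional = TRUE)
  unknown <- setdiff(methods, names(reg))
  if (length(unknown)) {
    abort(sprintf("unknown resamplers in config: %s", paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      domains = domains, replicates = as.integer(replicates),
      test_size = as.integer(test_size), methods = methods,
      method_params = method_params, cv_folds = as.integer(cv_folds),
      tuning_grid = tuning_grid, classifiers = classifiers,
      master_seed = as.integer(master_seed), output_dir = output_dir
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> %d domain(s) x %d replicate(s), %d method(s), test size %d, seed %d\n",
    nrow(x$domains), x$replicates, length(x$methods), x$test_size, x$master_seed
  ))
  invisible(x)
}

# Seed lineage: one stream index per (domain, replicate, purpose) slot.
study_seed <- function(master, domain_idx, replicate, purpose) {
  offset <- c(test = 0L, train = 1L, resample = 2L, tune = 3L)[[purpose]]
  derive_seed(master, domain_idx * 1000L + replicate * 10L + offset)
}

#' Run the replicated simulation study
#'
#' For each domain and replicate: generates a training set, resamples it
#' with every configured method (plus the `"none"` baseline), tunes a
#' decision tree by stratified cross-validated grid search on the
#' resampled data, scores AUPRC and AUROC on the domain's shared test
#' set, and ranks all methods within the replicate. Fully deterministic
#' given the master seed. A resampler failure on a replicate is recorded
#' and excluded from that replicate's ranking.
#'
#' @param config A [study_config()].
#' @param verbose Print progress to stderr.
#' @return A `sim_study` object: list with `results` (long tibble:
#'   domain levels, replicate, method, family, auprc, auroc, rank,
#'   rank_diff), `summary` (per domain x method aggregates from
#'   [aggregate_ranks()]), `failures`, `config`.
#' @export
run_simulation_study <- function(config = study_config(), verbose = FALSE) {
  reg <- resampler_registry(include_optional = TRUE)
  rows <- list()
  failures <- list()
  for (d in seq_len(nrow(config$domains))) {
    spec <- config$domains$spec[[d]]
    test_set <- generate_test_set(
      spec, total = config$test_size,
      seed = study_seed(config$master_seed, d, 0L, "test")
    )
    if (verbose) {
      message(sprintf("domain %d/%d (%s, s=%d, i=%d)",
                      d, nrow(config$domains), spec$complexity, spec$s, spec$i))
    }
    for (r in seq_len(config$replicates)) {
      train <- generate_domain(spec, seed = study_seed(config$master_seed, d, r, "train"))
      per_method <- list()
      for (m in c("none", config$methods)) {
        resampled <- if (m == "none") {
          train
        } else {
          params <- config$method_params[[m]] %||% list()
          res <- tryCatch(
            reg[[m]]$fn(train, params, seed = study_seed(config$master_seed, d, r, "resample")),
            error = function(e) e
          )
          if (inherits(res, "error")) {
            failures[[length(failures) + 1L]] <- tibble(
              complexity = spec$complexity, s = spec$s, i = spec$i,
              replicate = r, method = m, reason = conditionMessage(res)
            )
            next
          }
          res$data
        }
        if (length(unique(resampled$y)) < 2L) {
          failures[[length(failures) + 1L]] <- tibble(
            complexity = spec$complexity, s = spec$s, i = spec$i,
            replicate = r, method = m, reason = "resampled data lost a class"
          )
          next
        }
        tuned <- tune_tree(
          resampled, grid = config$tuning_grid, cv_folds = config$cv_folds,
          seed = study_seed(config$master_seed, d, r, "tune")
        )
        model <- tuned$adapter$fit(resampled)
        prob <- tuned$adapter$predict_prob(model, test_set)
        per_method[[m]] <- tibble(
          method = m,
          auprc = auprc(prob, test_set$y),
          auroc = auroc(prob, test_set$y)
        )
      }
      scored <- bind_rows(per_method)
      if (nrow(scored) >= 2L && "none" %in% scored$method) {
        ranked <- rank_methods(scored[c("method", "auprc")], baseline = "none")
        scored <- scored |>
          left_join(ranked[c("method", "rank", "rank_diff")], by = "method")
        scored$complexity <- spec$complexity
        scored$s <- spec$s
        scored$i <- spec$i
        scored$replicate <- r
        rows[[length(rows) + 1L]] <- scored
      }
    }
  }
  results <- bind_rows(rows)
  families <- c(
    none = "baseline",
    purrr::map_chr(reg, "family")
  )
  results$family <- unname(families[results$method])
  summary <- results |>
    mutate(domain = paste(.data$complexity, .data$s, .data$i, sep = "/")) |>
    group_by(.data$complexity, .data$s, .data$i) |>
    group_modify(~ aggregate_ranks(.x, baseline = "none")) |>
    ungroup() |>
    left_join(
      distinct(results, .data$method, .data$family),
      by = "method"
    )
  structure(
    list(
      results = results,
      summary = summary,
      failures = bind_rows(failures),
      config = config
    ),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d scored rows over %d domain(s), %d failure(s)\n",
    nrow(x$results),
    nrow(distinct(x$results, .data$complexity, .data$s, .data$i)),
    nrow(x$failures)
  ))
  invisible(x)
}

#' Tidy a simulation study
#'
#' @param x A `sim_study`.
#' @param ... Unused.
#' @return The long results tibble (one row per domain x replicate x
#'   method, with AUPRC, AUROC, rank and rank difference).
#' @method tidy sim_study
#' @export
tidy.sim_study <- function(x, ...) {
  x$results
}

#' One-row summary of a simulation study
#'
#' @param x A `sim_study`.
#' @param ... Unused.
#' @return A one-row tibble: domains, replicates, methods, failures, and
#'   the family with the highest mean rank difference.
#' @method glance sim_study
#' @export
glance.sim_study <- function(x, ...) {
  fam <- x$summary |>
    filter(.data$method != "none") |>
    group_by(.data$family) |>
    summarise(mean_rank_diff = mean(.data$mean_rank_diff), .groups = "drop") |>
    arrange(desc(.data$mean_rank_diff))
  tibble(
    n_domains = nrow(distinct(x$results, .data$complexity, .data$s, .data$i)),
    n_replicates = x$config$replicates,
    n_methods = length(x$config$methods),
    n_failures = nrow(x$failures),
    best_family = fam$family[1],
    best_family_mean_rank_diff = fam$mean_rank_diff[1]
  )
}

#' Family-level mean rank differences
#'
#' Averages the per-method mean rank differences within each resampling
#' family (oversampling, undersampling, filtering), per complexity level.
#'
#' @param study A `sim_study`.
#' @return A tibble: `complexity`, `family`, `mean_rank_diff`.
#' @export
family_rank_summary <- function(study) {
  study$summary |>
    filter(.data$method != "none") |>
    group_by(.data$complexity, .data$family) |>
    summarise(mean_rank_diff = mean(.data$mean_rank_diff), .groups = "drop")
}

#' Encode mixed feature columns for resampling
#'
#' Character/factor columns with fewer than five distinct levels are
#' one-hot encoded; those with five or more levels are retained as
#' ordinal integer codes (alphabetical level order). Numeric columns
#' pass through unchanged. The level mapping is attached as the
#' `"encoding"` attribute so a transform of new data can reuse it.
#'
#' @param raw Data frame with a label column `y`.
#' @param encoding Optional mapping from a previous call; unseen levels
#'   error.
#' @return An encoded tibble with attribute `"encoding"`.
#' @export
encode_features <- function(raw, encoding = NULL) {
  check_binary_labels(raw)
  cols <- setdiff(names(raw), "y")
  mapping <- encoding %||% list()
  out <- list()
  for (nm in cols) {
    v <- raw[[nm]]
    if (is.numeric(v)) {
      out[[nm]] <- v
      next
    }
    v <- as.character(v)
    levels_seen <- mapping[[nm]] %||% sort(unique(v))
    if (!all(v %in% levels_seen)) {
      abort(sprintf("encode_features: unseen level in column '%s'", nm))
    }
    mapping[[nm]] <- levels_seen
    if (length(levels_seen) < 5L) {
      for (lv in levels_seen) {
        out[[paste(nm, lv, sep = "_")]] <- as.numeric(v == lv)
      }
    } else {
      out[[nm]] <- as.numeric(match(v, levels_seen))
    }
  }
  # recode the label to 0/1 with the minority class as 1, the convention
  # every downstream resampler and metric assumes
  y_levels <- mapping[[".y_levels"]]
  if (is.null(y_levels)) {
    tab <- table(raw$y)
    lv <- names(sort(tab, decreasing = TRUE)) # minority last
    if (length(lv) == 2L && tab[[lv[1]]] == tab[[lv[2]]]) lv <- sort(lv)
    y_levels <- lv
    mapping[[".y_levels"]] <- y_levels
  }
  if (!all(as.character(raw$y) %in% y_levels)) {
    abort("encode_features: unseen level in label column")
  }
  out$y <- as.numeric(as.character(raw$y) == y_levels[2])
  res <- as_tibble(out)
  attr(res, "encoding") <- mapping
  res
}

# Stratified 7:3 (or other) split; re-drawn until both classes appear on
# both sides, which stratification guarantees whenever each class has at
# least 2 rows.
stratified_split <- function(data, train_frac = 0.7) {
  pos <- minority_label(data$y)
  train_idx <- integer()
  for (cls in unique(data$y)) {
    idx <- which(data$y == cls)
    n_train <- max(1L, as.integer(round_half_up(length(idx) * train_frac)))
    if (length(idx) >= 2L) n_train <- min(n_train, length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  list(
    train = data[sort(train_idx), , drop = FALSE],
    test = data[setdiff(seq_len(nrow(data)), train_idx), , drop = FALSE]
  )
}

#' Run the real-data (CSV directory) study
#'
#' For every CSV in `dir`: encodes features, profiles complexity on the
#' full dataset, splits 7:3 stratified by class, and evaluates the
#' baseline plus every configured resampler under every configured
#' classifier (tuned trees use cross-validated grid search; other
#' adapters are used as configured), scoring AUPRC and AUROC on the
#' held-out 30\%. Datasets whose split cannot retain both classes are
#' skipped with a log entry.
#'
#' @param dir Directory of CSV files with a binary label column.
#' @param config A [study_config()]; `classifiers` and `methods` drive
#'   the grid.
#' @param label Label column name in the CSVs.
#' @return A `real_study` object: `results` (dataset x method x
#'   classifier AUPRC/AUROC), `complexity` (per-dataset profiles with
#'   strata columns), `top` (top combinations per stratification rule),
#'   `skipped`.
#' @export
run_real_study <- function(dir, config = study_config(), label = "y") {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) abort("run_real_study: no CSV files found")
  reg <- resampler_registry(include_optional = TRUE)
  results <- list()
  profiles <- list()
  skipped <- list()
  for (fi in seq_along(files)) {
    id <- sub("\\.csv$", "", basename(files[fi]))
    raw <- read_dataset(files[fi], label = label)
    data <- encode_features(raw)
    if (length(unique(data$y)) < 2L || min(table(data$y)) < 2L) {
      skipped[[length(skipped) + 1L]] <- tibble(dataset = id, reason = "needs 2+ rows per class")
      next
    }
    profiles[[length(profiles) + 1L]] <- complexity_profile(data, dataset_id = id)
    split <- with_seed_or_not(
      derive_seed(config$master_seed, fi),
      stratified_split(data, 0.7)
    )
    for (m in c("none", config$methods)) {
      resampled <- if (m == "none") {
        split$train
      } else {
        res <- tryCatch(
          reg[[m]]$fn(split$train, config$method_params[[m]] %||% list(),
                      seed = derive_seed(config$master_seed, fi * 100L + match(m, config$methods))),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          skipped[[length(skipped) + 1L]] <- tibble(
            dataset = id, reason = sprintf("%s failed: %s", m, conditionMessage(res))
          )
          next
        }
        res$data
      }
      if (length(unique(resampled$y)) < 2L) next
      for (cl_name in names(config$classifiers)) {
        cl <- config$classifiers[[cl_name]]
        scored <- tryCatch({
          adapter_use <- cl
          if (identical(cl$name, "DT")) {
            tuned <- tune_tree(resampled, grid = config$tuning_grid,
                               cv_folds = config$cv_folds,
                               seed = derive_seed(config$master_seed, fi * 7L))
            adapter_use <- tuned$adapter
          }
          model <- adapter_use$fit(resampled)
          prob <- adapter_use$predict_prob(model, split$test)
          tibble(
            dataset = id, method = m, classifier = cl_name,
            auprc = auprc(prob, split$test$y),
            auroc = auroc(prob, split$test$y)
          )
        }, error = function(e) NULL)
        if (!is.null(scored)) results[[length(results) + 1L]] <- scored
      }
    }
  }
  results <- bind_rows(results)
  profiles <- bind_rows(profiles)
  if (nrow(profiles) > 0L) {
    profiles$f3_stratum <- stratify(profiles$f3, "tertiles")
    profiles$n2_stratum <- stratify(profiles$n2, "tertiles")
    profiles$c2_stratum <- stratify(profiles$c2, "tertiles")
    if (nrow(profiles) >= 4L) {
      profiles$imbalanced <- stratify(profiles$c2, "top25")
      profiles$f3_complex <- stratify(profiles$f3, "top25")
      profiles$f3_noncomplex <- stratify(profiles$f3, "bottom25")
      profiles$n2_complex <- stratify(profiles$n2, "top25")
      profiles$n2_noncomplex <- stratify(profiles$n2, "bottom25")
    }
  }
  top <- list()
  if (nrow(results) > 0L && nrow(profiles) >= 4L) {
    for (measure in c("f3", "n2")) {
      for (side in c("complex", "noncomplex")) {
        keep <- profiles$dataset[profiles$imbalanced &
                                   profiles[[paste(measure, side, sep = "_")]]]
        sub <- results |> filter(.data$dataset %in% keep)
        if (nrow(sub) > 0L) {
          top[[paste(measure, side, sep = "_")]] <-
            tryCatch(top_combinations(sub), error = function(e) NULL)
        }
      }
    }
  }
  structure(
    list(
      results = results, complexity = profiles,
      top = top, skipped = bind_rows(skipped), config = config
    ),
    class = "real_study"
  )
}

#' @export
print.real_study <- function(x, ...) {
  cat(sprintf(
    "<real_study> %d datasets, %d scored rows, %d skip/log entries\n",
    nrow(x$complexity), nrow(x$results), nrow(x$skipped)
  ))
  invisible(x)
}
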