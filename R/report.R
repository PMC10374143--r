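# Report bundle: the tabular twins of the study's figure panels, written
# as CSV + a JSON manifest of the configuration and seed lineage.

#' Write a summary bundle for a study
#'
#' For a simulation study, writes the per-complexity-level mean
#' rank-difference table with significance flags, the long results
#' table, and a JSON manifest of the configuration and master seed. For
#' a real-data study, also writes the complexity-profile table and the
#' top-combination tables.
#'
#' @param study A `sim_study` or `real_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
make_report <- function(study, dir = study$config$output_dir) {
  if (is.null(dir)) abort("make_report: no output directory configured")
  cfg <- study$config
  if (length(cfg$methods) == 0L) abort("make_report: empty method list")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path)
    written <<- c(written, path)
  }
  if (inherits(study, "sim_study")) {
    put(study$results, "results.csv")
    put(study$summary, "rank_summary.csv")
    put(family_rank_summary(study), "family_rank_summary.csv")
    if (nrow(study$failures)) put(study$failures, "failures.csv")
  } else if (inherits(study, "real_study")) {
    put(study$results, "results.csv")
    put(study$complexity, "complexity_profiles.csv")
    for (nm in names(study$top)) {
      if (!is.null(study$top[[nm]])) put(study$top[[nm]], paste0("top_", nm, ".csv"))
    }
  } else {
    abort("make_report: expected a sim_study or real_study")
  }
  manifest <- list(
    study = class(study)[1],
    replicates = cfg$replicates,
    test_size = cfg$test_size,
    methods = cfg$methods,
    cv_folds = cfg$cv_folds,
    master_seed = cfg$master_seed,
    domains = if (!is.null(cfg$domains)) {
      cfg$domains[c("complexity", "s", "i")]
    }
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, manifest_path)
  invisible(written)
}

#' Rebuild a study configuration from a report manifest
#'
#' @param path Path to a `manifest.json` written by [make_report()].
#' @return A [study_config()] equivalent to the one that produced the
#'   report (classifiers and tuning grid at their defaults).
#' @export
read_manifest_config <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  domains <- enumerate_domains() |>
    inner_join(as_tibble(m$domains), by = c("complexity", "s", "i"))
  study_config(
    domains = domains,
    replicates = m$replicates,
    test_size = m$test_size,
    methods = m$methods,
    cv_folds = m$cv_folds,
    master_seed = m$master_seed
  )
}
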