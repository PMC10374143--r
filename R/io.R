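# Shared dataset format: CSV with header X1..X6,y(,eta) for simulated
# domains, or arbitrary feature columns + binary y for real data. Domain
# manifests are JSON.

#' Write a labeled dataset to CSV
#'
#' @param data Labeled dataset.
#' @param path Output path.
#' @param keep_eta Keep the diagnostic `eta` column if present.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, keep_eta = TRUE) {
  out <- data
  out$.interval <- NULL
  out$.source <- NULL
  if (!keep_eta) out$eta <- NULL
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a labeled dataset from CSV
#'
#' @param path CSV path with a binary label column.
#' @param label Name of the label column (renamed to `y`).
#' @return A tibble.
#' @export
read_dataset <- function(path, label = "y") {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!label %in% names(out)) {
    abort(sprintf("label column '%s' not found in %s", label, path))
  }
  names(out)[names(out) == label] <- "y"
  out
}

#' Write a domain manifest
#'
#' Records the domain spec fields, seed and realized class counts as
#' JSON next to a generated dataset.
#'
#' @param spec A [domain_spec()].
#' @param data The generated dataset.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_domain_manifest <- function(spec, data, path) {
  pos <- minority_label(data$y)
  manifest <- list(
    complexity = spec$complexity,
    c = spec$c, s = spec$s, i = spec$i, rho = spec$rho,
    seed = spec$seed,
    n = nrow(data),
    n_minority = sum(data$y == pos),
    n_majority = sum(data$y != pos)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a domain manifest back into a spec
#'
#' @param path Manifest JSON path.
#' @return A [domain_spec()].
#' @export
read_domain_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  domain_spec(m$complexity, s = m$s, i = m$i, rho = m$rho, seed = m$seed)
}
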