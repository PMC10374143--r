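#' Resampling results
#'
#' Every resampler returns a `resample_result`: the resampled dataset plus
#' per-class counts of rows that were added (synthetic or duplicated) and
#' removed. The dataset carries a `.source` column tagging each row
#' `"original"` or `"synthetic"`.
#'
#' @param data The resampled dataset (tibble).
#' @param input The dataset the resampler was given.
#' @param method Name of the resampler.
#' @return An object of class `resample_result` with elements `data`,
#'   `added`, `removed`, `method`.
#' @keywords internal
new_resample_result <- function(data, input, method) {
  pos <- minority_label(input$y)
  count_by_class <- function(y) {
    c(minority = sum(y == pos), majority = sum(y != pos))
  }
  if (!".source" %in% names(data)) data$.source <- "original"
  in_counts <- count_by_class(input$y)
  orig <- data[data$.source == "original", ]
  synth <- data[data$.source == "synthetic", ]
  structure(
    list(
      data = as_tibble(data),
      added = count_by_class(if (nrow(synth)) synth$y else input$y[0]),
      removed = in_counts - count_by_class(orig$y),
      method = method
    ),
    class = "resample_result"
  )
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf(
    "<resample_result: %s> %d rows (added: %d min / %d maj; removed: %d min / %d maj)\n",
    x$method, nrow(x$data),
    x$added[["minority"]], x$added[["majority"]],
    x$removed[["minority"]], x$removed[["majority"]]
  ))
  invisible(x)
}

#' Tidy a resampling result
#'
#' @param x A `resample_result`.
#' @param ... Unused.
#' @return The resampled dataset as a tibble, with its `.source`
#'   provenance column.
#' @method tidy resample_result
#' @export
tidy.resample_result <- function(x, ...) {
  x$data
}

#' One-row summary of a resampling result
#'
#' @param x A `resample_result`.
#' @param ... Unused.
#' @return A one-row tibble: method, row counts before/after, per-class
#'   added/removed counts, and the output imbalance ratio.
#' @method glance resample_result
#' @export
glance.resample_result <- function(x, ...) {
  pos <- minority_label(x$data$y)
  n_min <- sum(x$data$y == pos)
  n_maj <- nrow(x$data) - n_min
  tibble(
    method = x$method,
    n = nrow(x$data),
    n_minority = n_min,
    n_majority = n_maj,
    added_minority = x$added[["minority"]],
    added_majority = x$added[["majority"]],
    removed_minority = x$removed[["minority"]],
    removed_majority = x$removed[["majority"]],
    imbalance_ratio = if (n_min > 0) n_maj / n_min else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Split a labeled dataset into minority/majority row indices.
class_split <- function(data) {
  pos <- minority_label(data$y)
  list(
    pos = pos,
    min_idx = which(data$y == pos),
    maj_idx = which(data$y != pos)
  )
}
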