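#' Construct a labeled ordinal dataset
#'
#' The container that flows through the whole package: a numeric feature
#' matrix `X` (samples in rows), an ordinal label vector `y` with values in
#' `1..C`, and sample identifiers.
#'
#' @param X Numeric matrix, samples x features. All entries must be finite.
#' @param y Integer-valued vector of ordinal class labels in `{1..C}`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the row names of `X` or `"s1".."sn"`.
#' @param C Number of ordinal classes. Defaults to `max(y)`; a class level
#'   absent from `y` triggers a warning, not an error (this happens routinely
#'   in bootstrap resamples).
#'
#' @return An object of class `labeled_dataset`: a list with elements `X`,
#'   `y`, `sample_ids`, `C`.
#' @export
labeled_dataset <- function(X, y, sample_ids = NULL, C = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  y <- as.integer(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (any(y < 1L)) stop("labels must be positive integers 1..C")
  if (is.null(C)) C <- max(y)
  C <- as.integer(C)
  if (any(y > C)) stop("labels exceed the stated class count C")
  missing_classes <- setdiff(seq_len(C), unique(y))
  if (length(missing_classes) > 0L) {
    warning("classes absent from y: ", paste(missing_classes, collapse = ", "))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(X)")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  structure(list(X = X, y = y, sample_ids = sample_ids, C = C),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", nrow(x$X), "samples x", ncol(x$X), "features,",
      x$C, "ordinal classes\n")
  cat("class counts:", paste(tabulate(x$y, x$C), collapse = "/"), "\n")
  invisible(x)
}

#' Subset a labeled dataset by sample indices
#'
#' @param data A `labeled_dataset`.
#' @param idx Integer indices (duplicates allowed, e.g. bootstrap draws).
#' @return A `labeled_dataset` with the selected rows. Bootstrap duplicates
#'   get suffixed ids to keep them unique.
#' @export
subset_samples <- function(data, idx) {
  stopifnot(inherits(data, "labeled_dataset"))
  ids <- data$sample_ids[idx]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = ".rep")
  suppressWarnings(
    labeled_dataset(data$X[idx, , drop = FALSE], data$y[idx],
                    sample_ids = ids, C = data$C)
  )
}
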