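#' Construct a labelled expression dataset
#'
#' Bundles a numeric sample-by-feature matrix with one class label per
#' sample. This is the container every other function in the package
#' consumes: rows are samples (the antigens the candidate feature subsets
#' are evaluated against), columns are features (genes, probes, ...).
#'
#' @param x Numeric matrix or data frame, `n` samples by `q` features.
#'   All values must be finite.
#' @param labels Vector of `n` class labels (any atomic type; coerced to
#'   factor with levels in sorted order). At least two distinct classes
#'   are required.
#' @param feature_names Optional character vector of length `q`; defaults
#'   to the column names of `x`, or `"f0" ... "f{q-1}"` when absent.
#' @param sample_ids Optional character vector of length `n`.
#'
#' @return An object of class `labeled_dataset`: a list with elements
#'   `x` (numeric matrix), `labels` (factor), `feature_names`,
#'   `sample_ids`, and the sizes `n`, `q`, `c`.
#'
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 4, 5), c("a", "a", "b", "b"))
#' d$q
#' @export
labeled_dataset <- function(x, labels, feature_names = NULL, sample_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    bad <- which(!apply(x, 2, function(col) all(!is.na(suppressWarnings(as.numeric(col))))))
    abort(sprintf("expression matrix is not numeric (first offending column: %s)",
                  if (length(bad)) colnames(x)[bad[1]] %||% bad[1] else "?"))
  }
  if (any(!is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite expression value at row %d, column %d", idx[1], idx[2]))
  }
  if (length(labels) != nrow(x)) {
    abort(sprintf("%d labels for %d samples", length(labels), nrow(x)))
  }
  labels <- factor(as.character(labels), levels = sort(unique(as.character(labels))))
  if (nlevels(labels) < 2) {
    abort("at least 2 distinct classes are required")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(x) %||% paste0("f", seq_len(ncol(x)) - 1L)
  }
  stopifnot(length(feature_names) == ncol(x))
  if (is.null(sample_ids)) {
    sample_ids <- rownames(x) %||% paste0("s", seq_len(nrow(x)))
  }
  dimnames(x) <- list(sample_ids, feature_names)
  structure(
    list(x = x, labels = labels, feature_names = feature_names,
         sample_ids = sample_ids,
         n = nrow(x), q = ncol(x), c = nlevels(labels)),
    class = "labeled_dataset"
  )
}

#' Coerce a data frame to a labelled dataset
#'
#' @param data A data frame with one column of class labels and the
#'   remaining columns numeric features, or an existing
#'   [labeled_dataset()] (returned unchanged).
#' @param label_column Name of the label column. Default `"class"`.
#'
#' @return A [labeled_dataset()].
#' @export
as_labeled_dataset <- function(data, label_column = "class") {
  if (inherits(data, "labeled_dataset")) {
    return(data)
  }
  data <- as.data.frame(data)
  if (!label_column %in% names(data)) {
    abort(sprintf("label column '%s' not found", label_column))
  }
  labels <- data[[label_column]]
  feats <- data[setdiff(names(data), label_column)]
  check_numeric_features(feats)
  labeled_dataset(as.matrix(feats), labels,
                  sample_ids = if (!is.null(rownames(data))) rownames(data))
}

#' Read a labelled expression matrix from delimited text
#'
#' Expects a header row. By default rows are samples and columns are
#' features, with class labels either in one named column or in a sidecar
#' file (one label per line, same sample order). Feature-major dumps
#' (features in rows), common for microarray text exports, are handled by
#' `transpose = TRUE`.
#'
#' @param path Path to the delimited file.
#' @param label_column Name of the label column inside the file, or the
#'   path of a separate label file (tried when no such column exists).
#' @param delimiter Field delimiter, default `","`.
#' @param transpose If `TRUE`, the file is read as features x samples and
#'   transposed before assembly; the label column is then looked up among
#'   rows (first column holds feature names).
#'
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path, label_column = "class", delimiter = ",",
                         transpose = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("dataset file not found: %s", path))
  }
  tab <- readr::read_delim(path, delim = delimiter, show_col_types = FALSE,
                           progress = FALSE)
  tab <- as.data.frame(tab, check.names = FALSE)
  if (transpose) {
    rn <- as.character(tab[[1]])
    mat <- t(as.matrix(tab[-1]))
    colnames(mat) <- rn
    tab <- as.data.frame(mat, check.names = FALSE)
    tab <- data.frame(lapply(tab, flex_numeric), check.names = FALSE,
                      row.names = rownames(tab))
  }
  if (label_column %in% names(tab)) {
    return(as_labeled_dataset(tab, label_column))
  }
  if (file.exists(label_column)) {
    labels <- readLines(label_column)
    labels <- labels[nzchar(labels)]
    if (length(labels) != nrow(tab)) {
      abort(sprintf("label file has %d labels for %d samples",
                    length(labels), nrow(tab)))
    }
    check_numeric_features(tab)
    return(labeled_dataset(as.matrix(tab), labels))
  }
  abort(sprintf("label column '%s' is neither a column of %s nor a file",
                label_column, path))
}

check_numeric_features <- function(feats) {
  bad <- which(!vapply(feats, is.numeric, logical(1)))
  if (length(bad)) {
    col <- names(feats)[bad[1]]
    cell <- suppressWarnings(which(is.na(as.numeric(as.character(feats[[col]])))))
    row <- if (length(cell)) cell[1] else 1L
    abort(sprintf("non-numeric expression cell at row %d, column '%s'", row, col))
  }
  invisible(feats)
}

# keep label-like character columns while failing loudly on bad cells
flex_numeric <- function(col) {
  if (is.numeric(col)) return(col)
  num <- suppressWarnings(as.numeric(col))
  if (any(is.na(num))) col else num
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features, %d classes (%s)\n",
              x$n, x$q, x$c,
              paste(sprintf("%s:%d", levels(x$labels), tabulate(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.labeled_dataset <- function(x, ..., label_column = "class") {
  out <- as.data.frame(x$x, check.names = FALSE)
  out[[label_column]] <- as.character(x$labels)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
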