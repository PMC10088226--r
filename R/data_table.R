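#' Tabular classification dataset
#'
#' `data_table` is the package's dataset container: a numeric sample-by-feature
#' matrix, integer class labels in `0..C-1`, a logical mask of missing cells,
#' and per-feature metadata. Rows are samples, columns are features. Missing
#' cells hold `NA` in `values` and `TRUE` in `missing_mask`; labels are never
#' missing.
#'
#' @param values numeric matrix, samples in rows, features in columns. `NA`
#'   entries are taken as missing.
#' @param labels vector of class labels, one per row. Integer labels already in
#'   `0..C-1` are kept as-is; anything else is mapped to `0..C-1` by first
#'   appearance and the original values retained in `label_levels`.
#' @param feature_names optional character vector of column names.
#' @param missing_mask optional logical matrix, same shape as `values`;
#'   defaults to `is.na(values)`.
#' @param label_levels optional character vector giving the original label for
#'   each integer code.
#'
#' @return an object of class `data_table` with fields `values`, `labels`,
#'   `class_count`, `feature_names`, `missing_mask`, `feature_kinds` (each
#'   feature tagged `"binary"` iff its observed values lie in \{0, 1\}, else
#'   `"numeric"`), and `label_levels`.
#' @export
data_table <- function(values, labels, feature_names = NULL,
                       missing_mask = NULL, label_levels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("a data_table needs at least 2 samples")
  if (ncol(values) < 1L) stop("a data_table needs at least 1 feature")
  if (length(labels) != nrow(values))
    stop("labels must have one entry per row of `values`")
  if (anyNA(labels)) stop("labels must not be missing")

  if (is.null(label_levels)) {
    if (is.numeric(labels) && all(labels == floor(labels)) &&
        setequal(unique(labels), seq_len(length(unique(labels))) - 1L)) {
      labels <- as.integer(labels)
      label_levels <- as.character(sort(unique(labels)))
    } else {
      lv <- as.character(unique(as.character(labels)))
      label_levels <- lv
      labels <- match(as.character(labels), lv) - 1L
    }
  } else {
    labels <- as.integer(labels)
  }
  class_count <- length(unique(labels))
  if (class_count < 2L) stop("fewer than 2 classes")

  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(values)))
    stop("missing_mask must match the shape of `values`")
  values[missing_mask] <- NA_real_
  if (anyNA(values[!missing_mask]))
    stop("NA values present outside missing_mask")

  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names))
      feature_names <- paste0("f", seq_len(ncol(values)))
  }
  colnames(values) <- feature_names

  feature_kinds <- vapply(seq_len(ncol(values)), function(j) {
    v <- values[!missing_mask[, j], j]
    if (length(v) && all(v %in% c(0, 1))) "binary" else "numeric"
  }, character(1))

  structure(
    list(values = values, labels = labels,
         class_count = as.integer(class_count),
         feature_names = feature_names,
         missing_mask = missing_mask,
         feature_kinds = feature_kinds,
         label_levels = label_levels),
    class = "data_table")
}

#' @export
print.data_table <- function(x, ...) {
  cat(sprintf("data_table: %d samples x %d features, %d classes, %d missing cells\n",
              nrow(x$values), ncol(x$values), x$class_count,
              sum(x$missing_mask)))
  invisible(x)
}

#' Number of samples / features of a data_table
#' @param table a [data_table].
#' @return integer count.
#' @export
n_samples <- function(table) nrow(table$values)

#' @rdname n_samples
#' @export
n_features <- function(table) ncol(table$values)

#' Row subset of a data_table
#'
#' Keeps all features and metadata; used by the cross-validation harness to
#' carve out training and test folds. Requires the subset to retain at least
#' two classes.
#'
#' @param table a [data_table].
#' @param rows integer vector of row indices to keep.
#' @return a [data_table] restricted to `rows`.
#' @export
subset_rows <- function(table, rows) {
  data_table(table$values[rows, , drop = FALSE],
             table$labels[rows],
             feature_names = table$feature_names,
             missing_mask = table$missing_mask[rows, , drop = FALSE],
             label_levels = table$label_levels)
}

#' Read a UCI-style CSV dataset
#'
#' Reads an RFC-4180 CSV with a header row into a [data_table]. One column is
#' the class label; every other column must be numeric except where a cell
#' matches a missing token. Class labels are mapped to `0..C-1` in order of
#' first appearance; the original strings are kept in `label_levels` so output
#' files can restore them.
#'
#' @param path CSV file path.
#' @param label_column column name, or 1-based column index, of the label.
#' @param missing_tokens character vector of cell values flagged as missing
#'   (default: empty string, `"?"`, `"NA"`).
#' @return a [data_table].
#' @export
read_csv_dataset <- function(path, label_column,
                             missing_tokens = c("", "?", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (is.numeric(label_column)) {
    if (label_column < 1 || label_column > ncol(raw))
      stop("label column index out of range")
    lab_idx <- as.integer(label_column)
  } else {
    lab_idx <- match(label_column, names(raw))
    if (is.na(lab_idx)) stop("label column not found: ", label_column)
  }
  if (ncol(raw) < 2L) stop("need at least one feature column besides the label")

  labels_chr <- trimws(raw[[lab_idx]])
  if (length(unique(labels_chr)) < 2L) stop("fewer than 2 classes")
  feat <- raw[, -lab_idx, drop = FALSE]

  mask <- vapply(feat, function(col) trimws(col) %in% missing_tokens,
                 logical(nrow(raw)))
  mask <- matrix(mask, nrow = nrow(raw))
  vals <- matrix(NA_real_, nrow(raw), ncol(feat))
  for (j in seq_len(ncol(feat))) {
    obs <- !mask[, j]
    if (!any(obs)) stop("column '", names(feat)[j], "' is entirely missing")
    x <- suppressWarnings(as.numeric(trimws(feat[obs, j])))
    if (anyNA(x))
      stop("non-numeric cell in column '", names(feat)[j],
           "' that is not a declared missing token")
    vals[obs, j] <- x
  }

  lv <- unique(labels_chr)
  data_table(vals, match(labels_chr, lv) - 1L,
             feature_names = names(feat), missing_mask = mask,
             label_levels = lv)
}

#' Write a data_table as CSV
#'
#' Inverse of [read_csv_dataset()]: feature columns followed by a `label`
#' column holding the original label strings; missing cells are written as
#' `"?"`. `read_csv_dataset(write_csv_dataset(x))` reproduces `values`,
#' `labels` and `missing_mask` exactly.
#'
#' @param table a [data_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(table, path) {
  vals <- table$values
  out <- as.data.frame(vals)
  for (j in seq_len(ncol(out))) {
    col <- as.character(vals[, j])
    col[table$missing_mask[, j]] <- "?"
    out[[j]] <- col
  }
  names(out) <- table$feature_names
  out$label <- table$label_levels[table$labels + 1L]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a run artifact to a directory
#'
#' Writes search results, metrics reports, curve sets, or plain comparison
#' tables as structured text: JSON for scalars and traces, CSV for point lists
#' and per-sample predictions. Feature indices are written 0-based.
#'
#' @param result a `search_result`, `metrics_report`, `curve_set`, or
#'   data.frame.
#' @param path output directory (created if absent).
#' @param name base file name (default derived from the artifact class).
#' @return character vector of created file paths (the manifest).
#' @export
write_result_bundle <- function(result, path, name = NULL) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- character(0)
  if (inherits(result, "search_result")) {
    name <- name %||% "search_result"
    f <- file.path(path, paste0(name, ".json"))
    jsonlite::write_json(list(
      selected_features = result$best$indices - 1L,
      fitness = result$best$fitness,
      trace = result$trace,
      objective_calls = result$objective_calls,
      seed = result$seed), f, auto_unbox = TRUE, digits = NA)
    files <- f
  } else if (inherits(result, "metrics_report")) {
    name <- name %||% "metrics"
    f <- file.path(path, paste0(name, ".json"))
    jsonlite::write_json(list(
      accuracy = result$accuracy, precision = result$precision,
      sensitivity = result$sensitivity, specificity = result$specificity,
      f_score = result$f_score,
      per_class = result$per_class,
      confusion = result$confusion$counts), f, auto_unbox = TRUE, digits = NA)
    files <- f
  } else if (inherits(result, "curve_set")) {
    name <- name %||% paste0(tolower(result$kind), "_curve")
    f1 <- file.path(path, paste0(name, ".csv"))
    utils::write.csv(result$points, f1, row.names = FALSE)
    f2 <- file.path(path, paste0(name, ".json"))
    jsonlite::write_json(list(kind = result$kind, auc = result$auc),
                         f2, auto_unbox = TRUE, digits = NA)
    files <- c(f1, f2)
  } else if (is.data.frame(result)) {
    name <- name %||% "table"
    f <- file.path(path, paste0(name, ".csv"))
    utils::write.csv(result, f, row.names = FALSE)
    files <- f
  } else {
    stop("unsupported artifact of class ", paste(class(result), collapse = "/"))
  }
  files
}

#' Read back a serialized search result
#'
#' @param path JSON file written by [write_result_bundle()].
#' @return a `search_result` (indices restored to 1-based internal form).
#' @export
read_search_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(best = candidate_solution(as.integer(x$selected_features) + 1L,
                                   fitness = x$fitness),
         trace = as.numeric(x$trace),
         objective_calls = as.integer(x$objective_calls),
         seed = as.integer(x$seed)),
    class = "search_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
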